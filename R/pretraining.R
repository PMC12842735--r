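# Self-pre-training: the model is pre-trained on the downstream task's own
# training images. Two objectives share all machinery except the prediction
# head and the loss: "mae" reconstructs masked pixels under MSE, "mde"
# predicts the deep embeddings of masked patches under L1.

#' Pixel-space masked-autoencoder loss (MSE over masked patches)
#'
#' @param pred |Em| x P^2 predicted pixels for the masked patches only.
#' @param truth |Em| x P^2 original pixels at the same positions.
#' @param mask The `mask_spec` that produced the masked set.
#' @return list(loss, per_patch): mean squared error over all masked-patch
#'   pixels, plus the per-patch breakdown (mean over that patch's pixels).
#' @export
mae_loss <- function(pred, truth, mask) {
  if (length(mask$masked_idx) == 0) stop("degenerate mask: no masked patches")
  if (nrow(pred) != length(mask$masked_idx))
    stop("predictions must cover exactly the masked positions")
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch pred vs truth")
  d2 <- (pred - truth)^2
  list(loss = mean(d2), per_patch = rowMeans(d2))
}

#' Embedding-space masked-deep-embedding loss (L1 over masked patches)
#'
#' The targets are the patch embeddings of the original, uncorrupted
#' patches at masked positions; gradient flow into the target branch is
#' severed by the training step (the loss itself is a pure function).
#'
#' @param pred |Em| x D predicted embeddings for the masked patches only.
#' @param target |Em| x D computed embeddings at the same positions.
#' @param mask The `mask_spec`.
#' @return list(loss, per_patch): mean absolute difference over all
#'   masked-position embedding coordinates.
#' @export
mde_loss <- function(pred, target, mask) {
  if (length(mask$masked_idx) == 0) stop("degenerate mask: no masked patches")
  if (nrow(pred) != length(mask$masked_idx))
    stop("predictions must cover exactly the masked positions")
  if (!all(dim(pred) == dim(target)))
    stop("shape mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs target ", paste(dim(target), collapse = "x"))
  ad <- abs(pred - target)
  list(loss = mean(ad), per_patch = rowMeans(ad))
}

#' Learning rate at a (possibly fractional) epoch
#'
#' Linear ramp from 0 to `base_lr` over `warmup_epochs`, then cosine decay
#' to 0 at `total_epochs`:
#' `lr(e) = base_lr * 0.5 * (1 + cos(pi * (e - warmup) / (total - warmup)))`.
#'
#' @param epoch Real-valued epoch in `[0, total_epochs]`.
#' @param cfg A config carrying `base_lr`, `warmup_epochs`, `total_epochs`.
#' @return Learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$total_epochs)
    stop("epoch ", epoch, " outside [0, ", cfg$total_epochs, "]")
  if (epoch <= cfg$warmup_epochs) {
    if (cfg$warmup_epochs == 0) return(cfg$base_lr)
    return(cfg$base_lr * epoch / cfg$warmup_epochs)
  }
  span <- cfg$total_epochs - cfg$warmup_epochs
  cfg$base_lr * 0.5 * (1 + cos(pi * (epoch - cfg$warmup_epochs) / span))
}

#' Run masked self-pre-training
#'
#' Trains an [mde_model()] on a set of images with AdamW (decoupled weight
#' decay on weight matrices), per-epoch learning rates from [lr_at()], and a
#' fresh random mask per image per step. Fully deterministic under
#' `cfg$seed` up to floating-point reduction order.
#'
#' @param images List of image matrices (the downstream training images).
#' @param cfg A [run_config()].
#' @param objective `"mde"` or `"mae"`.
#' @param epochs Number of epochs (default `cfg$total_epochs`).
#' @param detach_target Sever gradients into the embedding-target branch
#'   (default TRUE).
#' @param simmim_routing Route the corrupted sequence through the encoder
#'   instead of the MAE visible-only routing.
#' @param verbose Print per-epoch loss lines.
#' @return A checkpoint list: `params`, `cfg`, `objective`, `log`
#'   (data.frame epoch/lr/loss), `initial_loss`, `final_loss`, `model`.
#' @export
run_pretraining <- function(images, cfg, objective = c("mde", "mae"),
                            epochs = NULL, detach_target = TRUE,
                            simmim_routing = FALSE, verbose = FALSE) {
  objective <- match.arg(objective)
  if (!length(images)) stop("no images to pre-train on")
  epochs <- if (is.null(epochs)) cfg$total_epochs else epochs
  model <- mde_model(cfg,
                     head = if (objective == "mde") "embedding" else "pixel",
                     simmim_routing = simmim_routing)
  N <- (cfg$image_size %/% cfg$patch_size)^2
  state <- adamw_init(model$params)
  n <- length(images)
  bs <- min(cfg$batch_size, n)
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  initial_loss <- NA_real_

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(substream_seed(cfg$seed, "pretrain"))
  sched <- cfg; sched$total_epochs <- epochs
  sched$warmup_epochs <- min(cfg$warmup_epochs, epochs)
  for (ep in seq_len(epochs)) {
    lr <- lr_at(ep - 0.5, sched)  # epoch-midpoint evaluation of the schedule
    ord <- sample.int(n)
    ep_losses <- c()
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + bs - 1L, n)]
      gsum <- NULL; lsum <- 0
      for (j in idx) {
        mask <- sample_mask(N, cfg$mask_ratio)
        st <- mde_step(model, images[[j]], mask, objective,
                       want_grads = TRUE, detach_target = detach_target)
        if (!is.finite(st$loss))
          stop("non-finite loss at epoch ", ep, "; aborting with diagnostics: ",
               "lr=", lr, " image=", j)
        gsum <- if (is.null(gsum)) st$grads else tree_add(gsum, st$grads)
        lsum <- lsum + st$loss
      }
      gavg <- tree_scale(gsum, 1 / length(idx))
      upd <- adamw_step(model$params, gavg, state, lr,
                        wd = cfg$weight_decay, beta1 = cfg$beta1,
                        beta2 = cfg$beta2)
      model$params <- upd$params; state <- upd$state
      ep_losses <- c(ep_losses, lsum / length(idx))
      i <- i + bs
    }
    if (ep == 1) initial_loss <- ep_losses[1]
    log <- rbind(log, data.frame(epoch = ep, lr = lr,
                                 loss = mean(ep_losses)))
    if (verbose)
      message(sprintf("epoch %3d  lr %.3e  loss %.5f", ep, lr, mean(ep_losses)))
  }
  list(params = model$params, cfg = cfg, objective = objective,
       log = log, initial_loss = initial_loss,
       final_loss = log$loss[nrow(log)], model = model)
}
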