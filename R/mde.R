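# Masked-autoencoder style model whose decoder predicts either raw pixels
# (classic MAE baseline) or deep patch embeddings (MDE). The encoder sees
# visible patches only; the decoder receives the full-length sequence in
# which masked slots hold a single shared learnable mask token. A config
# switch (`simmim_routing`) implements the alternative routing in which the
# corrupted full-length sequence is fed to the encoder itself.

#' Initialize an MDE / MAE model
#'
#' @param cfg A [run_config()].
#' @param head Prediction head: `"embedding"` (MDE, predicts the `d_enc`-dim
#'   patch embedding of each masked patch) or `"pixel"` (MAE baseline,
#'   predicts the `P^2` pixel values).
#' @param tokenizer `"affine"` (single linear layer, default) or `"mlp"`
#'   (two-layer with GELU).
#' @param simmim_routing If `TRUE`, the corrupted full-length token sequence
#'   is routed through the encoder and the decoder stack is bypassed.
#' @return A list of class `mde_model` with `params`, fixed positional
#'   tables, and configuration. Weights are drawn from the "init" substream
#'   of `cfg$seed`.
#' @export
mde_model <- function(cfg, head = c("embedding", "pixel"),
                      tokenizer = c("affine", "mlp"),
                      simmim_routing = FALSE) {
  head <- match.arg(head); tokenizer <- match.arg(tokenizer)
  P <- cfg$patch_size
  in_dim <- P * P
  rows <- cfg$image_size %/% P; cols <- rows
  out_dim <- if (head == "embedding") cfg$d_enc else in_dim
  params <- with_substream(cfg$seed, "init", function() {
    tok <- if (tokenizer == "affine") {
      list(W = rmat(in_dim, cfg$d_enc), b = rep(0, cfg$d_enc))
    } else {
      list(W = rmat(in_dim, cfg$d_enc), b = rep(0, cfg$d_enc),
           W2 = rmat(cfg$d_enc, cfg$d_enc), b2 = rep(0, cfg$d_enc))
    }
    list(tok = tok,
         enc = init_encoder(cfg$d_enc, cfg$enc_depth, cfg$enc_heads),
         proj = list(W = rmat(cfg$d_enc, cfg$d_dec), b = rep(0, cfg$d_dec)),
         emask = stats::rnorm(cfg$d_dec, 0, 0.02),
         emask_enc = stats::rnorm(cfg$d_enc, 0, 0.02),
         dec = init_encoder(cfg$d_dec, cfg$dec_depth, cfg$dec_heads),
         head = list(W = rmat(cfg$d_dec, out_dim), b = rep(0, out_dim)))
  })
  structure(list(params = params, cfg = cfg, head = head,
                 tokenizer = tokenizer, simmim_routing = simmim_routing,
                 rows = rows, cols = cols,
                 pos_enc = positional_encoding(rows, cols, cfg$d_enc),
                 pos_dec = positional_encoding(rows, cols, cfg$d_dec)),
            class = "mde_model")
}

#' Embed flattened patches into token space
#'
#' Applies the model's patch tokenizer (affine map or shallow MLP) to each
#' row of the patch matrix.
#'
#' @param patches N x P^2 matrix (rows of a `patch_grid`).
#' @param model An `mde_model` (or a bare tokenizer parameter list via
#'   `model$params$tok`).
#' @return N x `d_enc` embedding matrix.
#' @export
embed_patches <- function(patches, model) {
  tok <- model$params$tok
  if (ncol(patches) != nrow(tok$W))
    stop("patch vector length ", ncol(patches),
         " does not match tokenizer input dim ", nrow(tok$W))
  e <- sweep(patches %*% tok$W, 2, tok$b, `+`)
  if (!is.null(tok$W2)) e <- sweep(gelu(e) %*% tok$W2, 2, tok$b2, `+`)
  e
}

#' Encode visible tokens only
#'
#' Runs the transformer encoder over the visible subset of embeddings (with
#' their positional encodings already added). The masked patches are never
#' seen by the encoder.
#'
#' @param x_visible |Eum| x `d_enc` matrix of visible tokens + positions.
#' @param model An `mde_model`.
#' @return |Eum| x `d_enc` matrix of latent tokens.
#' @export
encode_visible <- function(x_visible, model) {
  encoder_fwd(x_visible, model$params$enc)$y
}

#' Assemble the decoder input sequence
#'
#' Restores the original patch ordering: visible slots receive the encoder
#' latents projected to decoder width, masked slots receive the single
#' shared learnable mask token; decoder positional encodings are added to
#' every slot.
#'
#' @param latent |Eum| x `d_enc` encoder outputs (original visible order).
#' @param mask A `mask_spec`.
#' @param model An `mde_model`.
#' @return N x `d_dec` decoder input matrix.
#' @export
assemble_decoder_input <- function(latent, mask, model) {
  if (nrow(latent) != length(mask$visible_idx))
    stop("latent length ", nrow(latent), " does not match ",
         length(mask$visible_idx), " visible slots")
  if (length(intersect(mask$masked_idx, mask$visible_idx)))
    stop("mask integrity error: overlapping masked and visible index sets")
  p <- model$params
  ec <- matrix(rep(p$emask, each = mask$n), mask$n, model$cfg$d_dec)
  ec[mask$visible_idx, ] <- sweep(latent %*% p$proj$W, 2, p$proj$b, `+`)
  ec + model$pos_dec[seq_len(mask$n), , drop = FALSE]
}

#' Run the decoder stack over a full-length token sequence
#'
#' @param ec N x `d_dec` decoder input from [assemble_decoder_input()].
#' @param model An `mde_model`.
#' @return N x `d_dec` decoder outputs.
#' @export
decode <- function(ec, model) {
  if (ncol(ec) != model$cfg$d_dec) stop("decoder input width mismatch")
  encoder_fwd(ec, model$params$dec)$y
}

#' Apply the linear prediction head at masked positions
#'
#' @param decoder_out N x `d_dec` decoder outputs.
#' @param mask A `mask_spec`.
#' @param model An `mde_model`; `model$head` selects pixel vs embedding
#'   prediction.
#' @return |Em| x out matrix, rows ordered by increasing masked index.
#' @export
predict_targets <- function(decoder_out, mask, model) {
  h <- model$params$head
  out <- sweep(decoder_out[mask$masked_idx, , drop = FALSE] %*% h$W, 2, h$b, `+`)
  out
}

# Full forward + backward of one pre-training example. Returns the loss and
# (optionally) gradients for every trainable parameter. `detach_target`
# severs gradient flow into the embedding-target branch (the default and the
# anti-collapse choice); when FALSE the target branch also trains the
# tokenizer.
mde_step <- function(model, image, mask, objective = c("mde", "mae"),
                     want_grads = TRUE, detach_target = TRUE) {
  objective <- match.arg(objective)
  if ((objective == "mde") != (model$head == "embedding"))
    stop("head/objective mismatch: objective '", objective,
         "' requires the ", if (objective == "mde") "embedding" else "pixel",
         " head")
  p <- model$params; cfg <- model$cfg
  grid <- patchify(image, cfg$patch_size)
  X <- grid$patches
  N <- grid$n
  vis <- mask$visible_idx; msk <- mask$masked_idx
  M <- length(msk)

  Hpre <- sweep(X %*% p$tok$W, 2, p$tok$b, `+`)
  mlp_tok <- !is.null(p$tok$W2)
  E <- if (mlp_tok) sweep(gelu(Hpre) %*% p$tok$W2, 2, p$tok$b2, `+`) else Hpre

  if (model$simmim_routing) {
    xin <- E
    xin[msk, ] <- matrix(rep(p$emask_enc, each = M), M, cfg$d_enc)
    xin <- xin + model$pos_enc[seq_len(N), , drop = FALSE]
    ef <- encoder_fwd(xin, p$enc)
    dec_out_full <- ef$y %*% p$proj$W
    dec_out_full <- sweep(dec_out_full, 2, p$proj$b, `+`)
    pred <- sweep(dec_out_full[msk, , drop = FALSE] %*% p$head$W, 2, p$head$b, `+`)
  } else {
    xv <- E[vis, , drop = FALSE] + model$pos_enc[vis, , drop = FALSE]
    ef <- encoder_fwd(xv, p$enc)
    latent <- ef$y
    ec <- matrix(rep(p$emask, each = N), N, cfg$d_dec)
    proj_lat <- sweep(latent %*% p$proj$W, 2, p$proj$b, `+`)
    ec[vis, ] <- proj_lat
    ec <- ec + model$pos_dec[seq_len(N), , drop = FALSE]
    df <- encoder_fwd(ec, p$dec)
    pred <- sweep(df$y[msk, , drop = FALSE] %*% p$head$W, 2, p$head$b, `+`)
  }

  if (objective == "mde") {
    target <- E[msk, , drop = FALSE]
    diff <- pred - target
    loss <- mean(abs(diff))
    dpred <- sign(diff) / length(diff)
  } else {
    target <- X[msk, , drop = FALSE]
    diff <- pred - target
    loss <- mean(diff^2)
    dpred <- 2 * diff / length(diff)
  }
  if (!want_grads)
    return(list(loss = loss, pred = pred, target = target, E = E))

  g <- tree_zero(p)
  if (model$simmim_routing) {
    g$head$W <- t(dec_out_full[msk, , drop = FALSE]) %*% dpred
    g$head$b <- colSums(dpred)
    ddec_out <- matrix(0, N, cfg$d_dec)
    ddec_out[msk, ] <- dpred %*% t(p$head$W)
    g$proj$W <- t(ef$y) %*% ddec_out
    g$proj$b <- colSums(ddec_out)
    denc_y <- ddec_out %*% t(p$proj$W)
    eb <- encoder_bwd(denc_y, ef, p$enc)
    g$enc <- eb$grads
    dxin <- eb$dx
    g$emask_enc <- colSums(dxin[msk, , drop = FALSE])
    dE <- dxin; dE[msk, ] <- 0
  } else {
    msk_dec <- df$y[msk, , drop = FALSE]
    g$head$W <- t(msk_dec) %*% dpred
    g$head$b <- colSums(dpred)
    ddec_y <- matrix(0, N, cfg$d_dec)
    ddec_y[msk, ] <- dpred %*% t(p$head$W)
    db <- encoder_bwd(ddec_y, df, p$dec)
    g$dec <- db$grads
    dec_in_grad <- db$dx
    g$emask <- colSums(dec_in_grad[msk, , drop = FALSE])
    dlat_proj <- dec_in_grad[vis, , drop = FALSE]
    g$proj$W <- t(latent) %*% dlat_proj
    g$proj$b <- colSums(dlat_proj)
    dlatent <- dlat_proj %*% t(p$proj$W)
    ebk <- encoder_bwd(dlatent, ef, p$enc)
    g$enc <- ebk$grads
    dE <- matrix(0, N, cfg$d_enc)
    dE[vis, ] <- ebk$dx
  }
  if (objective == "mde" && !detach_target) dE[msk, ] <- dE[msk, ] - dpred
  if (mlp_tok) {
    a <- gelu(Hpre)
    g$tok$W2 <- t(a) %*% dE
    g$tok$b2 <- colSums(dE)
    dh <- (dE %*% t(p$tok$W2)) * gelu_grad(Hpre)
    g$tok$W <- t(X) %*% dh
    g$tok$b <- colSums(dh)
  } else {
    g$tok$W <- t(X) %*% dE
    g$tok$b <- colSums(dE)
  }
  list(loss = loss, grads = g, pred = pred, target = target, E = E, dE = dE)
}

#' Strip a pre-training checkpoint down to its fine-tuning payload
#'
#' The decoder, projection, mask token and prediction head exist only to
#' drive pre-training; exported encoder checkpoints contain none of them.
#'
#' @param ckpt A checkpoint from [run_pretraining()] (or an `mde_model`).
#' @return list with `tok` and `enc` parameter trees plus a config echo.
#' @export
export_encoder_checkpoint <- function(ckpt) {
  params <- if (inherits(ckpt, "mde_model")) ckpt$params else ckpt$params
  list(tok = params$tok, enc = params$enc,
       cfg = if (inherits(ckpt, "mde_model")) ckpt$cfg else ckpt$cfg,
       schema = "mdeimplant-encoder-v1")
}

#' Compose a qualitative reconstruction image
#'
#' Visualization only; never participates in any loss. For the pixel head
#' the predicted pixels are pasted into the masked slots. For the embedding
#' head predicted embeddings are mapped back to pixel space through the
#' least-squares pseudo-inverse of the (affine) patch tokenizer.
#'
#' @param model An `mde_model`.
#' @param image Input image matrix.
#' @param mask A `mask_spec` (or `NULL` to reconstruct nothing).
#' @return list(image, masked_preview): composite image and the input with
#'   masked patches grayed out.
#' @export
visualize_reconstruction <- function(model, image, mask = NULL) {
  grid <- patchify(image, model$cfg$patch_size)
  preview <- grid$patches
  if (!is.null(mask) && length(mask$masked_idx))
    preview[mask$masked_idx, ] <- 0.5
  comp <- grid$patches
  if (!is.null(mask) && length(mask$masked_idx)) {
    st <- mde_step(model, image, mask,
                   objective = if (model$head == "embedding") "mde" else "mae",
                   want_grads = FALSE)
    if (model$head == "pixel") {
      comp[mask$masked_idx, ] <- st$pred
    } else {
      tok <- model$params$tok
      if (!is.null(tok$W2))
        stop("embedding-head visualization requires the affine tokenizer")
      Winv <- pinv(tok$W)
      px <- sweep(st$pred, 2, tok$b, `-`) %*% Winv
      comp[mask$masked_idx, ] <- px
    }
  }
  list(image = unpatchify(comp, grid$rows, grid$cols, grid$P),
       masked_preview = unpatchify(preview, grid$rows, grid$cols, grid$P))
}

#' Moore-Penrose pseudo-inverse via SVD
#' @param A Numeric matrix. @param tol Relative singular-value cutoff.
#' @keywords internal
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
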