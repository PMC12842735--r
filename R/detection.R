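# Stage 1 of the two-stage pipeline: a pre-trained (or randomly initialized)
# ViT encoder acts as detection backbone; a minimal anchor-free dense head
# on the token-resolution feature map emits per-cell class logits, box
# regression targets and an implant-system hint. This deliberately replaces
# a full Mask R-CNN + FPN stack: the detector is a pluggable contract (any
# tool emitting scored part boxes can feed stage 2), and the scientific
# content lives in the pre-training objective and the assembly stage.

#' Initialize a part detector
#'
#' @param cfg A [run_config()].
#' @param classes Character vector of part class names (foreground).
#' @param systems Character vector of implant-system names for the optional
#'   system hint head.
#' @param encoder_ckpt Optional encoder checkpoint from
#'   [export_encoder_checkpoint()]; when NULL the backbone is randomly
#'   initialized.
#' @return A list of class `part_detector`.
#' @export
part_detector <- function(cfg, classes, systems = implant_systems(),
                          encoder_ckpt = NULL) {
  K <- length(classes)
  rows <- cfg$image_size %/% cfg$patch_size
  params <- with_substream(cfg$seed, "detector-init", function() {
    tok <- list(W = rmat(cfg$patch_size^2, cfg$d_enc), b = rep(0, cfg$d_enc))
    enc <- init_encoder(cfg$d_enc, cfg$enc_depth, cfg$enc_heads)
    Hh <- 2L * cfg$d_enc  # hidden width of the box / system MLP heads
    list(tok = tok, enc = enc,
         head = list(Wc = rmat(cfg$d_enc, K + 1), bc = rep(0, K + 1),
                     Wb1 = rmat(cfg$d_enc, Hh, sd = 0.05), bb1 = rep(0, Hh),
                     Wb = rmat(Hh, 4, sd = 0.05), bb = rep(0, 4),
                     Ws1 = rmat(cfg$d_enc, Hh, sd = 0.05), bs1 = rep(0, Hh),
                     Ws = rmat(Hh, length(systems)),
                     bs = rep(0, length(systems))),
         fpn = lapply(1:4, function(i)
           list(W = rmat(cfg$d_enc, cfg$d_enc), b = rep(0, cfg$d_enc))))
  })
  if (!is.null(encoder_ckpt)) {
    if (!identical(dim(encoder_ckpt$tok$W), dim(params$tok$W)))
      stop("checkpoint/config mismatch: tokenizer shape differs")
    params$tok <- encoder_ckpt$tok
    params$enc <- encoder_ckpt$enc
  }
  structure(list(params = params, cfg = cfg, classes = classes,
                 systems = systems, rows = rows, cols = rows,
                 pos_enc = positional_encoding(rows, rows, cfg$d_enc)),
            class = "part_detector")
}

backbone_fwd <- function(det, image) {
  grid <- patchify(image, det$cfg$patch_size)
  E <- sweep(grid$patches %*% det$params$tok$W, 2, det$params$tok$b, `+`)
  x <- E + det$pos_enc
  ef <- encoder_fwd(x, det$params$enc)
  list(tokens = ef$y, enc_cache = ef, X = grid$patches, grid = grid)
}

.upsample_nn <- function(a, f) {
  # a: r x c x D; nearest-neighbor upsample by integer factor f
  r <- dim(a)[1]; cc <- dim(a)[2]
  a[rep(seq_len(r), each = f), rep(seq_len(cc), each = f), , drop = FALSE]
}
.avgpool <- function(a, f) {
  r <- dim(a)[1] %/% f; cc <- dim(a)[2] %/% f; D <- dim(a)[3]
  out <- array(0, c(r, cc, D))
  for (i in seq_len(r)) for (j in seq_len(cc))
    out[i, j, ] <- apply(a[((i - 1) * f + 1):(i * f),
                           ((j - 1) * f + 1):(j * f), , drop = FALSE],
                         3, mean)
  out
}

#' Build a simple feature pyramid from the ViT token map
#'
#' The stride-`P` token map is reshaped to a spatial grid (token `k` maps to
#' cell `(k %/% cols, k %% cols)` row-major), laterally projected per level,
#' then resampled to strides 4, 8, 16 and 32: finer levels by
#' nearest-neighbor upsampling, coarser levels by average pooling.
#'
#' @param det A `part_detector`.
#' @param image Image matrix with sides divisible by the patch size.
#' @return Named list `s4`, `s8`, `s16`, `s32` of row x col x D arrays,
#'   plus attribute `strides`.
#' @export
build_feature_pyramid <- function(det, image) {
  bb <- backbone_fwd(det, image)
  rows <- bb$grid$rows; cols <- bb$grid$cols; D <- det$cfg$d_enc
  fmap <- array(0, c(rows, cols, D))
  for (k in seq_len(rows * cols))
    fmap[(k - 1) %/% cols + 1, (k - 1) %% cols + 1, ] <- bb$tokens[k, ]
  P <- det$cfg$patch_size
  strides <- c(4L, 8L, 16L, 32L)
  out <- list()
  for (li in seq_along(strides)) {
    s <- strides[li]
    lat <- det$params$fpn[[li]]
    flat <- matrix(fmap, rows * cols, D)
    proj <- sweep(flat %*% lat$W, 2, lat$b, `+`)
    pm <- array(proj, c(rows, cols, D))
    f <- s / P
    lvl <- if (f < 1) .upsample_nn(pm, as.integer(1 / f))
           else if (f > 1) .avgpool(pm, as.integer(f))
           else pm
    out[[paste0("s", s)]] <- lvl
  }
  attr(out, "strides") <- strides
  out
}

#' Multi-class focal loss with class weighting
#'
#' `L_i = -w[y_i] * (1 - p_i)^gamma * log(p_i)` with `p_i` the softmax
#' probability of the true class; the mean over rows is returned. With
#' `gamma = 0` and unit weights this reduces exactly to (weighted)
#' cross-entropy.
#'
#' @param logits n x K matrix of unnormalized scores.
#' @param labels Integer vector in `1..K`.
#' @param gamma Focusing parameter (>= 0).
#' @param class_weights Positive weight per class (default all 1).
#' @return Scalar mean loss.
#' @export
focal_loss <- function(logits, labels, gamma = 2, class_weights = NULL) {
  if (gamma < 0) stop("gamma must be non-negative")
  K <- ncol(logits)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  if (any(class_weights <= 0)) stop("class weights must be positive")
  p <- softmax_rows(logits)
  pt <- pmax(p[cbind(seq_len(nrow(logits)), labels)], 1e-12)
  mean(-class_weights[labels] * (1 - pt)^gamma * log(pt))
}

# Gradient of focal_loss wrt logits (mean reduction).
focal_grad <- function(logits, labels, gamma = 2, class_weights = NULL) {
  n <- nrow(logits); K <- ncol(logits)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  p <- softmax_rows(logits)
  pt <- pmax(p[cbind(seq_len(n), labels)], 1e-12)
  w <- class_weights[labels]
  # dL/dpt
  dpt <- -w * (-gamma * (1 - pt)^pmax(gamma - 1, 0) *
                 (if (gamma > 0) log(pt) else 0) + (1 - pt)^gamma / pt)
  onehot <- matrix(0, n, K); onehot[cbind(seq_len(n), labels)] <- 1
  dz <- (dpt * pt) * (onehot - p)
  dz / n
}

# Assign feature-map cells their training targets. Two schemes:
# "center": only the cell containing each ground-truth box center is
#   positive (one crisp positive per box, offsets bounded by half a cell);
# "inside": every cell whose center falls inside a box is positive (ties
#   resolved to the smallest box).
assign_targets <- function(rows, cols, stride, boxes, labels, systems_id,
                           scheme = c("inside", "center")) {
  scheme <- match.arg(scheme)
  n <- rows * cols
  lab <- rep(1L, n)           # class 1 = background
  tbox <- matrix(NA_real_, n, 4)
  sys <- rep(NA_integer_, n)
  if (is.null(boxes) || nrow(boxes) == 0)
    return(list(labels = lab, tbox = tbox, sys = sys))
  areas <- boxes[, 3] * boxes[, 4]
  set_cell <- function(k, j, cx, cy) {
    lab[k] <<- labels[j] + 1L   # foreground classes start at 2
    bcx <- boxes[j, 1] + boxes[j, 3] / 2
    bcy <- boxes[j, 2] + boxes[j, 4] / 2
    tbox[k, ] <<- c((bcx - cx) / stride, (bcy - cy) / stride,
                    log(boxes[j, 3] / stride), log(boxes[j, 4] / stride))
    sys[k] <<- systems_id[j]
  }
  if (scheme == "center") {
    ord <- order(areas, decreasing = TRUE)  # small boxes win conflicts
    for (j in ord) {
      bcx <- boxes[j, 1] + boxes[j, 3] / 2
      bcy <- boxes[j, 2] + boxes[j, 4] / 2
      cidx <- min(max(floor(bcx / stride), 0), cols - 1)
      r <- min(max(floor(bcy / stride), 0), rows - 1)
      k <- r * cols + cidx + 1
      set_cell(k, j, (cidx + 0.5) * stride, (r + 0.5) * stride)
    }
  } else {
    for (k in seq_len(n)) {
      r <- (k - 1) %/% cols; cidx <- (k - 1) %% cols
      cx <- (cidx + 0.5) * stride; cy <- (r + 0.5) * stride
      inside <- which(boxes[, 1] <= cx & cx < boxes[, 1] + boxes[, 3] &
                      boxes[, 2] <= cy & cy < boxes[, 2] + boxes[, 4])
      if (!length(inside)) next
      j <- inside[which.min(areas[inside])]
      set_cell(k, j, cx, cy)
    }
  }
  list(labels = lab, tbox = tbox, sys = sys)
}

# Forward + loss + gradients of one fine-tuning example.
detect_step <- function(det, image, targets, gamma = 2, class_weights = NULL,
                        box_weight = 1, sys_weight = 0.5, want_grads = TRUE) {
  bb <- backbone_fwd(det, image)
  h <- det$params$head
  tkn <- bb$tokens
  logits <- sweep(tkn %*% h$Wc, 2, h$bc, `+`)
  preb <- sweep(tkn %*% h$Wb1, 2, h$bb1, `+`)
  hb <- gelu(preb)
  boxp <- sweep(hb %*% h$Wb, 2, h$bb, `+`)
  pres <- sweep(tkn %*% h$Ws1, 2, h$bs1, `+`)
  hs <- gelu(pres)
  sysl <- sweep(hs %*% h$Ws, 2, h$bs, `+`)
  pos <- which(targets$labels > 1L)
  l_cls <- focal_loss(logits, targets$labels, gamma, class_weights)
  l_box <- 0; l_sys <- 0
  if (length(pos)) {
    dbx <- boxp[pos, , drop = FALSE] - targets$tbox[pos, , drop = FALSE]
    l_box <- mean(abs(dbx))
    ps <- softmax_rows(sysl[pos, , drop = FALSE])
    pts <- pmax(ps[cbind(seq_along(pos), targets$sys[pos])], 1e-12)
    l_sys <- mean(-log(pts))
  }
  loss <- l_cls + box_weight * l_box + sys_weight * l_sys
  if (!want_grads)
    return(list(loss = loss, l_cls = l_cls, l_box = l_box, l_sys = l_sys,
                logits = logits, boxp = boxp, sysl = sysl))
  g <- tree_zero(det$params)
  dlog <- focal_grad(logits, targets$labels, gamma, class_weights)
  dboxp <- matrix(0, nrow(boxp), 4)
  dsysl <- matrix(0, nrow(sysl), ncol(sysl))
  if (length(pos)) {
    dbx <- boxp[pos, , drop = FALSE] - targets$tbox[pos, , drop = FALSE]
    dboxp[pos, ] <- box_weight * sign(dbx) / length(dbx)
    ps <- softmax_rows(sysl[pos, , drop = FALSE])
    oh <- matrix(0, length(pos), ncol(sysl))
    oh[cbind(seq_along(pos), targets$sys[pos])] <- 1
    dsysl[pos, ] <- sys_weight * (ps - oh) / length(pos)
  }
  g$head$Wc <- t(tkn) %*% dlog;  g$head$bc <- colSums(dlog)
  g$head$Wb <- t(hb) %*% dboxp;  g$head$bb <- colSums(dboxp)
  dhb <- (dboxp %*% t(h$Wb)) * gelu_grad(preb)
  g$head$Wb1 <- t(tkn) %*% dhb;  g$head$bb1 <- colSums(dhb)
  g$head$Ws <- t(hs) %*% dsysl;  g$head$bs <- colSums(dsysl)
  dhs <- (dsysl %*% t(h$Ws)) * gelu_grad(pres)
  g$head$Ws1 <- t(tkn) %*% dhs;  g$head$bs1 <- colSums(dhs)
  dtok <- dlog %*% t(h$Wc) + dhb %*% t(h$Wb1) + dhs %*% t(h$Ws1)
  eb <- encoder_bwd(dtok, bb$enc_cache, det$params$enc)
  g$enc <- eb$grads
  g$tok$W <- t(bb$X) %*% eb$dx
  g$tok$b <- colSums(eb$dx)
  list(loss = loss, grads = g, l_cls = l_cls, l_box = l_box, l_sys = l_sys)
}

.part_levels <- c("coronal", "middle", "apical")

# Pull part-level training samples (image + boxes + class/system ids) out of
# a generated dataset, collapsing design classes to their part level.
.detection_samples <- function(dataset, classes) {
  ann <- dataset$index$annotations
  ann <- ann[ann$level %in% .part_levels, , drop = FALSE]
  systems <- implant_systems()
  lapply(seq_along(dataset$images), function(i) {
    a <- ann[ann$image_id == i, , drop = FALSE]
    list(image = dataset$images[[i]],
         boxes = as.matrix(a[, c("x", "y", "w", "h")]),
         labels = match(a$level, classes),
         systems = match(a$system, systems))
  })
}

#' Fine-tune a detector on part-level annotations
#'
#' Trains the dense head and the ViT backbone end-to-end with AdamW; class
#' imbalance is handled by a focal loss whose class weights default to
#' inverse frequencies computed from the training annotations.
#'
#' @param dataset Output of [generate_dataset()] (or a list with `index`
#'   and `images`).
#' @param cfg A [run_config()]; `base_lr` here is the fine-tuning rate.
#' @param encoder_ckpt Optional pre-trained encoder checkpoint.
#' @param epochs Training epochs (0 returns the initialized detector).
#' @param classes Part classes to predict (default the three part levels).
#' @param gamma Focal-loss focusing parameter.
#' @param augment_ops Augmentations applied per image per epoch.
#' @param verbose Print per-epoch losses.
#' @return A trained `part_detector` with a `log` data.frame attached.
#' @export
run_finetune <- function(dataset, cfg, encoder_ckpt = NULL, epochs = 20,
                         classes = .part_levels, gamma = 2,
                         box_weight = 2, sys_weight = 0.5,
                         augment_ops = character(), verbose = FALSE) {
  samples <- .detection_samples(dataset, classes)
  n_ann <- sum(vapply(samples, function(s) length(s$labels), integer(1)))
  if (n_ann == 0) stop("no part-level annotations to fine-tune on")
  det <- part_detector(cfg, classes, encoder_ckpt = encoder_ckpt)
  freq <- table(factor(unlist(lapply(samples, `[[`, "labels")),
                       levels = seq_along(classes)))
  wfg <- as.numeric(sum(freq) / pmax(freq, 1))
  wfg <- wfg / mean(wfg)
  cw <- c(1, wfg)  # background weight 1, foreground inverse-frequency
  state <- adamw_init(det$params)
  stride <- cfg$patch_size
  n <- length(samples)
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(substream_seed(cfg$seed, "finetune"))
  sched <- cfg; sched$total_epochs <- max(epochs, 1)
  sched$warmup_epochs <- min(cfg$warmup_epochs, ceiling(epochs / 10))
  for (ep in seq_len(epochs)) {
    lr <- lr_at(ep - 0.5, sched)
    ord <- sample.int(n)
    losses <- numeric(0)
    bs <- min(cfg$batch_size, n)
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + bs - 1L, n)]
      gsum <- NULL; lsum <- 0
      for (j in idx) {
        s <- samples[[j]]
        if (length(augment_ops)) {
          s2 <- augment(list(image = s$image, boxes = s$boxes), augment_ops)
          s$image <- s2$image; s$boxes <- s2$boxes
        }
        tg <- assign_targets(det$rows, det$cols, stride, s$boxes, s$labels,
                             s$systems)
        st <- detect_step(det, s$image, tg, gamma, cw,
                          box_weight = box_weight, sys_weight = sys_weight)
        gsum <- if (is.null(gsum)) st$grads else tree_add(gsum, st$grads)
        lsum <- lsum + st$loss
      }
      upd <- adamw_step(det$params, tree_scale(gsum, 1 / length(idx)), state,
                        lr, wd = cfg$weight_decay,
                        beta1 = cfg$beta1, beta2 = cfg$beta2)
      det$params <- upd$params; state <- upd$state
      losses <- c(losses, lsum / length(idx))
      i <- i + bs
    }
    log <- rbind(log, data.frame(epoch = ep, lr = lr, loss = mean(losses)))
    if (verbose)
      message(sprintf("finetune epoch %3d  lr %.2e  loss %.4f",
                      ep, lr, mean(losses)))
  }
  det$log <- log
  det$class_weights <- cw
  if (epochs > 0)
    det$box_cal <- .fit_box_calibration(det, samples, classes)
  det
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 matrix (x, y, w, h). @param scores Numeric vector.
#' @param iou_thresh Suppression threshold.
#' @return Indices of kept boxes, in descending score order.
#' @export
nms_boxes <- function(boxes, scores, iou_thresh = 0.5) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    ious <- vapply(ord, function(j)
      .box_iou_xywh(boxes[i, ], boxes[j, ]), numeric(1))
    ord <- ord[ious <= iou_thresh]
  }
  keep
}

#' Detect implant design parts in an image
#'
#' Runs the detector, decodes per-cell boxes, thresholds scores and applies
#' greedy per-category NMS.
#'
.empty_dets <- function() {
  data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
             category = character(), level = character(), score = numeric(),
             system_hint = character(), stringsAsFactors = FALSE)
}

# Raw per-cell candidates above `pool_thresh` (no NMS, no voting).
.cell_candidates <- function(det, image, pool_thresh) {
  bb <- backbone_fwd(det, image)
  h <- det$params$head
  logits <- sweep(bb$tokens %*% h$Wc, 2, h$bc, `+`)
  boxp <- sweep(gelu(sweep(bb$tokens %*% h$Wb1, 2, h$bb1, `+`)) %*% h$Wb,
                2, h$bb, `+`)
  sysl <- sweep(gelu(sweep(bb$tokens %*% h$Ws1, 2, h$bs1, `+`)) %*% h$Ws,
                2, h$bs, `+`)
  p <- softmax_rows(logits)
  ps <- softmax_rows(sysl)
  stride <- det$cfg$patch_size
  S <- det$cfg$image_size
  rows <- det$rows; cols <- det$cols
  out <- list()
  for (k in seq_len(rows * cols)) {
    fg <- p[k, -1]
    ci <- which.max(fg)
    sc <- fg[ci]
    if (sc < pool_thresh) next
    r <- (k - 1) %/% cols; cidx <- (k - 1) %% cols
    cx <- (cidx + 0.5) * stride; cy <- (r + 0.5) * stride
    bw <- exp(boxp[k, 3]) * stride; bh <- exp(boxp[k, 4]) * stride
    bx <- cx + boxp[k, 1] * stride - bw / 2
    by <- cy + boxp[k, 2] * stride - bh / 2
    x1 <- max(0, bx); y1 <- max(0, by)
    x2 <- min(S, bx + bw); y2 <- min(S, by + bh)
    if (x2 - x1 < 1 || y2 - y1 < 1) next
    out[[length(out) + 1L]] <- data.frame(
      x = x1, y = y1, w = x2 - x1, h = y2 - y1,
      category = det$classes[ci], level = det$classes[ci], score = sc,
      system_hint = det$systems[which.max(ps[k, ])],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_dets())
  do.call(rbind, out)
}

# Per-category NMS over strong candidates, score-weighted box voting over
# the full pool, optional per-class box calibration. Suppression is greedy
# by descending score on IoU overlap OR center proximity: two same-class
# parts can only belong to different implants, which are never centered
# within a fraction of a part diagonal of each other, whereas noisy
# duplicates of one part often overlap their rival by less than the NMS
# threshold.
.merge_candidates <- function(pool, score_thresh, nms_iou, vote_iou, cal,
                              dist_factor = 0.7) {
  if (is.null(pool) || !nrow(pool)) return(.empty_dets())
  kept <- list()
  for (cl in unique(pool$category)) {
    sub <- pool[pool$category == cl, , drop = FALSE]
    bm <- as.matrix(sub[, c("x", "y", "w", "h")])
    strong <- which(sub$score >= score_thresh)
    if (!length(strong)) next
    ord <- strong[order(sub$score[strong], decreasing = TRUE)]
    ki <- integer(0)
    while (length(ord)) {
      i <- ord[1]; ki <- c(ki, i); ord <- ord[-1]
      if (!length(ord)) break
      ci <- c(bm[i, 1] + bm[i, 3] / 2, bm[i, 2] + bm[i, 4] / 2)
      rad <- dist_factor * sqrt(bm[i, 3] * bm[i, 4])
      sup <- vapply(ord, function(j) {
        cj <- c(bm[j, 1] + bm[j, 3] / 2, bm[j, 2] + bm[j, 4] / 2)
        .box_iou_xywh(bm[i, ], bm[j, ]) > nms_iou ||
          sqrt(sum((ci - cj)^2)) < rad
      }, logical(1))
      ord <- ord[!sup]
    }
    keep <- sub[ki, , drop = FALSE]
    if (!is.null(vote_iou)) {
      for (q in seq_along(ki)) {
        ious <- vapply(seq_len(nrow(sub)), function(j)
          .box_iou_xywh(bm[ki[q], ], bm[j, ]), numeric(1))
        vot <- which(ious >= vote_iou)
        wgt <- sub$score[vot] / sum(sub$score[vot])
        keep[q, c("x", "y", "w", "h")] <- colSums(bm[vot, , drop = FALSE] * wgt)
      }
    }
    if (!is.null(cal) && cl %in% cal$class) {
      cr <- cal[cal$class == cl, ]
      cx <- keep$x + keep$w / 2 + cr$dcx
      cy <- keep$y + keep$h / 2 + cr$dcy
      w <- keep$w * cr$rw; h <- keep$h * cr$rh
      keep$x <- cx - w / 2; keep$y <- cy - h / 2
      keep$w <- w; keep$h <- h
    }
    kept[[cl]] <- keep
  }
  if (!length(kept)) return(.empty_dets())
  d <- do.call(rbind, kept)
  d <- d[order(d$score, decreasing = TRUE), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Detect implant design parts in an image
#'
#' Adjacent cells inside the same part produce near-duplicate boxes; after
#' greedy per-category NMS each surviving box is refined by score-weighted
#' averaging over all pooled candidates it overlaps (box voting), which
#' reduces localization noise, and by the detector's per-class box
#' calibration when one was fitted during training.
#'
#' @param det A trained `part_detector`.
#' @param image Image matrix.
#' @param score_thresh Minimum class score for a reported detection.
#' @param nms_iou NMS IoU threshold within each category.
#' @param vote_iou Pooled candidates with at least this IoU against a kept
#'   box contribute to its vote (NULL disables voting).
#' @param pool_thresh Score floor for the voting candidate pool.
#' @param calibrate Apply the stored per-class box calibration, if any.
#' @param dist_factor Same-class boxes whose centers lie within
#'   `dist_factor * sqrt(area)` of a kept box are suppressed along with the
#'   IoU criterion (0 disables distance suppression).
#' @return data.frame (x, y, w, h, category, level, score, system_hint),
#'   sorted by descending score; possibly empty.
#' @export
predict_parts <- function(det, image, score_thresh = 0.3, nms_iou = 0.35,
                          vote_iou = 0.3, pool_thresh = 0.05,
                          calibrate = TRUE, dist_factor = 0.7) {
  pool <- .cell_candidates(det, image, min(pool_thresh, score_thresh))
  .merge_candidates(pool, score_thresh, nms_iou, vote_iou,
                    if (calibrate) det$box_cal else NULL, dist_factor)
}

#' Flip-averaged part detection (test-time augmentation)
#'
#' Pools per-cell candidates from the image and its horizontal and vertical
#' flips (mapped back to the original frame) and merges them with
#' per-category NMS, score-weighted box voting over the pooled candidates,
#' and the detector's box calibration. Averaging three views reduces the
#' localization noise of the dense head considerably on small parts.
#'
#' @inheritParams predict_parts
#' @export
predict_parts_tta <- function(det, image, score_thresh = 0.2,
                              nms_iou = 0.35, vote_iou = 0.25,
                              pool_thresh = 0.05, calibrate = TRUE,
                              dist_factor = 0.7) {
  S <- nrow(image)
  pt <- min(pool_thresh, score_thresh)
  d0 <- .cell_candidates(det, image, pt)
  fh <- .cell_candidates(det, image[, S:1, drop = FALSE], pt)
  if (nrow(fh)) fh$x <- S - fh$x - fh$w
  fv <- .cell_candidates(det, image[S:1, , drop = FALSE], pt)
  if (nrow(fv)) fv$y <- S - fv$y - fv$h
  .merge_candidates(rbind(d0, fh, fv), score_thresh, nms_iou, vote_iou,
                    if (calibrate) det$box_cal else NULL, dist_factor)
}

# Fit a per-class box calibration (median center offset and size ratio of
# matched predictions against ground truth) on the training samples.
.fit_box_calibration <- function(det, samples, classes) {
  res <- list()
  for (s in samples) {
    if (!nrow(s$boxes)) next
    d <- predict_parts_tta(det, s$image, calibrate = FALSE)
    if (!nrow(d)) next
    for (j in seq_len(nrow(s$boxes))) {
      cl <- classes[s$labels[j]]
      dj <- d[d$category == cl, , drop = FALSE]
      if (!nrow(dj)) next
      gb <- as.numeric(s$boxes[j, ])
      iv <- vapply(seq_len(nrow(dj)), function(q)
        .box_iou_xywh(as.numeric(dj[q, c("x", "y", "w", "h")]), gb),
        numeric(1))
      q <- which.max(iv)
      if (iv[q] < 0.2) next
      db <- as.numeric(dj[q, c("x", "y", "w", "h")])
      res[[length(res) + 1L]] <- data.frame(
        class = cl,
        dcx = (gb[1] + gb[3] / 2) - (db[1] + db[3] / 2),
        dcy = (gb[2] + gb[4] / 2) - (db[2] + db[4] / 2),
        rw = gb[3] / db[3], rh = gb[4] / db[4],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(NULL)
  all <- do.call(rbind, res)
  stats::aggregate(all[, c("dcx", "dcy", "rw", "rh")],
                   list(class = all$class), stats::median)
}
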