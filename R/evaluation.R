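# Average-precision evaluation in the COCO style: greedy one-to-one matching
# in descending score order at an IoU threshold, 101-point interpolated
# precision-recall integration, AP reported x100. Both AP50 and the COCO
# 0.50:0.05:0.95 average are always computed.

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes as (x, y, w, h) with positive area.
#' @return IoU in [0, 1]; symmetric in its arguments.
#' @export
iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop("iou requires positive-area boxes")
  .box_iou_xywh(a, b)
}

#' Average precision per class at one IoU threshold
#'
#' Detections are matched greedily in descending score order, one-to-one per
#' ground truth within the same image and class, at `IoU >= iou_thresh`.
#' The precision-recall curve is integrated with 101-point interpolation
#' (precision at recall r is the maximum precision at any recall >= r,
#' sampled at r = 0, 0.01, ..., 1) and reported x100.
#'
#' @param dets data.frame with `image_id`, `category`, `x`, `y`, `w`, `h`,
#'   `score`.
#' @param gts data.frame with `image_id`, `category`, `x`, `y`, `w`, `h`.
#' @param iou_thresh Matching threshold (default 0.5).
#' @return list: `per_class` named numeric vector (classes with ground
#'   truth), `mean_ap`, `skipped` (classes with detections but no ground
#'   truth).
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  classes <- unique(gts$category)
  skipped <- setdiff(unique(dets$category), classes)
  per_class <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    g <- gts[gts$category == cl, , drop = FALSE]
    d <- dets[dets$category == cl, , drop = FALSE]
    n_gt <- nrow(g)
    if (!nrow(d)) { per_class[cl] <- 0; next }
    d <- d[order(d$score, decreasing = TRUE), , drop = FALSE]
    matched <- rep(FALSE, n_gt)
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      cand <- which(!matched & g$image_id == d$image_id[i])
      if (!length(cand)) next
      ious <- vapply(cand, function(j)
        .box_iou_xywh(as.numeric(d[i, c("x", "y", "w", "h")]),
                      as.numeric(g[j, c("x", "y", "w", "h")])), numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_thresh) {
        tp[i] <- TRUE
        matched[cand[best]] <- TRUE
      }
    }
    ctp <- cumsum(tp)
    prec <- ctp / seq_along(tp)
    rec <- ctp / n_gt
    rgrid <- seq(0, 1, by = 0.01)
    pint <- vapply(rgrid, function(r) {
      ok <- rec >= r - 1e-12
      if (!any(ok)) 0 else max(prec[ok])
    }, numeric(1))
    per_class[cl] <- 100 * mean(pint)
  }
  list(per_class = per_class,
       mean_ap = if (length(per_class)) mean(per_class) else NA_real_,
       skipped = skipped)
}

#' Full detection evaluation report
#'
#' @param dets,gts As in [average_precision()].
#' @param iou_thresholds Thresholds for the COCO average (default
#'   0.50:0.05:0.95).
#' @return list of class `eval_report`: `ap50`, `ap_coco`, `per_class_50`,
#'   per-threshold table.
#' @export
evaluate_detections <- function(dets, gts,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  aps <- lapply(iou_thresholds, function(t) average_precision(dets, gts, t))
  m <- vapply(aps, `[[`, numeric(1), "mean_ap")
  structure(list(
    ap50 = m[which.min(abs(iou_thresholds - 0.5))],
    ap_coco = mean(m),
    per_class_50 = aps[[which.min(abs(iou_thresholds - 0.5))]]$per_class,
    by_threshold = data.frame(iou = iou_thresholds, mean_ap = m)
  ), class = "eval_report")
}

# Ground-truth boxes of one level as an evaluation data.frame.
.gt_frame <- function(index, level = "implant", image_ids = NULL) {
  ann <- index$annotations
  ann <- if (level == "part") ann[ann$level %in% .part_levels, , drop = FALSE]
         else ann[ann$level == level, , drop = FALSE]
  if (!is.null(image_ids)) ann <- ann[ann$image_id %in% image_ids, , drop = FALSE]
  cat_name <- index$categories$name[match(ann$category_id,
                                          index$categories$id)]
  data.frame(image_id = ann$image_id,
             category = if (level == "part") ann$level else cat_name,
             x = ann$x, y = ann$y, w = ann$w, h = ann$h,
             stringsAsFactors = FALSE)
}

#' Oracle part detections: ground truth plus bounded jitter
#'
#' Produces scored part detections from the ground-truth annotations with
#' truncated-normal jitter (sd `jitter_sd`, clipped to `max_jitter` pixels)
#' on every box coordinate - an upper-bound stand-in for a perfect stage-1
#' detector when testing stage 2 in isolation.
#'
#' @param index A `coco_index` with part-level annotations.
#' @param image_ids Images to cover (default all).
#' @param jitter_sd,max_jitter Jitter scale and hard cap in pixels.
#' @return data.frame of part detections (x, y, w, h, level, category,
#'   score, system_hint, image_id).
#' @export
oracle_part_detections <- function(index, image_ids = NULL, jitter_sd = 0.5,
                                   max_jitter = 2) {
  ann <- index$annotations
  ann <- ann[ann$level %in% .part_levels, , drop = FALSE]
  if (!is.null(image_ids)) ann <- ann[ann$image_id %in% image_ids, , drop = FALSE]
  jit <- function(n) pmin(max_jitter, pmax(-max_jitter,
                                           stats::rnorm(n, 0, jitter_sd)))
  n <- nrow(ann)
  data.frame(image_id = ann$image_id,
             x = ann$x + jit(n), y = ann$y + jit(n),
             w = pmax(2, ann$w + jit(n)), h = pmax(2, ann$h + jit(n)),
             level = ann$level, category = ann$level,
             score = stats::runif(n, 0.7, 1.0),
             system_hint = ann$system, implant = ann$implant,
             stringsAsFactors = FALSE)
}

#' Patient-level cross-validated evaluation
#'
#' Splits the dataset at patient level with one fixed test set, runs a
#' detection pipeline once per iteration, and reports AP on the fixed test
#' set for each iteration plus mean and sd. The supplied pipeline is a
#' function `(dataset, train_ids, test_ids, iteration) -> detections
#' data.frame` at the requested level.
#'
#' @param dataset Output of [generate_dataset()].
#' @param pipeline Pipeline function (see Details); the default uses oracle
#'   part detections plus stage-2 assembly at implant level.
#' @param level `"part"` or `"implant"` ground truth to evaluate against.
#' @param n_sets Number of patient-level splits (default 5).
#' @param n_iter Iterations (default `n_sets`).
#' @param seed Seed for the split and pipeline substreams.
#' @return list of class `crossval_report`: per-fold `eval_report`s, `ap50`
#'   vector, `mean_ap50`, `sd_ap50`, split sizes.
#' @export
crossval_evaluate <- function(dataset, pipeline = NULL, level = "implant",
                              n_sets = 5, n_iter = n_sets, seed = 1L) {
  index <- dataset$index
  split <- split_patient_level(index, n_sets, seed = seed)
  test_ids <- split$sets[[split$test_set]]
  train_sets <- setdiff(seq_len(n_sets), split$test_set)
  if (is.null(pipeline)) {
    pipeline <- function(dataset, train_ids, test_ids, iteration) {
      parts <- oracle_part_detections(dataset$index, test_ids)
      out <- lapply(unique(parts$image_id), function(iid) {
        im <- assemble_implants(parts[parts$image_id == iid, , drop = FALSE])
        if (!nrow(im)) return(NULL)
        im$image_id <- iid
        im$category <- paste0("implant_", im$system)
        im
      })
      do.call(rbind, out[!vapply(out, is.null, logical(1))])
    }
  }
  gts <- .gt_frame(index, level, test_ids)
  folds <- list(); ap50 <- numeric(0)
  for (it in seq_len(n_iter)) {
    val <- train_sets[(it - 1) %% length(train_sets) + 1]
    train_ids <- unlist(split$sets[setdiff(train_sets, val)])
    dets <- with_substream(seed, paste0("cv-iter-", it), function()
      pipeline(dataset, train_ids, test_ids, it))
    rep_ <- evaluate_detections(dets, gts)
    folds[[it]] <- rep_
    ap50 <- c(ap50, rep_$ap50)
  }
  structure(list(folds = folds, ap50 = ap50, mean_ap50 = mean(ap50),
                 sd_ap50 = stats::sd(ap50),
                 test_size = length(test_ids),
                 set_sizes = lengths(split$sets)),
            class = "crossval_report")
}

#' Mask-ratio / epoch sweep at synthetic scale
#'
#' For each (mask ratio, pre-training epochs) pair: pre-train a tiny model
#' on the synthetic training images with the MDE objective, fine-tune the
#' part detector from the exported encoder, and report held-out part-level
#' AP50. Emits one row per configuration; failed configurations are marked
#' rather than aborting the sweep. No claim is made that synthetic trends
#' must match full-scale radiograph results.
#'
#' @param ratios Mask ratios in (0, 1).
#' @param epochs_list Pre-training epoch counts.
#' @param cfg Tiny [run_config()] template.
#' @param n_images Synthetic training images (an extra 40% is held out).
#' @param finetune_epochs Detector fine-tuning epochs.
#' @param seed Root seed.
#' @return data.frame (mask_ratio, pretrain_epochs, seed, ap50, ap_coco,
#'   status).
#' @export
run_mask_ratio_sweep <- function(ratios, epochs_list, cfg = run_config_tiny(),
                                 n_images = 24, finetune_epochs = 8,
                                 seed = 1L) {
  rows <- list()
  n_test <- max(4, round(0.4 * n_images))
  data <- generate_dataset(n_images + n_test, seed = substream_seed(seed, "sweep-data"),
                           image_size = cfg$image_size,
                           n_implants_range = c(1L, 1L), noise = 0.01)
  train_idx <- seq_len(n_images)
  test_idx <- n_images + seq_len(n_test)
  gts <- .gt_frame(data$index, "part", test_idx)
  for (r in ratios) for (epc in epochs_list) {
    row <- data.frame(mask_ratio = r, pretrain_epochs = epc, seed = seed,
                      ap50 = NA_real_, ap_coco = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      c2 <- cfg; c2$mask_ratio <- r
      ck <- run_pretraining(data$images[train_idx], c2, "mde", epochs = epc)
      enc <- export_encoder_checkpoint(ck)
      c3 <- cfg; c3$base_lr <- 1e-3
      det <- run_finetune(list(index = data$index,
                               images = data$images[train_idx]),
                          c3, encoder_ckpt = enc, epochs = finetune_epochs)
      dets <- do.call(rbind, lapply(test_idx, function(i) {
        d <- predict_parts(det, data$images[[i]])
        if (nrow(d)) { d$image_id <- i; d } else NULL
      }))
      if (is.null(dets)) stop("no detections")
      ev <- evaluate_detections(dets, gts)
      row$ap50 <- ev$ap50; row$ap_coco <- ev$ap_coco
      row
    }, error = function(e) {
      row$status <- paste("failed:", conditionMessage(e))
      row
    })
    rows[[length(rows) + 1L]] <- res
  }
  do.call(rbind, rows)
}
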