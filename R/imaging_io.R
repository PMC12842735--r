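# Box convention used everywhere in this package: COCO (x, y, w, h),
# 0-based pixel coordinates, origin at the image top-left corner.

#' Run configuration
#'
#' Bundles every knob of a pre-training / fine-tuning run in one validated
#' list. Defaults follow the reference training recipe for radiographs:
#' 416x416 inputs, 16x16 patches, 25% mask ratio, AdamW with base learning
#' rate 1.5e-4, weight decay 0.05, beta1 0.9, beta2 0.95, 10 warmup epochs
#' followed by cosine decay.
#'
#' @param seed Integer root seed; all random substreams are derived from it.
#' @param image_size Image side length in pixels (square images).
#' @param patch_size Patch side length `P`; must divide `image_size`.
#' @param mask_ratio Fraction of patches hidden during pre-training, in (0,1).
#' @param d_enc,d_dec Encoder / decoder embedding dimensions.
#' @param enc_depth,dec_depth Number of transformer blocks.
#' @param enc_heads,dec_heads Attention heads (must divide the matching dim).
#' @param base_lr,weight_decay,beta1,beta2 AdamW hyper-parameters.
#' @param warmup_epochs,total_epochs Linear warmup length and total epochs.
#' @param batch_size Images per optimizer step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       image_size = 416L, patch_size = 16L, mask_ratio = 0.25,
                       d_enc = 768L, d_dec = 512L,
                       enc_depth = 12L, dec_depth = 4L,
                       enc_heads = 12L, dec_heads = 8L,
                       base_lr = 1.5e-4, weight_decay = 0.05,
                       beta1 = 0.9, beta2 = 0.95,
                       warmup_epochs = 10, total_epochs = 100,
                       batch_size = 16L) {
  if (mask_ratio <= 0 || mask_ratio >= 1)
    stop("mask_ratio must lie strictly between 0 and 1")
  if (image_size %% patch_size != 0)
    stop("image_size must be divisible by patch_size")
  if (warmup_epochs > total_epochs)
    stop("warmup_epochs must not exceed total_epochs")
  if (base_lr <= 0) stop("base_lr must be positive")
  if (d_enc %% enc_heads != 0 || d_dec %% dec_heads != 0)
    stop("embedding dims must be divisible by the head counts")
  structure(list(
    seed = as.integer(seed), image_size = as.integer(image_size),
    patch_size = as.integer(patch_size), mask_ratio = mask_ratio,
    d_enc = as.integer(d_enc), d_dec = as.integer(d_dec),
    enc_depth = as.integer(enc_depth), dec_depth = as.integer(dec_depth),
    enc_heads = as.integer(enc_heads), dec_heads = as.integer(dec_heads),
    base_lr = base_lr, weight_decay = weight_decay,
    beta1 = beta1, beta2 = beta2,
    warmup_epochs = warmup_epochs, total_epochs = total_epochs,
    batch_size = as.integer(batch_size)
  ), class = "run_config")
}

#' Tiny preset of [run_config()] for CPU-scale experiments
#'
#' 64x64 images with 8x8 patches and a 2-layer, 64-dim encoder. Learning
#' rates are raised relative to the full-scale recipe because tiny models
#' trained with single-image batches tolerate (and need) larger steps.
#'
#' @param ... Overrides passed on to [run_config()].
#' @export
run_config_tiny <- function(...) {
  defaults <- list(image_size = 64L, patch_size = 8L,
                   d_enc = 64L, d_dec = 48L,
                   enc_depth = 2L, dec_depth = 1L,
                   enc_heads = 4L, dec_heads = 4L,
                   base_lr = 1e-3, warmup_epochs = 5, total_epochs = 50,
                   batch_size = 8L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(run_config, defaults)
}

#' Derive a named random substream seed from a root seed
#'
#' Every stochastic stage (mask sampling, augmentation, weight init, splits,
#' scene generation) draws its seed from the root seed plus the stage name,
#' so a stage can be reproduced without replaying the stages before it.
#'
#' @param root Integer root seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(root, name) {
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 1014651319
  as.integer((as.numeric(root) * 2654435 + h) %% 2147483647)
}

.coco_required <- c("images", "annotations", "categories")

#' Read a COCO detection JSON file into a dataset index
#'
#' Parses the standard `images`/`annotations`/`categories` layout (the
#' detection dialect, with `bbox = [x, y, w, h]`). Extra per-record fields
#' used by this package (`patient_id` on images, `level` and `system` on
#' annotations/categories) are carried through when present.
#'
#' @param path Path to a COCO JSON file.
#' @return A `coco_index`: list with data.frames `images`, `annotations`,
#'   `categories`. Annotation boxes are expanded into `x`, `y`, `w`, `h`
#'   columns.
#' @export
read_coco <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  missing <- setdiff(.coco_required, names(js))
  if (length(missing))
    stop("COCO format error: missing key(s) ", paste(missing, collapse = ", "))
  images <- as.data.frame(js$images, stringsAsFactors = FALSE)
  cats <- as.data.frame(js$categories, stringsAsFactors = FALSE)
  ann <- as.data.frame(js$annotations, stringsAsFactors = FALSE)
  if (nrow(ann)) {
    if (is.null(ann$bbox)) stop("COCO format error: missing key bbox")
    bb <- do.call(rbind, lapply(ann$bbox, as.numeric))
    ann$bbox <- NULL
    ann$x <- bb[, 1]; ann$y <- bb[, 2]; ann$w <- bb[, 3]; ann$h <- bb[, 4]
    dangling <- setdiff(ann$image_id, images$id)
    if (length(dangling))
      stop("COCO integrity error: annotation references unknown image_id ",
           paste(utils::head(dangling, 3), collapse = ", "))
    if (length(setdiff(ann$category_id, cats$id)))
      stop("COCO integrity error: annotation references unknown category_id")
  } else {
    ann <- data.frame(id = integer(), image_id = integer(),
                      category_id = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric())
  }
  new_coco_index(images, ann, cats)
}

new_coco_index <- function(images, annotations, categories) {
  structure(list(images = images, annotations = annotations,
                 categories = categories),
            class = "coco_index")
}

#' Write a dataset index back to COCO JSON
#'
#' Inverse of [read_coco()]: `read_coco(write_coco(x, f))` reproduces `x`
#' up to JSON key ordering; boxes are preserved exactly.
#'
#' @param index A `coco_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(index, path) {
  ann <- index$annotations
  ann_out <- ann[setdiff(names(ann), c("x", "y", "w", "h"))]
  ann_out$bbox <- lapply(seq_len(nrow(ann)),
                         function(i) as.numeric(ann[i, c("x", "y", "w", "h")]))
  js <- list(images = index$images, annotations = ann_out,
             categories = index$categories)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = FALSE,
                       dataframe = "rows")
  invisible(path)
}

#' Validate annotation invariants of a dataset index
#'
#' Checks positive box sizes, containment in image bounds, known category
#' ids and known image ids; stops with a descriptive error on violation.
#'
#' @param index A `coco_index`.
#' @return `TRUE`, invisibly.
#' @export
validate_index <- function(index) {
  ann <- index$annotations
  if (!nrow(ann)) return(invisible(TRUE))
  if (any(ann$w <= 0) || any(ann$h <= 0))
    stop("annotation invariant violated: non-positive box size")
  im <- index$images[match(ann$image_id, index$images$id), ]
  if (any(is.na(im$id)))
    stop("annotation invariant violated: dangling image_id")
  if (any(ann$x < 0) || any(ann$y < 0) ||
      any(ann$x + ann$w > im$width) || any(ann$y + ann$h > im$height))
    stop("annotation invariant violated: box outside image bounds")
  if (any(!ann$category_id %in% index$categories$id))
    stop("annotation invariant violated: unknown category_id")
  if (is.null(index$images$patient_id) || any(is.na(index$images$patient_id)))
    stop("annotation invariant violated: image without patient_id")
  invisible(TRUE)
}

#' Partition a dataset into patient-level splits
#'
#' Splits images into `n_sets` groups such that no patient contributes
#' images to more than one group (preventing patient-level leakage between
#' training, validation and test data). Patients are packed greedily by
#' descending image count into sets with target capacities
#' `floor(n/n_sets)`, the division remainder going to one designated set
#' which becomes the fixed test set. With one image per patient this yields
#' exactly equal splits plus a slightly larger test set.
#'
#' @param index A `coco_index` whose `images` carry `patient_id`.
#' @param n_sets Number of splits (>= 2).
#' @param seed Integer seed controlling tie-breaking among equal-size patients.
#' @return A list of class `patient_split` with elements `sets` (list of
#'   image-id vectors), `patients` (list of patient-id vectors) and
#'   `test_set` (index of the fixed test split).
#' @export
split_patient_level <- function(index, n_sets, seed = 1L) {
  if (n_sets < 2) stop("n_sets must be at least 2")
  imgs <- index$images
  pats <- unique(imgs$patient_id)
  if (length(pats) < n_sets)
    stop("infeasible split: fewer distinct patients (", length(pats),
         ") than requested sets (", n_sets, ")")
  counts <- table(imgs$patient_id)[as.character(pats)]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(substream_seed(seed, "patient-split"))
  ord <- sample.int(length(pats))
  pats <- pats[ord]; counts <- as.integer(counts)[ord]
  o2 <- order(counts, decreasing = TRUE)
  pats <- pats[o2]; counts <- counts[o2]

  n <- nrow(imgs)
  base <- n %/% n_sets
  target <- rep(base, n_sets)
  target[n_sets] <- target[n_sets] + (n - base * n_sets)
  remaining <- target
  assign <- integer(length(pats))
  for (i in seq_along(pats)) {
    s <- which.max(remaining)
    assign[i] <- s
    remaining[s] <- remaining[s] - counts[i]
  }
  sets <- lapply(seq_len(n_sets), function(s) {
    p <- pats[assign == s]
    imgs$id[imgs$patient_id %in% p]
  })
  patients <- lapply(seq_len(n_sets), function(s) pats[assign == s])
  sizes <- lengths(sets)
  structure(list(sets = sets, patients = patients,
                 test_set = which.max(sizes)),
            class = "patient_split")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Run a function under a private, named RNG substream
#'
#' Seeds the RNG with [substream_seed()] for the duration of `f` and
#' restores the previous RNG state afterwards, so a stage can be reproduced
#' in isolation without replaying the stages before it.
#'
#' @param root Root seed.
#' @param name Substream name.
#' @param f Function of no arguments executed with the substream active.
#' @return The value of `f()`.
#' @export
with_substream <- function(root, name, f) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(substream_seed(root, name))
  f()
}
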