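# Patch tokenization, positional encodings, random masking, augmentation.
# Images are numeric matrices (rows = y, cols = x) with intensities in [0, 1].

#' Partition an image into non-overlapping square patches
#'
#' Patches are enumerated row-major over the patch grid; each patch is
#' flattened column-within-row (x fastest) into one row of the returned
#' matrix. The operation is lossless: [unpatchify()] inverts it bit-exactly.
#'
#' @param image Numeric matrix, H x W.
#' @param P Patch side length; must divide both image dimensions.
#' @return A list of class `patch_grid`: `patches` (N x P^2 matrix),
#'   `rows`, `cols`, `P`, `n`.
#' @export
patchify <- function(image, P) {
  H <- nrow(image); W <- ncol(image)
  if (H %% P != 0 || W %% P != 0)
    stop("image dimensions (", H, "x", W, ") not divisible by patch size ", P)
  rows <- H %/% P; cols <- W %/% P
  n <- rows * cols
  patches <- matrix(0, n, P * P)
  k <- 0L
  for (r in seq_len(rows)) {
    for (cidx in seq_len(cols)) {
      k <- k + 1L
      blk <- image[((r - 1) * P + 1):(r * P), ((cidx - 1) * P + 1):(cidx * P)]
      patches[k, ] <- as.vector(t(blk))  # x fastest within a patch row
    }
  }
  structure(list(patches = patches, rows = rows, cols = cols, P = P, n = n),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' @param grid A `patch_grid`, or a plain N x P^2 matrix together with
#'   `rows`, `cols`, `P`.
#' @param rows,cols,P Grid geometry when `grid` is a plain matrix.
#' @return The H x W image matrix.
#' @export
unpatchify <- function(grid, rows = NULL, cols = NULL, P = NULL) {
  if (inherits(grid, "patch_grid")) {
    rows <- grid$rows; cols <- grid$cols; P <- grid$P; m <- grid$patches
  } else m <- grid
  img <- matrix(0, rows * P, cols * P)
  k <- 0L
  for (r in seq_len(rows)) {
    for (cidx in seq_len(cols)) {
      k <- k + 1L
      img[((r - 1) * P + 1):(r * P), ((cidx - 1) * P + 1):(cidx * P)] <-
        matrix(m[k, ], P, P, byrow = TRUE)
    }
  }
  img
}

#' Fixed two-dimensional sine-cosine positional encodings
#'
#' Non-trainable position table in the style used by masked-autoencoder
#' implementations: half the channels encode the row coordinate, half the
#' column coordinate, each as interleaved sin/cos at geometrically spaced
#' frequencies. Values lie in [-1, 1] and distinct grid positions receive
#' distinct vectors.
#'
#' @param rows,cols Patch-grid shape.
#' @param D Embedding dimension; must be divisible by 4.
#' @return An N x D matrix, rows ordered row-major like [patchify()].
#' @export
positional_encoding <- function(rows, cols, D) {
  if (D %% 4 != 0) stop("positional encoding dimension must be divisible by 4")
  d4 <- D %/% 4
  omega <- 1 / (10000^((seq_len(d4) - 1) / d4))
  enc1d <- function(pos) {  # length(pos) x D/2
    ang <- outer(pos, omega)
    cbind(sin(ang), cos(ang))
  }
  gr <- expand.grid(col = seq_len(cols) - 1, row = seq_len(rows) - 1)
  # expand.grid varies col fastest -> row-major patch order
  cbind(enc1d(gr$row), enc1d(gr$col))
}

#' Sample a random patch mask
#'
#' Draws exactly `round(r * N)` (round-half-up) masked patch indices
#' uniformly without replacement from the active RNG stream.
#'
#' @param N Total number of patches.
#' @param r Mask ratio in (0, 1).
#' @return A list of class `mask_spec`: `n`, `r`, `masked_idx`,
#'   `visible_idx` (1-based, each sorted increasing).
#' @export
sample_mask <- function(N, r) {
  if (r <= 0 || r >= 1) stop("mask ratio must lie strictly in (0, 1)")
  if (N < 1) stop("N must be at least 1")
  m <- floor(r * N + 0.5)  # round half up; exact count is contractual
  if (m == 0 || m == N)
    stop("degenerate mask: round(r*N) = ", m, " of ", N, " patches")
  masked <- sort(sample.int(N, m))
  structure(list(n = N, r = r, masked_idx = masked,
                 visible_idx = setdiff(seq_len(N), masked)),
            class = "mask_spec")
}

# ---- augmentation -----------------------------------------------------------
# A sample is list(image = matrix, boxes = n x 4 matrix (x, y, w, h; 0-based),
# plus arbitrary passenger fields). Geometric ops transform boxes with pixels.

rot_cw_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]
rot_ccw_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

.aug_box <- function(boxes, op, W, H) {
  if (is.null(boxes) || nrow(boxes) == 0) return(boxes)
  b <- boxes
  out <- switch(op,
    hflip = { b[, 1] <- W - boxes[, 1] - boxes[, 3]; b },
    vflip = { b[, 2] <- H - boxes[, 2] - boxes[, 4]; b },
    rot90cw = cbind(H - (boxes[, 2] + boxes[, 4]), boxes[, 1],
                    boxes[, 4], boxes[, 3]),
    rot90ccw = cbind(boxes[, 2], W - (boxes[, 1] + boxes[, 3]),
                     boxes[, 4], boxes[, 3]),
    stop("unknown geometric op ", op))
  dimnames(out) <- dimnames(boxes)
  out
}

.aug_ops <- c("noise", "hflip", "vflip", "rot90cw", "rot90ccw")

#' Apply radiograph augmentations to an image + boxes sample
#'
#' Supported operations: pixel `noise` (a per-image fraction of pixels,
#' drawn uniformly in `[0, max_noise_frac]`, is replaced by uniform values
#' spanning the image intensity range), `hflip`, `vflip`, and clockwise /
#' counter-clockwise 90-degree rotation. Geometric operations transform the
#' annotation boxes consistently with the pixels. Each requested op fires
#' independently with probability `prob` using the active RNG stream.
#'
#' @param sample List with `image` (matrix) and optional `boxes` (n x 4).
#' @param ops Character vector, subset of
#'   `c("noise","hflip","vflip","rot90cw","rot90ccw")`.
#' @param prob Per-op application probability (set to 1 for deterministic
#'   application).
#' @param max_noise_frac Upper bound on the fraction of noised pixels.
#' @return The augmented sample (same structure).
#' @export
augment <- function(sample, ops, prob = 0.5, max_noise_frac = 0.06) {
  bad <- setdiff(ops, .aug_ops)
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  img <- sample$image; boxes <- sample$boxes
  for (op in ops) {
    if (stats::runif(1) > prob) next
    if (op == "noise") {
      f <- stats::runif(1, 0, max_noise_frac)
      npx <- floor(f * length(img))
      if (npx > 0) {
        pos <- sample.int(length(img), npx)
        rng <- range(img)
        img[pos] <- stats::runif(npx, rng[1], rng[2])
      }
    } else {
      H <- nrow(img); W <- ncol(img)
      boxes <- .aug_box(boxes, op, W, H)
      img <- switch(op,
        hflip = img[, W:1, drop = FALSE],
        vflip = img[H:1, , drop = FALSE],
        rot90cw = rot_cw_mat(img),
        rot90ccw = rot_ccw_mat(img))
    }
  }
  sample$image <- img; sample$boxes <- boxes
  sample
}
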