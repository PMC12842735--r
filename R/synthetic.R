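# Procedural generator of radiograph-like scenes containing vertically
# oriented screw-shaped implants composed of coronal / middle / apical
# parts. Rendering is additive intensity composition (implants are brighter
# than background, mimicking radiopacity) over a smoothed-noise background;
# no physics is modeled. Ground-truth part boxes are recomputed from the
# rendered pixel support, so annotations are exact by construction and the
# implant box is the tight union of its three part boxes.

# Design-class taxonomy (a representative, visually realized subset of the
# full implant-design classification) with default sampling weights shaped
# like the observed class imbalance: coronal bone:tissue:microthread:no-threads
# = 1240:870:410:208, middle parallel:tapered:v-shaped = 1935:621:382,
# apical hole-round:hole-oblong:apex-cone:apex-flat = 1710:545:364:188.
.design_classes <- list(
  coronal = c(bone_level = 1240, tissue_level = 870,
              microthread = 410, no_threads = 208),
  middle = c(parallel = 1935, tapered = 621, v_shaped = 382),
  apical = c(hole_round = 1710, hole_oblong = 545,
             apex_cone = 364, apex_flat = 188)
)

# Three synthetic implant systems with distinct geometry priors (height as a
# fraction of the image side, body aspect w/h, platform widening) so the
# system classes are separable from part widths alone.
.system_priors <- list(
  bego  = list(h_frac = c(0.62, 0.76), aspect = 0.20, platform = 1.20),
  bicon = list(h_frac = c(0.36, 0.46), aspect = 0.62, platform = 1.70),
  iti   = list(h_frac = c(0.50, 0.60), aspect = 0.38, platform = 1.35)
)

#' Names of the synthetic implant systems
#' @export
implant_systems <- function() names(.system_priors)

#' Names and default sampling weights of the rendered design classes
#' @return Named list with `coronal`, `middle`, `apical` weight vectors.
#' @export
design_taxonomy <- function() .design_classes

.wsample <- function(w) names(w)[sample.int(length(w), 1, prob = w / sum(w))]

#' Sample an implant template for a synthetic system
#'
#' Draws design-class attributes (coronal level/threading, middle body
#' shape, apical hole/apex shape) from configurable weights defaulting to
#' the taxonomy's observed class imbalance, and geometry from the system's
#' prior. Uses the active RNG stream; identical stream state yields an
#' identical template.
#'
#' @param system_class One of [implant_systems()].
#' @param image_size Image side in pixels (geometry scales with it).
#' @param weights Optional named list overriding the per-level class
#'   weights (same shape as [design_taxonomy()]).
#' @return A list of class `implant_template`.
#' @export
sample_template <- function(system_class, image_size = 64L, weights = NULL) {
  pr <- .system_priors[[system_class]]
  if (is.null(pr)) stop("unknown implant system class: ", system_class)
  w <- .design_classes
  if (!is.null(weights)) w[names(weights)] <- weights
  H <- max(12L, round(stats::runif(1, pr$h_frac[1], pr$h_frac[2]) * image_size))
  w_m <- max(5L, round(pr$aspect * H))
  w_c <- max(w_m + 2L, round(w_m * pr$platform))
  structure(list(
    system = system_class,
    coronal = .wsample(w$coronal),
    middle = .wsample(w$middle),
    apical = .wsample(w$apical),
    height = H, body_width = w_m, platform_width = w_c
  ), class = "implant_template")
}

# Render one template into a local canvas; returns intensity canvas plus a
# logical support mask per part. Local geometry: parts stacked vertically,
# coronal:middle:apical heights approximately 0.25 : 0.5 : 0.25.
render_template <- function(tpl) {
  H <- tpl$height; Wc <- tpl$platform_width; Wm <- tpl$body_width
  h_c <- max(3L, round(0.25 * H)); h_a <- max(3L, round(0.25 * H))
  h_m <- H - h_c - h_a
  W <- Wc
  canvas <- matrix(0, H, W)
  masks <- list(coronal = matrix(FALSE, H, W),
                middle = matrix(FALSE, H, W),
                apical = matrix(FALSE, H, W))
  cx <- (W + 1) / 2
  span <- function(width) {
    half <- width / 2
    lo <- max(1L, ceiling(cx - half)); hi <- min(W, floor(cx + half - 1e-9))
    lo:hi
  }
  # coronal: bright platform; tissue level carries a wider collar on top
  for (r in seq_len(h_c)) {
    wdt <- if (tpl$coronal == "tissue_level" && r <= ceiling(h_c * 0.4)) Wc
           else round(Wc * 0.9)
    cols <- span(wdt)
    val <- 0.70
    if (tpl$coronal == "microthread") val <- val + 0.10 * (r %% 2)
    if (tpl$coronal == "no_threads") val <- 0.72
    canvas[r, cols] <- val
    masks$coronal[r, cols] <- TRUE
  }
  # middle: threaded body, parallel or tapered profile
  taper_end <- if (tpl$middle == "tapered") 0.70 else 1.0
  band_period <- if (tpl$middle == "v_shaped") 4L else 3L
  band_amp <- if (tpl$middle == "v_shaped") 0.18 else 0.10
  for (i in seq_len(h_m)) {
    r <- h_c + i
    frac <- (i - 1) / max(1, h_m - 1)
    wdt <- round(Wm * (1 + (taper_end - 1) * frac))
    cols <- span(max(3L, wdt))
    val <- 0.55 + band_amp * ((i %/% band_period) %% 2 * 2 - 1) * 0.5
    canvas[r, cols] <- val
    masks$middle[r, cols] <- TRUE
  }
  # apical: taper to apex; optional dark hole
  w_top <- round(Wm * taper_end)
  w_tip <- if (tpl$apical == "apex_flat") max(3L, round(w_top * 0.6)) else 2L
  for (i in seq_len(h_a)) {
    r <- h_c + h_m + i
    frac <- (i - 1) / max(1, h_a - 1)
    wdt <- max(2L, round(w_top + (w_tip - w_top) * frac))
    cols <- span(wdt)
    canvas[r, cols] <- 0.55
    masks$apical[r, cols] <- TRUE
  }
  if (tpl$apical %in% c("hole_round", "hole_oblong")) {
    hy <- h_c + h_m + round(h_a * 0.35)
    rad_x <- max(1, round(w_top * 0.18))
    rad_y <- if (tpl$apical == "hole_oblong") max(2, round(h_a * 0.30)) else rad_x
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      if (((r - hy) / rad_y)^2 + ((cc - cx) / rad_x)^2 <= 1 && masks$apical[r, cc])
        canvas[r, cc] <- canvas[r, cc] - 0.35
    }
  }
  list(canvas = canvas, masks = masks)
}

.mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  # 0-based COCO box from 1-based matrix support
  c(x = min(idx[, 2]) - 1, y = min(idx[, 1]) - 1,
    w = diff(range(idx[, 2])) + 1, h = diff(range(idx[, 1])) + 1)
}

#' Specify a synthetic scene
#'
#' @param image_size Side length in pixels.
#' @param implants List of placements: each `list(template, x, y, rot)` with
#'   0-based top-left pixel position and rotation in `{0, 90, 180, 270}`.
#' @param noise Amplitude of per-pixel background noise.
#' @param patient_id Patient identifier attached to the scene.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size, implants, noise = 0.02,
                       patient_id = "pat0001") {
  structure(list(image_size = as.integer(image_size), implants = implants,
                 noise = noise, patient_id = patient_id),
            class = "scene_spec")
}

.smooth_background <- function(S, noise) {
  g <- 8L
  coarse <- matrix(stats::runif(g * g), g, g)
  xi <- seq(1, g, length.out = S)
  lo <- pmin(floor(xi), g - 1L); fr <- xi - lo
  up1 <- coarse[lo, , drop = FALSE] * (1 - fr) + coarse[lo + 1L, , drop = FALSE] * fr
  up <- up1[, lo, drop = FALSE] * rep(1 - fr, each = S) +
        up1[, lo + 1L, drop = FALSE] * rep(fr, each = S)
  bg <- 0.22 + 0.10 * up
  if (noise > 0) bg <- bg + matrix(stats::runif(S * S, -noise, noise), S, S)
  bg
}

.rotk <- function(m, rot) {
  k <- (rot %/% 90) %% 4
  for (i in seq_len(k)) m <- rot_cw_mat(m)
  m
}

#' Render a synthetic scene into an image plus exact annotations
#'
#' Implants are composed additively over a smoothed-noise background; each
#' rendered part contributes one annotation box equal to the bounding box of
#' its pixel support, and each implant contributes one box equal to the
#' tight union of its part boxes.
#'
#' @param spec A [scene_spec()].
#' @return list(image, parts, implants, patient_id): `parts` is a
#'   data.frame (x, y, w, h, level, class, system, implant), `implants` a
#'   data.frame (x, y, w, h, system).
#' @export
render_scene <- function(spec) {
  S <- spec$image_size
  img <- .smooth_background(S, spec$noise)
  parts <- list(); implants <- list()
  for (ii in seq_along(spec$implants)) {
    pl <- spec$implants[[ii]]
    rt <- render_template(pl$template)
    rot <- if (is.null(pl$rot)) 0 else pl$rot
    canvas <- .rotk(rt$canvas, rot)
    masks <- lapply(rt$masks, .rotk, rot = rot)
    h <- nrow(canvas); w <- ncol(canvas)
    x0 <- pl$x; y0 <- pl$y  # 0-based
    if (x0 < 0 || y0 < 0 || x0 + w > S || y0 + h > S)
      stop("placement error: implant ", ii, " (", w, "x", h,
           " at ", x0, ",", y0, ") outside ", S, "x", S, " image")
    rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
    img[rows, cols] <- img[rows, cols] + canvas
    boxes <- list()
    for (lv in names(masks)) {
      bb <- .mask_bbox(masks[[lv]])
      if (is.null(bb)) next
      boxes[[lv]] <- c(bb["x"] + x0, bb["y"] + y0, bb["w"], bb["h"])
      parts[[length(parts) + 1L]] <- data.frame(
        x = boxes[[lv]][1], y = boxes[[lv]][2],
        w = boxes[[lv]][3], h = boxes[[lv]][4],
        level = lv, class = paste0(lv, "_", pl$template[[lv]]),
        system = pl$template$system, implant = ii,
        stringsAsFactors = FALSE)
    }
    bm <- do.call(rbind, boxes)
    ux <- min(bm[, 1]); uy <- min(bm[, 2])
    implants[[length(implants) + 1L]] <- data.frame(
      x = ux, y = uy,
      w = max(bm[, 1] + bm[, 3]) - ux, h = max(bm[, 2] + bm[, 4]) - uy,
      system = pl$template$system, stringsAsFactors = FALSE)
  }
  list(image = pmin(pmax(img, 0), 1),
       parts = if (length(parts)) do.call(rbind, parts) else
         data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                    level = character(), class = character(),
                    system = character(), implant = integer()),
       implants = if (length(implants)) do.call(rbind, implants) else
         data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                    system = character()),
       patient_id = spec$patient_id)
}

.box_iou_xywh <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Draw a random scene: rejection-samples non-overlapping placements.
sample_scene <- function(image_size, n_implants, noise = 0.02,
                         patient_id = "pat0001", systems = implant_systems(),
                         rotations = 0, overlap_cap = 0.05) {
  placed <- list()
  for (i in seq_len(n_implants)) {
    ok <- FALSE
    for (try in seq_len(60)) {
      sys <- systems[sample.int(length(systems), 1)]
      tpl <- sample_template(sys, image_size)
      rot <- rotations[sample.int(length(rotations), 1)]
      hw <- c(tpl$height, tpl$platform_width)
      if (rot %% 180 != 0) hw <- rev(hw)
      if (hw[1] >= image_size || hw[2] >= image_size) next
      x <- sample.int(image_size - hw[2], 1) - 1L
      y <- sample.int(image_size - hw[1], 1) - 1L
      cand <- c(x, y, hw[2], hw[1])
      clash <- any(vapply(placed, function(p)
        .box_iou_xywh(cand, c(p$x, p$y, p$w, p$h)) > overlap_cap, logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <-
          list(template = tpl, x = x, y = y, rot = rot, w = hw[2], h = hw[1])
        ok <- TRUE
        break
      }
    }
    if (!ok) break  # scene is full; fewer implants than requested
  }
  scene_spec(image_size,
             lapply(placed, function(p) p[c("template", "x", "y", "rot")]),
             noise = noise, patient_id = patient_id)
}

.category_table <- function() {
  part_names <- unlist(lapply(names(.design_classes), function(lv)
    paste0(lv, "_", names(.design_classes[[lv]]))), use.names = FALSE)
  part_level <- rep(names(.design_classes), lengths(.design_classes))
  impl_names <- paste0("implant_", implant_systems())
  data.frame(id = seq_len(length(part_names) + length(impl_names)),
             name = c(part_names, impl_names),
             level = c(part_level, rep("implant", length(impl_names))),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic implant radiograph dataset
#'
#' Renders `n_images` random scenes, assigns patients in groups of
#' `images_per_patient` consecutive images, and returns (optionally writes)
#' a COCO-style index with part-level and implant-level annotations.
#' Deterministic under `seed`.
#'
#' @param n_images Number of images (>= 1).
#' @param seed Integer seed.
#' @param image_size Image side length.
#' @param n_implants_range Integer range `c(lo, hi)` of implants per scene.
#' @param images_per_patient Images contributed by each synthetic patient.
#' @param noise Background noise amplitude.
#' @param rotations Allowed implant rotations (degrees, multiples of 90).
#' @param out_dir If non-NULL, write PNG images and `annotations.json` here.
#' @return list(index (`coco_index`), images (list of matrices),
#'   scenes (list of rendered scenes)).
#' @export
generate_dataset <- function(n_images, seed = 1L, image_size = 64L,
                             n_implants_range = c(1L, 2L),
                             images_per_patient = 2L, noise = 0.02,
                             rotations = 0, out_dir = NULL) {
  if (n_images < 1) stop("n_images must be >= 1")
  cats <- .category_table()
  cat_id <- stats::setNames(cats$id, cats$name)
  imgs <- list(); anns <- list(); scenes <- list(); pix <- list()
  ann_id <- 0L
  with_substream(seed, "synthetic-data", function() {
    for (i in seq_len(n_images)) {
      pid <- sprintf("pat%04d", (i - 1L) %/% images_per_patient + 1L)
      k <- sample(seq(n_implants_range[1], n_implants_range[2]), 1)
      sc <- render_scene(sample_scene(image_size, k, noise = noise,
                                      patient_id = pid,
                                      rotations = rotations))
      scenes[[i]] <<- sc
      pix[[i]] <<- sc$image
      imgs[[i]] <<- data.frame(id = i, file_name = sprintf("img_%04d.png", i),
                               width = image_size, height = image_size,
                               patient_id = pid, stringsAsFactors = FALSE)
      if (nrow(sc$parts)) for (j in seq_len(nrow(sc$parts))) {
        ann_id <<- ann_id + 1L
        pr <- sc$parts[j, ]
        anns[[length(anns) + 1L]] <<- data.frame(
          id = ann_id, image_id = i, category_id = unname(cat_id[pr$class]),
          x = pr$x, y = pr$y, w = pr$w, h = pr$h,
          level = pr$level, system = pr$system, implant = pr$implant,
          stringsAsFactors = FALSE)
      }
      if (nrow(sc$implants)) for (j in seq_len(nrow(sc$implants))) {
        ann_id <<- ann_id + 1L
        im <- sc$implants[j, ]
        anns[[length(anns) + 1L]] <<- data.frame(
          id = ann_id, image_id = i,
          category_id = unname(cat_id[paste0("implant_", im$system)]),
          x = im$x, y = im$y, w = im$w, h = im$h,
          level = "implant", system = im$system, implant = j,
          stringsAsFactors = FALSE)
      }
    }
  })
  index <- new_coco_index(do.call(rbind, imgs),
                          if (length(anns)) do.call(rbind, anns) else
                            data.frame(id = integer(), image_id = integer(),
                                       category_id = integer(), x = numeric(),
                                       y = numeric(), w = numeric(),
                                       h = numeric()),
                          cats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      path <- file.path(out_dir, index$images$file_name[i])
      tryCatch(png::writePNG(pix[[i]], path),
               error = function(e) stop("failed writing ", path, ": ",
                                        conditionMessage(e)))
    }
    write_coco(index, file.path(out_dir, "annotations.json"))
  }
  list(index = index, images = pix, scenes = scenes)
}
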