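# Stage 2 of the two-stage pipeline: group scored part detections into
# implants (k-means on box centers with k-means++ seeding, at most 300 Lloyd
# iterations, several restarts), refine groups with spatial-consistency
# thresholds, infer missing parts along the implant axis, and emit one
# bounding box per implant.

#' Estimate the number of implants in an image from its part detections
#'
#' A complete implant contributes exactly one coronal part, so the coronal
#' count is the primary estimate; with no coronal detections the fallback is
#' `ceiling(n_parts / 3)`. (Taking the cluster count equal to the number of
#' part detections itself would yield only singleton clusters, so the count
#' is tied to implants instead; a `literal_k` mode selecting k = n_parts is
#' available in [assemble_implants()] for comparison.)
#'
#' @param dets data.frame of part detections with a `level` column.
#' @return Integer k with `0 <= k <= nrow(dets)`.
#' @export
estimate_implant_count <- function(dets) {
  n <- nrow(dets)
  if (n == 0) return(0L)
  k <- sum(dets$level == "coronal")
  if (k < 1) k <- ceiling(n / 3)
  as.integer(min(k, n))
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_seed <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(X, 1, function(p)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - p)^2)))
    if (sum(d2) <= 0) {
      centers[j, ] <- X[sample.int(n, 1), ] + stats::rnorm(ncol(X), 0, 1e-6)
    } else {
      centers[j, ] <- X[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

# Lloyd iterations via stats::kmeans on k-means++ seeds, best of `restarts`.
kmeanspp <- function(X, k, restarts = 10, iter_max = 300) {
  best <- NULL
  for (r in seq_len(restarts)) {
    seeds <- kmeanspp_seed(X, k)
    seeds <- seeds + matrix(stats::rnorm(length(seeds), 0, 1e-9),
                            nrow(seeds))  # guards duplicate seeds
    km <- tryCatch(
      stats::kmeans(X, centers = seeds, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) {
      km <- suppressWarnings(
        stats::kmeans(X, centers = seeds, iter.max = iter_max,
                      algorithm = "Lloyd"))
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Group part detections into implant candidates
#'
#' k-means with k-means++ seeding on box centers (at most 300 iterations,
#' best of `restarts` restarts under the active RNG stream), followed by
#' spatial-consistency refinement: within each group at most one member per
#' part level survives (highest score wins), and members whose center lies
#' farther from the group median center than `max_center_dist` (default 1.5x
#' the group's summed member-box height) are discarded with a logged reason.
#'
#' Part centers of one implant spread far along the implant axis (near
#' vertical in dental radiographs) while neighboring implants are separated
#' horizontally, so the vertical coordinate is down-weighted by
#' `axis_scale` before clustering. Set `axis_scale = 1` for isotropic
#' clustering (e.g. for rotated scenes).
#'
#' @param dets data.frame of part detections (x, y, w, h, level, score,
#'   optional system_hint).
#' @param k Number of groups, `1 <= k <= nrow(dets)`.
#' @param restarts k-means++ restarts (best objective wins).
#' @param max_center_dist Absolute distance cap; NULL for the adaptive
#'   default.
#' @param axis_scale Down-weighting of the along-axis coordinate during
#'   clustering (1 = isotropic).
#' @return List of `part_group` lists: `members` (data.frame), `axis` (unit
#'   2-vector), `completeness` (named logical), `discarded` (data.frame with
#'   `reason`).
#' @export
cluster_parts <- function(dets, k, restarts = 10, max_center_dist = NULL,
                          axis_scale = 0.25) {
  n <- nrow(dets)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of detections")
  cx <- dets$x + dets$w / 2; cy <- dets$y + dets$h / 2
  X <- cbind(cx, cy)
  if (n > 1 && axis_scale != 1) X <- cbind(cx, cy * axis_scale)
  if (k == n) {
    cl <- seq_len(n)
  } else if (k == 1) {
    cl <- rep(1L, n)
  } else {
    cl <- kmeanspp(X, k, restarts = restarts)$cluster
  }
  groups <- lapply(seq_len(k), function(g) {
    members <- dets[cl == g, , drop = FALSE]
    discarded <- members[0, , drop = FALSE]
    discarded$reason <- character(0)
    # one member per level: keep the highest score
    for (lv in unique(members$level)) {
      sub <- which(members$level == lv)
      if (length(sub) > 1) {
        drop <- sub[-which.max(members$score[sub])]
        d2 <- members[drop, , drop = FALSE]; d2$reason <- "duplicate-level"
        discarded <- rbind(discarded, d2)
        members <- members[-drop, , drop = FALSE]
      }
    }
    # distance consistency around the group median center
    if (nrow(members) > 1) {
      mx <- stats::median(members$x + members$w / 2)
      my <- stats::median(members$y + members$h / 2)
      cap <- if (is.null(max_center_dist)) 1.5 * sum(members$h)
             else max_center_dist
      dist <- sqrt((members$x + members$w / 2 - mx)^2 +
                     (members$y + members$h / 2 - my)^2)
      bad <- which(dist > cap)
      if (length(bad)) {
        d2 <- members[bad, , drop = FALSE]; d2$reason <- "center-distance"
        discarded <- rbind(discarded, d2)
        members <- members[-bad, , drop = FALSE]
      }
    }
    axis <- c(0, 1)
    if (nrow(members) > 1) {
      ctr <- cbind(members$x + members$w / 2, members$y + members$h / 2)
      cc <- sweep(ctr, 2, colMeans(ctr))
      ev <- eigen(crossprod(cc), symmetric = TRUE)
      axis <- ev$vectors[, 1]
      if (axis[2] < 0) axis <- -axis
    }
    structure(list(members = members, axis = axis,
                   completeness = stats::setNames(
                     .part_levels %in% members$level, .part_levels),
                   discarded = discarded),
              class = "part_group")
  })
  groups
}

.along <- function(group) {
  # dominant axis: "v" (vertical) or "h" (horizontal)
  if (abs(group$axis[2]) >= abs(group$axis[1])) "v" else "h"
}

.extent <- function(box, ax) {
  if (ax == "v") c(box[2], box[2] + box[4]) else c(box[1], box[1] + box[3])
}
.cross_span <- function(m, ax) {
  if (ax == "v") c(min(m$x), max(m$x + m$w)) else c(min(m$y), max(m$y + m$h))
}

#' Infer the box of a missing part level within a group
#'
#' The estimate is placed along the implant axis (coronal above middle above
#' apical in image coordinates; the rotated analogue along a horizontal
#' axis). A missing middle with both neighbors present is positioned by
#' linear interpolation between them; a missing end part is extrapolated
#' from the middle's extent scaled by the default coronal:middle:apical
#' height ratio `rho` (0.25 : 0.5 : 0.25 of the implant extent).
#'
#' @param group A `part_group` missing exactly `level`.
#' @param level The missing level (`"coronal"`, `"middle"`, `"apical"`).
#' @param rho Named height ratios of the three levels.
#' @return Numeric box (x, y, w, h) with attribute `inferred = TRUE`.
#' @export
infer_missing_part <- function(group, level,
                               rho = c(coronal = 0.25, middle = 0.5,
                                       apical = 0.25)) {
  m <- group$members
  if (!nrow(m)) stop("cannot infer a part from an empty group")
  if (level %in% m$level) stop("level ", level, " is not missing")
  ax <- .along(group)
  cs <- .cross_span(m, ax)
  get <- function(lv) {
    i <- which(m$level == lv)
    if (!length(i)) return(NULL)
    as.numeric(m[i[1], c("x", "y", "w", "h")])
  }
  boxes <- list(coronal = get("coronal"), middle = get("middle"),
                apical = get("apical"))
  mk <- function(a0, a1, c0, c1) {
    b <- if (ax == "v") c(c0, a0, c1 - c0, a1 - a0)
         else c(a0, c0, a1 - a0, c1 - c0)
    attr(b, "inferred") <- TRUE
    b
  }
  if (level == "middle" && !is.null(boxes$coronal) && !is.null(boxes$apical)) {
    e1 <- .extent(boxes$coronal, ax); e2 <- .extent(boxes$apical, ax)
    lo <- min(e1[2], e2[2]); hi <- max(e1[1], e2[1])
    if (e1[1] <= e2[1]) { lo <- e1[2]; hi <- e2[1] } else { lo <- e2[2]; hi <- e1[1] }
    return(mk(lo, hi, cs[1], cs[2]))
  }
  # extrapolation from the neighbor closest to the missing level
  ref <- if (!is.null(boxes$middle)) boxes$middle
         else if (level == "coronal") boxes$apical else boxes$coronal
  ref_lv <- if (!is.null(boxes$middle)) "middle"
            else if (level == "coronal") "apical" else "coronal"
  er <- .extent(ref, ax)
  len <- (er[2] - er[1]) * rho[[level]] / rho[[ref_lv]]
  # orientation along the axis: coronal sits at the low-coordinate end when
  # the coronal (or the middle-to-apical direction) says so
  low_end <- TRUE  # does the coronal sit at the low-coordinate end?
  if (!is.null(boxes$coronal) && !is.null(boxes$middle))
    low_end <- mean(.extent(boxes$coronal, ax)) < mean(.extent(boxes$middle, ax))
  else if (!is.null(boxes$middle) && !is.null(boxes$apical))
    low_end <- mean(.extent(boxes$middle, ax)) < mean(.extent(boxes$apical, ax))
  else if (!is.null(boxes$coronal) && !is.null(boxes$apical))
    low_end <- mean(.extent(boxes$coronal, ax)) < mean(.extent(boxes$apical, ax))
  before <- (level == "coronal") == low_end
  if (before) mk(er[1] - len, er[1], cs[1], cs[2])
  else mk(er[2], er[2] + len, cs[1], cs[2])
}

#' Assemble one implant detection per part group
#'
#' The implant box is the tight union of member (and inferred) part boxes;
#' the score is the mean member score; the system class is chosen by the
#' highest total score among the members' system hints (ties broken by the
#' highest single hint score).
#'
#' @param groups List of `part_group`s, optionally completed by
#'   [infer_missing_part()] boxes stored in `group$inferred`.
#' @return data.frame (x, y, w, h, system, score, n_members, n_inferred,
#'   member_ids).
#' @export
assemble_implant_boxes <- function(groups) {
  rows <- lapply(groups, function(g) {
    m <- g$members
    if (!nrow(m)) return(NULL)
    boxes <- as.matrix(m[, c("x", "y", "w", "h")])
    if (!is.null(g$inferred) && length(g$inferred))
      boxes <- rbind(boxes, do.call(rbind, g$inferred))
    x <- min(boxes[, 1]); y <- min(boxes[, 2])
    w <- max(boxes[, 1] + boxes[, 3]) - x
    h <- max(boxes[, 2] + boxes[, 4]) - y
    sys <- NA_character_
    if (!is.null(m$system_hint)) {
      tot <- tapply(m$score, m$system_hint, sum)
      cand <- names(tot)[tot == max(tot)]
      if (length(cand) > 1) {
        mx <- tapply(m$score, m$system_hint, max)[cand]
        cand <- cand[which.max(mx)]
      }
      sys <- cand[1]
    }
    data.frame(x = x, y = y, w = w, h = h, system = sys,
               score = mean(m$score), n_members = nrow(m),
               n_inferred = length(g$inferred %||% list()),
               member_ids = paste(rownames(m), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), system = character(), score = numeric(),
                      n_members = integer(), n_inferred = integer(),
                      member_ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full stage-2 assembly: parts in, implant boxes out
#'
#' Estimates the implant count, clusters the part detections, infers missing
#' part levels, and assembles implant boxes. Groups reduced below two part
#' levels by consistency discards are dropped; untouched single-part groups
#' are kept.
#'
#' @param dets data.frame of part detections (x, y, w, h, level, score,
#'   optional system_hint).
#' @param literal_k Use k = number of detections (the literal clustering
#'   rule) instead of the implant-count estimate.
#' @param infer_missing Infer boxes for missing part levels before assembly.
#' @param ... Passed to [cluster_parts()].
#' @return data.frame as from [assemble_implant_boxes()].
#' @export
assemble_implants <- function(dets, literal_k = FALSE, infer_missing = TRUE,
                              ...) {
  if (is.null(dets) || nrow(dets) == 0)
    return(assemble_implant_boxes(list()))
  k <- if (literal_k) nrow(dets) else estimate_implant_count(dets)
  if (k == 0) return(assemble_implant_boxes(list()))
  groups <- cluster_parts(dets, k, ...)
  keep <- vapply(groups, function(g) {
    nlev <- sum(g$completeness)
    nlev >= 2 || nrow(g$discarded) == 0
  }, logical(1))
  groups <- groups[keep]
  if (infer_missing) {
    groups <- lapply(groups, function(g) {
      missing <- .part_levels[!g$completeness]
      if (length(missing) && nrow(g$members) >= 1 && sum(g$completeness) >= 1 &&
          length(missing) < 3) {
        g$inferred <- lapply(missing, function(lv) {
          tryCatch(infer_missing_part(g, lv), error = function(e) NULL)
        })
        g$inferred <- g$inferred[!vapply(g$inferred, is.null, logical(1))]
      }
      g
    })
  }
  assemble_implant_boxes(groups)
}
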