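mk_parts <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(x = r[[1]], y = r[[2]], w = r[[3]], h = r[[4]],
               level = r[[5]], score = r[[6]],
               system_hint = if (length(r) > 6) r[[7]] else "bego",
               stringsAsFactors = FALSE)))
}

test_that("implant count estimation follows the coronal rule with fallback", {
  d3 <- mk_parts(list(0, 0, 5, 5, "coronal", .9), list(0, 6, 5, 5, "middle", .9),
                 list(0, 12, 5, 5, "apical", .9))
  expect_equal(estimate_implant_count(d3), 1L)
  d6 <- rbind(d3, within(d3, x <- x + 50))
  expect_equal(estimate_implant_count(d6), 2L)
  d4 <- mk_parts(list(0, 0, 5, 5, "middle", .9), list(0, 6, 5, 5, "middle", .9),
                 list(50, 0, 5, 5, "apical", .9), list(50, 6, 5, 5, "apical", .9))
  expect_equal(estimate_implant_count(d4), 2L)  # ceiling(4/3)
  expect_equal(estimate_implant_count(d3[0, ]), 0L)
})

test_that("clustering recovers well-separated implants and handles degenerate k", {
  set.seed(80)
  two <- mk_parts(
    list(10, 10, 10, 8, "coronal", .9), list(11, 20, 8, 16, "middle", .8),
    list(12, 38, 6, 8, "apical", .7),
    list(210, 12, 10, 8, "coronal", .95), list(211, 22, 8, 16, "middle", .85),
    list(212, 40, 6, 8, "apical", .75))
  gr <- cluster_parts(two, 2)
  sizes <- sort(vapply(gr, function(g) nrow(g$members), integer(1)))
  expect_equal(sizes, c(3L, 3L))
  xs <- vapply(gr, function(g) mean(g$members$x), numeric(1))
  expect_equal(sort(round(xs / 100)), c(0, 2))
  # singleton groups at k = n
  gr2 <- cluster_parts(two, 6)
  expect_true(all(vapply(gr2, function(g) nrow(g$members), integer(1)) == 1))
  expect_error(cluster_parts(two, 7), "k must satisfy")
})

test_that("k-means++ objective beats random assignments on small instances", {
  set.seed(81)
  withinss <- function(X, cl) {
    sum(vapply(unique(cl), function(g) {
      sub <- X[cl == g, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  for (trial in 1:5) {
    n <- 8
    X <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    dets <- data.frame(x = X[, 1] - 2, y = X[, 2] - 2, w = 4, h = 4,
                       level = "middle", score = 1, system_hint = "iti")
    km <- mdeimplant:::kmeanspp(cbind(X[, 1], X[, 2] * 0.25), 3)
    obj <- km$tot.withinss
    Xs <- cbind(X[, 1], X[, 2] * 0.25)
    rand_best <- min(replicate(1000, withinss(Xs, sample(1:3, n, TRUE))),
                     na.rm = TRUE)
    expect_lte(obj, rand_best + 1e-9)
    # exhaustive best 3-partition for n = 8
    parts <- expand.grid(rep(list(1:3), n))
    exact <- min(apply(parts, 1, function(cl) withinss(Xs, cl)))
    expect_lte(exact, obj + 1e-9)
    expect_lt(obj, exact * 1.5 + 1e-9)  # k-means++ with restarts is near-exact
  }
})

test_that("missing-middle interpolation spans the gap between neighbors", {
  g <- structure(list(
    members = mk_parts(list(12, 10, 16, 30, "coronal", .9),
                       list(14, 100, 12, 30, "apical", .8)),
    axis = c(0, 1),
    completeness = c(coronal = TRUE, middle = FALSE, apical = TRUE),
    discarded = NULL), class = "part_group")
  b <- infer_missing_part(g, "middle")
  expect_equal(b[2], 40, tolerance = 2)           # top at coronal bottom
  expect_equal(b[2] + b[4], 100, tolerance = 2)   # bottom at apical top
  expect_true(attr(b, "inferred"))
  expect_error(infer_missing_part(g, "coronal"), "not missing")
})

test_that("missing end parts are extrapolated along the axis with the height ratio", {
  g <- structure(list(
    members = mk_parts(list(10, 40, 12, 40, "middle", .9)),
    axis = c(0, 1),
    completeness = c(coronal = FALSE, middle = TRUE, apical = FALSE),
    discarded = NULL), class = "part_group")
  ba <- infer_missing_part(g, "apical")
  expect_equal(ba[2], 80)          # directly below the middle
  expect_equal(ba[4], 40 * 0.25 / 0.5)  # height ratio rho_a / rho_m
  bc <- infer_missing_part(g, "coronal")
  expect_equal(bc[2] + bc[4], 40)  # directly above the middle
})

test_that("inference follows a rotated (horizontal) implant axis", {
  g <- structure(list(
    members = mk_parts(list(10, 20, 30, 14, "coronal", .9),
                       list(90, 21, 28, 13, "apical", .8)),
    axis = c(1, 0),
    completeness = c(coronal = TRUE, middle = FALSE, apical = TRUE),
    discarded = NULL), class = "part_group")
  b <- infer_missing_part(g, "middle")
  expect_equal(b[1], 40, tolerance = 2)        # left at coronal right edge
  expect_equal(b[1] + b[3], 90, tolerance = 2) # right at apical left edge
})

test_that("implant boxes are tight unions with mean scores and score-voted systems", {
  g <- structure(list(
    members = mk_parts(list(10, 10, 20, 30, "coronal", 0.9, "bego"),
                       list(12, 40, 16, 50, "middle", 0.6, "iti"),
                       list(14, 90, 12, 20, "apical", 0.6, "iti")),
    axis = c(0, 1),
    completeness = c(coronal = TRUE, middle = TRUE, apical = TRUE),
    discarded = NULL), class = "part_group")
  out <- assemble_implant_boxes(list(g))
  expect_equal(as.numeric(out[1, c("x", "y", "w", "h")]), c(10, 10, 20, 100))
  expect_equal(out$score, mean(c(0.9, 0.6, 0.6)))
  expect_identical(out$system, "iti")  # total score 1.2 beats 0.9
  # single-member group: implant box equals the member box
  g1 <- g; g1$members <- g$members[1, ]; g1$inferred <- NULL
  out1 <- assemble_implant_boxes(list(g1))
  expect_equal(as.numeric(out1[1, c("x", "y", "w", "h")]), c(10, 10, 20, 30))
})

test_that("assembly satisfies containment, conservation and permutation invariance", {
  data <- generate_dataset(6, seed = 55L, image_size = 416L,
                           n_implants_range = c(2L, 3L))
  set.seed(56)
  parts <- oracle_part_detections(data$index)
  for (iid in unique(parts$image_id)) {
    p <- parts[parts$image_id == iid, , drop = FALSE]
    k <- estimate_implant_count(p)
    groups <- with_substream(1L, "grp", function() cluster_parts(p, k))
    # conservation: every detection is a member of exactly one group or was
    # discarded with a reason
    got <- sum(vapply(groups, function(g)
      nrow(g$members) + nrow(g$discarded), integer(1)))
    expect_equal(got, nrow(p))
    imp <- with_substream(1L, "grp", function() assemble_implants(p))
    # containment of members in the assembled box
    for (g in groups) {
      gb <- c(min(g$members$x), min(g$members$y))
      hit <- which(abs(imp$x - gb[1]) < 20 & abs(imp$y - gb[2]) < 20)
      if (length(hit) == 1) {
        ib <- as.numeric(imp[hit, c("x", "y", "w", "h")])
        expect_true(all(g$members$x >= ib[1] - 1e-9 &
                        g$members$y >= ib[2] - 1e-9 &
                        g$members$x + g$members$w <= ib[1] + ib[3] + 1e-9 &
                        g$members$y + g$members$h <= ib[2] + ib[4] + 1e-9))
      }
    }
    # permutation invariance
    perm <- sample(nrow(p))
    imp2 <- with_substream(1L, "grp", function()
      assemble_implants(p[perm, , drop = FALSE]))
    o1 <- imp[order(imp$x, imp$y), c("x", "y", "w", "h", "system")]
    o2 <- imp2[order(imp2$x, imp2$y), c("x", "y", "w", "h", "system")]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2)
  }
})

test_that("literal clustering mode produces singleton-cluster boxes", {
  two <- mk_parts(
    list(10, 10, 10, 8, "coronal", .9), list(11, 20, 8, 16, "middle", .8),
    list(12, 38, 6, 8, "apical", .7))
  set.seed(2)
  imp <- assemble_implants(two, literal_k = TRUE, infer_missing = FALSE)
  expect_equal(nrow(imp), 3)
})
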