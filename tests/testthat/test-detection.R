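test_that("feature pyramid shapes and token-to-cell mapping are exact", {
  cfg <- tiny_cfg()  # 64x64, P=8
  det <- part_detector(cfg, c("coronal", "middle", "apical"))
  img <- random_image(64, seed = 70)
  pyr <- build_feature_pyramid(det, img)
  expect_named(pyr, c("s4", "s8", "s16", "s32"))
  expect_equal(dim(pyr$s4)[1:2], c(16, 16))
  expect_equal(dim(pyr$s8)[1:2], c(8, 8))
  expect_equal(dim(pyr$s16)[1:2], c(4, 4))
  expect_equal(dim(pyr$s32)[1:2], c(2, 2))
  # index oracle at the native stride: token k -> cell (k %/% cols, k %% cols)
  bb <- mdeimplant:::backbone_fwd(det, img)
  lat <- det$params$fpn[[2]]
  proj <- sweep(bb$tokens %*% lat$W, 2, lat$b, `+`)
  for (k in c(1, 9, 37, 64)) {
    r <- (k - 1) %/% 8 + 1; cc <- (k - 1) %% 8 + 1
    expect_equal(pyr$s8[r, cc, ], proj[k, ], tolerance = 1e-12)
  }
  # 416x416 / P=16 -> 26x26 native map
  cfg2 <- run_config(seed = 1, enc_depth = 0L, d_enc = 16L, enc_heads = 4L,
                     d_dec = 16L, dec_depth = 0L, dec_heads = 4L)
  det2 <- part_detector(cfg2, "part")
  pyr2 <- build_feature_pyramid(det2, matrix(0.5, 416, 416))
  expect_equal(dim(pyr2$s16)[1:2], c(26, 26))
})

test_that("focal loss has the advertised closed forms and reduces to cross-entropy", {
  # gamma=0, unit weights, p_true=0.5 binary -> ln 2
  lg <- matrix(c(0, 0), 1)
  expect_equal(focal_loss(lg, 1L, gamma = 0), log(2), tolerance = 1e-12)
  # perfectly confident correct prediction -> loss -> 0
  expect_lt(focal_loss(matrix(c(50, 0), 1), 1L, gamma = 2), 1e-12)
  # gamma=2 elementwise oracle
  p <- 0.9
  lo <- matrix(c(log(p), log(1 - p)), 1)
  expect_equal(focal_loss(lo, 1L, gamma = 2), -(1 - p)^2 * log(p),
               tolerance = 1e-9)
  # reduction to weighted cross-entropy on random logits
  set.seed(71)
  L <- matrix(rnorm(40 * 5), 40)
  y <- sample(1:5, 40, replace = TRUE)
  w <- runif(5, 0.5, 2)
  pr <- exp(L - apply(L, 1, max)); pr <- pr / rowSums(pr)
  ce <- mean(-w[y] * log(pr[cbind(1:40, y)]))
  expect_lt(abs(focal_loss(L, y, gamma = 0, class_weights = w) - ce), 1e-7)
  # strictly decreasing in the true-class probability
  f <- vapply(seq(-2, 2, by = 0.5), function(z)
    focal_loss(matrix(c(z, 0), 1), 1L, gamma = 2), numeric(1))
  expect_true(all(diff(f) < 0))
  # analytic gradient matches finite differences
  gan <- mdeimplant:::focal_grad(L, y, gamma = 2, class_weights = w)
  eps <- 1e-6
  for (idx in c(1, 57, 200)) {
    Lp <- L; Lp[idx] <- L[idx] + eps
    Lm <- L; Lm[idx] <- L[idx] - eps
    num <- (focal_loss(Lp, y, 2, w) - focal_loss(Lm, y, 2, w)) / (2 * eps)
    expect_lt(abs(num - gan[idx]), 1e-6)
  }
  expect_error(focal_loss(L, y, gamma = -1), "non-negative")
})

test_that("NMS matches a brute-force reference and is idempotent", {
  set.seed(72)
  ref_nms <- function(boxes, scores, thr) {
    ord <- order(scores, decreasing = TRUE)
    keep <- logical(length(scores))
    for (i in ord) {
      ok <- TRUE
      for (j in which(keep)) {
        if (iou(boxes[i, ], boxes[j, ]) > thr &&
            scores[j] >= scores[i]) ok <- FALSE
      }
      if (ok) keep[i] <- TRUE
    }
    which(keep)
  }
  # two identical boxes, scores 0.9/0.8 -> only the 0.9 box survives
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_identical(nms_boxes(b, c(0.9, 0.8), 0.5), 1L)
  for (trial in 1:30) {
    n <- sample(3:12, 1)
    boxes <- cbind(runif(n, 0, 50), runif(n, 0, 50),
                   runif(n, 5, 25), runif(n, 5, 25))
    sc <- runif(n)
    k1 <- nms_boxes(boxes, sc, 0.5)
    expect_setequal(k1, ref_nms(boxes, sc, 0.5))
    # idempotence
    k2 <- k1[nms_boxes(boxes[k1, , drop = FALSE], sc[k1], 0.5)]
    expect_identical(sort(k2), sort(k1))
  }
})

test_that("target assignment follows the inside-box rule with smallest-box ties", {
  boxes <- rbind(c(8, 8, 32, 32), c(16, 16, 8, 8))  # nested boxes
  tg <- mdeimplant:::assign_targets(8, 8, 8, boxes, c(1L, 2L), c(1L, 1L))
  # cell (row 2, col 2) center = (20, 20): inside both, smaller box wins
  k <- 2 * 8 + 2 + 1
  expect_equal(tg$labels[k], 3L)  # class 2 + background offset
  # cell (0,0) center (4,4): background
  expect_equal(tg$labels[1], 1L)
  # box target reconstructs the ground-truth box exactly
  t <- tg$tbox[k, ]
  cx <- 20; cy <- 20
  expect_equal(cx + t[1] * 8 - exp(t[3]) * 8 / 2, 16)
  expect_equal(cy + t[2] * 8 - exp(t[4]) * 8 / 2, 16)
})

test_that("zero-epoch fine-tuning returns the initialized detector", {
  data <- micro_dataset()
  cfg <- tiny_cfg()
  det0 <- run_finetune(data, cfg, epochs = 0)
  ref <- part_detector(cfg, c("coronal", "middle", "apical"))
  expect_identical(det0$params$tok$W, ref$params$tok$W)
  expect_identical(det0$params$head$Wc, ref$params$head$Wc)
})

test_that("detections depend on the checkpoint only through its weights", {
  data <- micro_dataset()
  cfg <- tiny_cfg(batch_size = 4L, base_lr = 2e-3)
  det1 <- run_finetune(data, cfg, epochs = 2)
  det2 <- run_finetune(data, cfg, epochs = 2)
  expect_identical(det1$params$head$Wc, det2$params$head$Wc)
  d1 <- predict_parts(det1, data$images[[1]], score_thresh = 0.05)
  d2 <- predict_parts(det2, data$images[[1]], score_thresh = 0.05)
  expect_identical(d1, d2)
  # blank background with a high threshold -> empty detection list
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(predict_parts(det1, blank, score_thresh = 0.999)), 0)
})

test_that("fine-tuning accepts a pre-trained encoder and validates shapes", {
  data <- micro_dataset()
  cfg <- tiny_cfg(batch_size = 4L)
  pk <- run_pretraining(data$images[1:4], cfg, "mde", epochs = 1)
  enc <- export_encoder_checkpoint(pk)
  det <- run_finetune(data, cfg, encoder_ckpt = enc, epochs = 1)
  expect_s3_class(det, "part_detector")
  bad <- enc; bad$tok$W <- bad$tok$W[1:10, ]
  expect_error(part_detector(cfg, "p", encoder_ckpt = bad), "mismatch")
})
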