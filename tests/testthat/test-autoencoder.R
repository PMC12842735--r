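test_that("patch embedding matches an explicit affine oracle", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  g <- patchify(random_image(16, seed = 2), 4)
  E <- embed_patches(g$patches, model)
  expect_equal(dim(E), c(16L, cfg$d_enc))
  # single-patch oracle: plain matrix product plus bias
  for (k in c(1, 7, 16)) {
    oracle <- as.numeric(g$patches[k, , drop = FALSE] %*%
                           model$params$tok$W) + model$params$tok$b
    expect_equal(as.numeric(E[k, ]), oracle, tolerance = 1e-6)
  }
  # zero patches, zero bias -> zero embeddings
  m0 <- model; m0$params$tok$b <- rep(0, cfg$d_enc)
  expect_equal(embed_patches(matrix(0, 3, 16), m0), matrix(0, 3, cfg$d_enc))
  expect_error(embed_patches(matrix(0, 3, 9), model), "does not match")
})

test_that("the encoder sees only visible tokens and is permutation consistent", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  set.seed(3)
  x <- matrix(rnorm(12 * cfg$d_enc), 12)
  y <- encode_visible(x, model)
  expect_equal(nrow(y), 12)
  perm <- sample(12)
  y2 <- encode_visible(x[perm, ], model)
  expect_equal(y2, y[perm, ], tolerance = 1e-5)
  # depth-0 encoder is the identity
  cfg0 <- micro_cfg(enc_depth = 0L)
  m0 <- mde_model(cfg0)
  expect_identical(encode_visible(x, m0), x)
})

test_that("perturbing a masked patch never changes encoder output (exhaustive N=16)", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  img <- random_image(16, seed = 4)
  set.seed(8)
  mask <- sample_mask(16, 0.25)
  enc_out <- function(im) {
    g <- patchify(im, 4)
    E <- embed_patches(g$patches, model)
    encode_visible(E[mask$visible_idx, ] +
                     model$pos_enc[mask$visible_idx, ], model)
  }
  base <- enc_out(img)
  P <- 4
  for (k in seq_len(16)) {
    im2 <- img
    r0 <- ((k - 1) %/% 4) * P; c0 <- ((k - 1) %% 4) * P
    im2[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P)] <-
      1 - im2[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P)]
    out <- enc_out(im2)
    if (k %in% mask$masked_idx) {
      expect_identical(out, base, info = paste("masked patch", k))
    } else {
      expect_gt(max(abs(out - base)), 0, label = paste("visible patch", k))
    }
  }
})

test_that("decoder input restores original patch order with the mask token in masked slots", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  # exhaustive order-restoration check for all single-masked positions, N=4
  latents <- matrix(rnorm(3 * cfg$d_enc), 3)
  for (mi in 1:4) {
    mask <- structure(list(n = 4L, r = 0.25, masked_idx = mi,
                           visible_idx = setdiff(1:4, mi)),
                      class = "mask_spec")
    ec <- assemble_decoder_input(latents, mask, model)
    expect_equal(dim(ec), c(4L, cfg$d_dec))
    expect_equal(as.numeric(ec[mi, ]),
                 model$params$emask + model$pos_dec[mi, ])
    proj <- sweep(latents %*% model$params$proj$W, 2,
                  model$params$proj$b, `+`)
    expect_equal(ec[mask$visible_idx, ],
                 proj + model$pos_dec[mask$visible_idx, ],
                 ignore_attr = TRUE)
  }
  expect_error(assemble_decoder_input(latents[1:2, ],
    structure(list(n = 4L, masked_idx = 1L, visible_idx = 2:4),
              class = "mask_spec"), model), "does not match")
})

test_that("decoder outputs have contract shape and depth-0 is the identity", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  ec <- matrix(rnorm(16 * cfg$d_dec), 16)
  out <- decode(ec, model)
  expect_equal(dim(out), c(16L, cfg$d_dec))
  expect_identical(decode(ec, model), out)  # bit-stable repetition
  m0 <- mde_model(micro_cfg(dec_depth = 0L))
  expect_identical(decode(ec, m0), ec)
  expect_error(decode(ec[, 1:3], model), "width mismatch")
})

test_that("prediction heads return masked positions only, matching a gather oracle", {
  cfg <- micro_cfg()
  set.seed(9)
  mask <- sample_mask(16, 0.25)
  dec_out <- matrix(rnorm(16 * cfg$d_dec), 16)
  emb <- mde_model(cfg, head = "embedding")
  pe <- predict_targets(dec_out, mask, emb)
  expect_equal(dim(pe), c(length(mask$masked_idx), cfg$d_enc))
  px <- mde_model(cfg, head = "pixel")
  pp <- predict_targets(dec_out, mask, px)
  expect_equal(ncol(pp), 16L)  # P^2 pixel values
  # gather oracle: row i of the output is head(dec_out[masked_idx[i], ])
  for (i in seq_along(mask$masked_idx)) {
    k <- mask$masked_idx[i]
    oracle <- as.numeric(dec_out[k, , drop = FALSE] %*%
                           emb$params$head$W) + emb$params$head$b
    expect_equal(as.numeric(pe[i, ]), oracle, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences on a micro model", {
  cfg <- micro_cfg()
  model <- mde_model(cfg)
  img <- random_image(16, seed = 12)
  set.seed(13); mask <- sample_mask(16, 0.25)
  eps <- 1e-5
  check_leaf <- function(path, objective, detach) {
    st <- mdeimplant:::mde_step(model, img, mask, objective,
                                want_grads = TRUE, detach_target = detach)
    get_leaf <- function(m) Reduce(function(a, b) a[[b]], path, m$params)
    ana <- Reduce(function(a, b) a[[b]], path, st$grads)
    v <- get_leaf(model)
    for (i in c(1, length(v))) {
      mp <- model; leaf <- get_leaf(mp)
      leaf[i] <- v[i] + eps
      mp$params <- .set_leaf(mp$params, path, leaf)
      lp <- mdeimplant:::mde_step(mp, img, mask, objective,
                                  want_grads = FALSE,
                                  detach_target = detach)$loss
      leaf[i] <- v[i] - eps
      mp$params <- .set_leaf(mp$params, path, leaf)
      lm <- mdeimplant:::mde_step(mp, img, mask, objective,
                                  want_grads = FALSE,
                                  detach_target = detach)$loss
      num <- (lp - lm) / (2 * eps)
      expect_true(abs(num - ana[i]) < 1e-6 + 1e-4 * abs(num),
                  label = paste(objective, paste(path, collapse = "$"), i))
    }
  }
  .set_leaf <- function(params, path, value) {
    if (length(path) == 1) { params[[path[[1]]]] <- value; return(params) }
    params[[path[[1]]]] <- .set_leaf(params[[path[[1]]]], path[-1], value)
    params
  }
  for (p in list(list("head", "W"), list("proj", "W"), list("emask"),
                 list("enc", "blocks", 1L, "attn", "Wq"),
                 list("dec", "blocks", 1L, "mlp", "W1")))
    check_leaf(p, "mde", TRUE)
  check_leaf(list("tok", "W"), "mde", FALSE)
  model <- mde_model(cfg, head = "pixel")
  check_leaf(list("tok", "W"), "mae", TRUE)
})

test_that("exported encoder checkpoints contain no decoder or head parameters", {
  cfg <- micro_cfg()
  data <- list(random_image(16, seed = 20), random_image(16, seed = 21))
  ck <- run_pretraining(data, cfg, "mde", epochs = 2)
  enc <- export_encoder_checkpoint(ck)
  expect_setequal(setdiff(names(enc), c("cfg", "schema")), c("tok", "enc"))
  flat <- unlist(enc[c("tok", "enc")], recursive = TRUE)
  expect_false(any(grepl("(^|\\.)(head|emask|emask_enc|proj|dec)(\\.|$|[0-9])",
                         names(flat))))
})

test_that("reconstruction visualization is exact in its degenerate limits", {
  cfg <- micro_cfg()
  img <- random_image(16, seed = 30)
  # pixel head with perfect predictions: force head to reproduce targets is
  # impractical; instead check the no-mask limit and the pinv roundtrip
  emb <- mde_model(cfg, head = "embedding")
  vz <- visualize_reconstruction(emb, img, mask = NULL)
  expect_equal(vz$image, img)
  # pseudo-inverse roundtrip on a full-column-rank affine tokenizer
  g <- patchify(img, 4)
  # the 16 -> 8 dim tokenizer is not invertible; use a rank-preserving map
  cfg2 <- micro_cfg(d_enc = 16L, enc_heads = 4L)
  emb2 <- mde_model(cfg2)
  E2 <- embed_patches(g$patches, emb2)
  back <- sweep(E2, 2, emb2$params$tok$b, `-`) %*%
    mdeimplant:::pinv(emb2$params$tok$W)
  expect_lt(max(abs(back - g$patches)), 1e-4)
  set.seed(31); mask <- sample_mask(16, 0.25)
  vz2 <- visualize_reconstruction(emb2, img, mask)
  expect_equal(dim(vz2$image), dim(img))
  # unmasked patches are untouched in the composite
  comp <- patchify(vz2$image, 4)
  expect_equal(comp$patches[mask$visible_idx, ],
               g$patches[mask$visible_idx, ])
})

test_that("simmim-style routing runs the corrupted sequence through the encoder", {
  cfg <- micro_cfg()
  m <- mde_model(cfg, simmim_routing = TRUE)
  img <- random_image(16, seed = 33)
  set.seed(34); mask <- sample_mask(16, 0.25)
  st <- mdeimplant:::mde_step(m, img, mask, "mde", want_grads = TRUE)
  expect_true(is.finite(st$loss))
  expect_equal(dim(st$pred), c(length(mask$masked_idx), cfg$d_enc))
  # perturbing a masked patch changes nothing (mask token replaces it)
  im2 <- img; im2[1:4, 1:4] <- 0
  k <- 1
  if (k %in% mask$masked_idx) {
    st2 <- mdeimplant:::mde_step(m, im2, mask, "mde", want_grads = FALSE)
    expect_equal(st2$pred, st$pred)
  }
})
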