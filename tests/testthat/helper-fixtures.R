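# Shared tiny fixtures. Everything is generated in code; sizes are chosen so
# the whole suite runs in minutes on one CPU.

tiny_cfg <- function(...) {
  run_config_tiny(seed = 303L, ...)
}

# A very small transformer configuration for exhaustive / gradient tests.
micro_cfg <- function(...) {
  run_config_tiny(image_size = 16L, patch_size = 4L, d_enc = 8L, d_dec = 8L,
                  enc_depth = 1L, dec_depth = 1L, enc_heads = 2L,
                  dec_heads = 2L, seed = 11L, ...)
}

# Deterministic micro dataset reused across detection / assembly tests.
micro_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(10, seed = 99L, image_size = 64L,
                                 n_implants_range = c(1L, 2L),
                                 images_per_patient = 2L)
    cache
  }
})

random_image <- function(S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(S * S), S, S)
}

# data.frame of boxes -> matrix helper
box_mat <- function(df) as.matrix(df[, c("x", "y", "w", "h")])
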