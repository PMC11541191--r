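# Shared fixtures: small scenes, patterns and a memoised division batch so
# the expensive end-to-end simulation is computed once per test run.

# a small, fast scene for pipeline-level tests
small_scene_spec <- function(seed = 1L, n_mito = 4L) {
  scene_spec(cell_semi_axes = c(1.6, 1.3, 0.9),
             n_mitochondria = n_mito,
             mito_length_range = c(0.4, 1.0),
             chromatin_radius = 0.5,
             fov_shape = c(18L, 80L, 112L),
             rng_seed = seed)
}

# smooth random 2D pattern, good for registration tests
smooth_pattern <- function(ny = 64, nx = 64, seed = 2, sigma = 2) {
  set.seed(seed)
  v <- array(runif(3 * ny * nx), c(3, ny, nx))
  gauss_blur3d(v, sigma, c(1e6, 1, 1))[2, , ]
}

# digitised ball mask
ball_mask <- function(r = 10, n = 2 * r + 7) {
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  c0 <- (n + 1) / 2
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, c(n, n, n))
}

# brute-force intermeans oracle: all bin indices t satisfying
# t == round((mean_below + mean_above) / 2), round half up
intermeans_fixed_points <- function(counts) {
  i <- seq_along(counts) - 1
  keep <- integer(0)
  for (t in 0:(length(counts) - 2)) {
    nb <- sum(counts[i <= t]); na <- sum(counts[i > t])
    if (nb == 0 || na == 0) next
    mb <- sum(i[i <= t] * counts[i <= t]) / nb
    ma <- sum(i[i > t] * counts[i > t]) / na
    if (floor((mb + ma) / 2 + 0.5) == t) keep <- c(keep, t)
  }
  keep
}

# thin wrappers over internals used as oracles
apply_rigid_slice_for_test <- function(img, ty, tx) {
  mitoquant:::apply_rigid_slice(img, 0, ty, tx)
}
fft_convolve_for_test <- function(x, kernel) {
  mitoquant:::fft_convolve(x, kernel)
}

# memoised full-scale division batch shared by the acceptance tests
.batch_cache <- new.env(parent = emptyenv())
acceptance_batch <- function() {
  if (is.null(.batch_cache$batch)) {
    .batch_cache$batch <-
      simulate_division_batch(pipeline_config(seed = 1, n_divisions = 30))
  }
  .batch_cache$batch
}
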