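test_that("an already-aligned stack yields near-identity transforms", {
  base <- smooth_pattern(64, 64, seed = 21)
  st <- array(rep(base, each = 1), c(5, 64, 64))
  for (k in 1:5) st[k, , ] <- base
  al <- align_stack(st)
  expect_true(all(abs(al$transforms$ty) < 0.1))
  expect_true(all(abs(al$transforms$tx) < 0.1))
  expect_true(all(abs(al$transforms$rotation) < 0.1))
})

test_that("known injected per-slice shifts are recovered within half a pixel", {
  base <- smooth_pattern(64, 64, seed = 2)
  sh <- rbind(c(0, 0), c(1.5, -2), c(-2.5, 3), c(3, -1.5), c(-1, 2.5))
  st <- array(0, c(5, 64, 64))
  for (k in 1:5)
    st[k, , ] <- apply_rigid_slice_for_test(base, sh[k, 1], sh[k, 2])
  al <- align_stack(st, reference = "middle")
  # expected recovery: s_ref - s_k (alignment into the reference frame)
  exp_ty <- sh[3, 1] - sh[, 1]
  exp_tx <- sh[3, 2] - sh[, 2]
  expect_true(all(abs(al$transforms$ty - exp_ty) < 0.5))
  expect_true(all(abs(al$transforms$tx - exp_tx) < 0.5))
})

test_that("a planar shift is recovered by the correlation initialiser", {
  base <- smooth_pattern(48, 48, seed = 30)
  moved <- apply_rigid_slice_for_test(base, 3, -2)
  st <- array(0, c(2, 48, 48))
  st[1, , ] <- base; st[2, , ] <- moved
  al <- align_stack(st, reference = "first")
  expect_lt(abs(al$transforms$ty[2] - (-3)), 0.25)
  expect_lt(abs(al$transforms$tx[2] - 2), 0.25)
})

test_that("identity transforms leave a stack bitwise-equal in nearest mode", {
  st <- array(runif(4 * 20 * 20), c(4, 20, 20))
  tf <- rigid_transforms(rep(0, 4))
  expect_identical(apply_transforms(st, tf, interp = "nearest"), st)
  expect_error(apply_transforms(st, rigid_transforms(rep(0, 3))),
               "does not match")
})

test_that("transforms estimated on one channel co-register the other", {
  base_r <- smooth_pattern(64, 64, seed = 40)
  base_g <- smooth_pattern(64, 64, seed = 41)
  sh <- rbind(c(2, -1), c(-1.5, 2.5), c(0.5, 1))
  red <- green <- array(0, c(3, 64, 64))
  for (k in 1:3) {
    red[k, , ] <- apply_rigid_slice_for_test(base_r, sh[k, 1], sh[k, 2])
    green[k, , ] <- apply_rigid_slice_for_test(base_g, sh[k, 1], sh[k, 2])
  }
  al <- align_stack(red, reference = "first")
  g_al <- apply_transforms(green, al$transforms)
  ref <- apply_rigid_slice_for_test(base_g, sh[1, 1], sh[1, 2])
  core <- 12:52
  for (k in 1:3)
    expect_gt(cor(as.numeric(g_al[k, core, core]),
                  as.numeric(ref[core, core])), 0.98)
})

test_that("applying transforms then their inverses is bounded by interpolation error", {
  base <- smooth_pattern(64, 64, seed = 50)
  st <- array(0, c(2, 64, 64)); st[1, , ] <- base; st[2, , ] <- base
  tf <- rigid_transforms(c(1.5, -2), ty = c(2.3, -1.2), tx = c(-1.7, 0.8))
  back <- apply_transforms(apply_transforms(st, tf), invert_transforms(tf))
  core <- 16:48
  expect_lt(max(abs(back[, core, core] - st[, core, core])),
            0.05 * diff(range(base)))
})

test_that("transform sets round-trip through the text matrix file", {
  tf <- rigid_transforms(c(0.5, -1), ty = c(2, -3.25), tx = c(0, 4.5))
  path <- tempfile(fileext = ".txt")
  write_transforms(tf, path)
  back <- read_transforms(path)
  expect_equal(as.data.frame(back), as.data.frame(tf))
})

test_that("bleedthrough subtraction clips at zero and preserves dtype", {
  g <- array(100L, c(2, 4, 4)); r <- array(0L, c(2, 4, 4))
  expect_identical(subtract_bleedthrough(g, r, 1), g)
  r2 <- array(150L, c(2, 4, 4))
  out <- subtract_bleedthrough(g, r2, 1)
  expect_true(all(out == 0L))
  expect_true(is.integer(out))
  expect_error(subtract_bleedthrough(g, array(0L, c(2, 4, 5)), 1), "shapes")
})

test_that("calibrated over-subtraction barely disturbs the tubule signal", {
  sc <- generate_scene(small_scene_spec(seed = 5))
  green <- sc$green + 0.08 * sc$red
  sub <- subtract_bleedthrough(green, sc$red, 0.12)
  expect_lt(abs(sum(sub) - sum(sc$green)) / sum(sc$green), 0.05)
  # idempotent when red is silent
  again <- subtract_bleedthrough(sub, array(0, dim(sub)), 0.12)
  expect_equal(again, sub)
})

test_that("cropping respects half-open 0-based bounds and conserves mass", {
  v <- array(seq_len(4 * 6 * 8), c(4, 6, 8))
  full <- crop_roi(v, list(z = c(0, 4), y = c(0, 6), x = c(0, 8)))
  expect_identical(full, v)
  one <- crop_roi(v, list(z = c(1, 2), y = c(2, 3), x = c(3, 4)))
  expect_identical(as.numeric(one), as.numeric(v[2, 3, 4]))
  left <- crop_roi(v, list(z = c(0, 4), y = c(0, 6), x = c(0, 3)))
  right <- crop_roi(v, list(z = c(0, 4), y = c(0, 6), x = c(3, 8)))
  expect_equal(sum(left) + sum(right), sum(v))
  expect_error(crop_roi(v, list(z = c(0, 0), y = c(0, 6), x = c(0, 8))),
               "empty")
})

test_that("Richardson-Lucy with a delta PSF is the identity", {
  set.seed(1)
  v <- array(runif(16 * 16 * 16, 0, 100), c(16, 16, 16))
  dp <- array(0, c(3, 3, 3)); dp[2, 2, 2] <- 1
  expect_equal(rl_deconvolve(v, dp, 7), v, tolerance = 1e-10)
  expect_error(rl_deconvolve(v, dp, 0), "iterations")
  expect_error(rl_deconvolve(v, dp * 0.5, 5), "sum to 1")
})

test_that("deconvolution sharpens a blurred rod and conserves flux", {
  psf <- suppressWarnings(theoretical_psf(510, shape = c(5L, 15L, 15L)))
  rod <- array(0, c(9, 33, 33)); rod[5, 16:18, 8:26] <- 1000
  blur <- pmax(fft_convolve_for_test(rod, psf), 0)
  dec <- rl_deconvolve(blur, psf, 20)
  expect_lt(abs(sum(dec) / sum(blur) - 1), 0.01)
  fwhm_px <- function(v) { p <- v[5, , 17]; sum(p >= max(p) / 2) }
  expect_lt(fwhm_px(dec), fwhm_px(blur))
  expect_lte(abs(fwhm_px(dec) - fwhm_px(rod)), 1)
  expect_true(all(dec >= 0))
})

test_that("RL iterations monotonically reduce the Poisson divergence", {
  set.seed(3)
  core <- pmax(gauss_blur3d(array(runif(8 * 16 * 16, 0, 50), c(8, 16, 16)),
                            1.2, c(1, 1, 1)), 0)
  v <- array(0, c(24, 32, 32)); v[9:16, 9:24, 9:24] <- core
  k3 <- array(0, c(3, 3, 3))
  k3[2, 2, 2] <- 0.4
  k3[1, 2, 2] <- k3[3, 2, 2] <- k3[2, 1, 2] <- k3[2, 3, 2] <-
    k3[2, 2, 1] <- k3[2, 2, 3] <- 0.1
  blr <- pmax(fft_convolve_for_test(v, k3), 0)
  kl <- vapply(1:6, function(it) {
    est <- rl_deconvolve(blr, k3, it)
    m <- pmax(fft_convolve_for_test(est, k3), 1e-12)
    sum(ifelse(blr > 0, blr * log(blr / m), 0) - blr + m)
  }, 0)
  expect_true(all(diff(kl) < 1e-8))
})
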