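test_that("rounded-mode refraction chain reproduces the published worked example", {
  g <- refraction_chain(optical_geometry(), rounded = TRUE)
  expect_equal(g$theta, 32.63, tolerance = 0.01 / 32.63)
  expect_equal(g$theta_r, 36.81, tolerance = 0.01 / 36.81)
  expect_lt(abs(g$h - 2.381), 0.001)
  expect_lt(abs(g$l - 1.286), 0.001)
  expect_lt(abs(g$cg_act - 1.710), 0.01)
  expect_lt(abs(g$ls - 0.290), 0.01)
})

test_that("full-precision chain agrees with an independent recomputation", {
  g <- refraction_chain(optical_geometry())
  # independent forward recomputation of the same trigonometric chain
  th <- atan(198.5 / 310)
  thr <- asin(sin(th) * 1.52 / 1.37)
  h <- 2 / sin(pi / 2 - th)
  l <- h * sin(th)
  hp <- l / sin(thr)
  cg_act <- hp * sin(pi / 2 - thr)
  expect_equal(g$ls, 2 - cg_act, tolerance = 1e-12)
  expect_lt(abs(g$ls - 0.285), 0.001)
})

test_that("matched refractive indices give no refraction and zero shift", {
  g <- refraction_chain(optical_geometry(n_glass = 1.4, n_specimen = 1.4))
  expect_equal(g$theta_r, g$theta, tolerance = 1e-12)
  expect_equal(g$ls, 0, tolerance = 1e-12)
})

test_that("total internal reflection regime is rejected", {
  steep <- optical_geometry(r_max = 400, ol_app = 100)
  expect_error(refraction_chain(steep), "total internal reflection")
})

test_that("shift shrinks monotonically as specimen index approaches glass", {
  ns <- seq(1.37, 1.519, length.out = 8)
  ls <- vapply(ns, function(n)
    refraction_chain(optical_geometry(n_specimen = n))$ls, 0)
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[length(ls)], 0.005)
})

test_that("longitudinal shift scales linearly with depth", {
  g <- refraction_chain(optical_geometry(), rounded = TRUE)
  expect_identical(longitudinal_shift_at_depth(g, 0), 0)
  expect_equal(longitudinal_shift_at_depth(g, g$cg_app), g$ls)
  # published depth anchors: ~80 nm at 0.5 um, ~500 nm at 3.5 um
  expect_lt(abs(longitudinal_shift_at_depth(g, 0.5) - 0.080), 0.01)
  expect_lt(abs(longitudinal_shift_at_depth(g, 3.5) - 0.500), 0.015)
  d <- c(0.3, 0.9, 2.7)
  expect_equal(longitudinal_shift_at_depth(g, 3 * d[1]),
               3 * longitudinal_shift_at_depth(g, d[1]))
})

test_that("Rayleigh radii match the instrument's predicted pixel values", {
  expect_lt(abs(rayleigh_radius_px(510) - 5.14), 0.01)
  expect_lt(abs(rayleigh_radius_px(610) - 6.15), 0.01)
  expect_equal(rayleigh_radius_px(510, pixel_nm = 85),
               rayleigh_radius_px(510, pixel_nm = 42.5) / 2)
})

test_that("theoretical PSF is normalised, centred and mirror-symmetric", {
  psf <- theoretical_psf(510, shape = c(7L, 21L, 21L))
  expect_lt(abs(sum(psf) - 1), 1e-9)
  expect_true(all(psf >= 0))
  expect_equal(which.max(psf), (prod(dim(psf)) + 1) %/% 2)
  d <- dim(psf)
  expect_equal(psf, psf[d[1]:1, , ], tolerance = 1e-9)
  expect_equal(psf, psf[, d[2]:1, ], tolerance = 1e-9)
  expect_equal(psf, psf[, , d[3]:1], tolerance = 1e-9)
})

test_that("PSF lateral first minimum sits at the Airy radius", {
  psf <- theoretical_psf(510, shape = c(1L, 25L, 25L))
  ctr <- 13L
  prof <- psf[1, ctr, ctr:25]
  # first local minimum along the +x profile
  dmin <- which(diff(prof) > 0)[1]
  airy_px <- 0.61 * 0.510 / 1.4 / 0.0425
  expect_lt(abs((dmin - 1) - airy_px), 1)
})

test_that("longer emission wavelength widens the PSF", {
  sh <- c(7L, 21L, 21L)
  p510 <- theoretical_psf(510, shape = sh)
  p610 <- theoretical_psf(610, shape = sh)
  mom2 <- function(p) {
    g <- expand.grid(z = 1:sh[1], y = 1:sh[2], x = 1:sh[3])
    c0 <- (sh + 1) / 2
    sum(p * ((g$y - c0[2])^2 + (g$x - c0[3])^2))
  }
  expect_gt(mom2(p610), mom2(p510))
  expect_warning(theoretical_psf(510, shape = c(3L, 5L, 5L)), "Airy")
})

test_that("apparent inflation follows the shift span", {
  flat <- refraction_chain(optical_geometry(n_glass = 1.4, n_specimen = 1.4))
  expect_equal(apparent_inflation(3, flat), 0, tolerance = 1e-12)

  g <- refraction_chain(optical_geometry())
  infl <- apparent_inflation(3, g, depth_top = 0.5)
  expect_gt(infl, 0.10)
  expect_lt(infl, 0.20)

  half <- g; half$ls <- g$ls / 2
  expect_equal(apparent_inflation(3, half, depth_top = 0.5), infl / 2,
               tolerance = 0.15)

  huge <- g; huge$ls <- 10
  expect_error(apparent_inflation(3, huge, depth_top = 0.5), "span")
})
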