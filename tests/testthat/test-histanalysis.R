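test_that("grey histograms count into 256 classes as specified", {
  v <- array(rep(0:255, each = 4), c(4, 16, 16))
  h <- grey_histogram(v, "fixed", x_max = 256)
  expect_equal(h$freq, rep(1 / 256, 256))
  expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  expect_equal(h$width, 1)

  const <- array(1234, c(2, 8, 8))
  hr <- grey_histogram(const, "relative")
  expect_identical(which(hr$counts > 0), 256L)   # all mass in the top class
  expect_error(grey_histogram(array(0, c(2, 2, 2)), "relative"), "x_max")

  # fixed mode accumulates out-of-range values in the top class
  hf <- grey_histogram(array(c(10, 40000), c(1, 1, 2)), "fixed", x_max = 30000)
  expect_identical(hf$counts[256], 1L)
})

test_that("relative-mode frequency vectors are invariant under exact scaling", {
  set.seed(5)
  v <- gauss_blur3d(array(runif(8 * 32 * 32, 0, 5000), c(8, 32, 32)),
                    1.2, c(1, 1, 1))
  h1 <- grey_histogram(v, "relative")
  h2 <- grey_histogram(0.8 * v, "relative")
  expect_identical(h1$counts, h2$counts)
  # fixed-mode vectors shift left instead
  f1 <- grey_histogram(v, "fixed", x_max = 6000)
  f2 <- grey_histogram(0.8 * v, "fixed", x_max = 6000)
  expect_false(identical(f1$counts, f2$counts))
  mean_class <- function(h) sum((seq_len(256) - 1) * h$freq)
  expect_lt(mean_class(f2), mean_class(f1))
})

test_that("identical distributions regress to slope one with F near zero", {
  set.seed(6)
  f <- prop.table(rpois(256, 20) + 1)
  r <- log_frequency_regression(f, f)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_lt(r$f_statistic, 1e-12)
  expect_gt(r$p_value, 0.999)
  expect_identical(r$df1, 1L)
  expect_identical(r$df2, r$n_bins_used - 2L)
  expect_error(log_frequency_regression(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0)),
               "fewer than 3")
})

test_that("zero-frequency classes are excluded from the regression", {
  f1 <- c(0.4, 0.3, 0.2, 0.1, 0, 0, 0, 0)
  f2 <- c(0.38, 0.32, 0.19, 0.11, 0, 0, 0, 0)
  r <- log_frequency_regression(f1, f2)
  expect_identical(r$n_bins_used, 4L)
  expect_identical(r$df2, 2L)
})

test_that("delta area vanishes for identical histograms and is antisymmetric", {
  set.seed(8)
  v <- gauss_blur3d(array(runif(6 * 24 * 24, 0, 3000), c(6, 24, 24)),
                    1, c(1, 1, 1))
  h1 <- grey_histogram(v, "relative")
  h2 <- grey_histogram(v * 0.82, "fixed", x_max = 4000)
  h1f <- grey_histogram(v, "fixed", x_max = 4000)
  expect_equal(delta_auc(h1, h1)$delta, 0, tolerance = 1e-12)
  ab <- delta_auc(h1f, h2); ba <- delta_auc(h2, h1f)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-9)
  expect_error(delta_auc(h1, h2), "share mode")
})

test_that("threshold class position uses the floor convention at bin edges", {
  v <- array(runif(512, 0, 256), c(8, 8, 8))
  h <- grey_histogram(v, "fixed", x_max = 256)   # width exactly 1
  expect_identical(threshold_class_position(0, h), 0L)
  expect_identical(threshold_class_position(256, h), 255L)
  for (k in c(1L, 63L, 128L, 200L, 255L))
    expect_identical(threshold_class_position(k, h), k)
  expect_warning(pos <- threshold_class_position(300, h), "clamped")
  expect_identical(pos, 255L)
})

test_that("relative-mode threshold classes are scale-invariant, fixed-mode drop", {
  set.seed(9)
  v <- gauss_blur3d(array(runif(8 * 32 * 32, 0, 8000), c(8, 32, 32)),
                    1.2, c(1, 1, 1))
  s <- 0.78
  t1 <- global_threshold(v); t2 <- global_threshold(s * v)
  r1 <- threshold_class_position(t1, grey_histogram(v, "relative"))
  r2 <- threshold_class_position(t2, grey_histogram(s * v, "relative"))
  expect_identical(r1, r2)
  f1 <- threshold_class_position(t1, grey_histogram(v, "fixed", x_max = 10000))
  f2 <- threshold_class_position(t2, grey_histogram(s * v, "fixed",
                                                    x_max = 10000))
  expect_lt(f2, f1)
})

test_that("threshold-intensity correlation behaves across regimes", {
  s <- seq(1, 0.7, length.out = 10)
  tc <- threshold_bleach_correlation(s * 1537, s)
  expect_gt(unname(tc$pearson$estimate), 0.999)
  set.seed(10)
  rs <- replicate(50, {
    sh <- sample(s)
    unname(threshold_bleach_correlation(sh * 1537, s)$pearson$estimate)
  })
  expect_lt(mean(abs(rs)), 0.4)
  expect_error(threshold_bleach_correlation(rep(1, 5), s[1:5]),
               "zero-variance")
})
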