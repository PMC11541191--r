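# Grey-value histogram machinery: fixed vs relative 256-class frequency
# distributions, log10-log10 frequency regression with an
# extra-sum-of-squares F-test against slope 1, fitted-curve area contrasts,
# and threshold-class positioning.

#' 256-class grey-value histogram of a stack
#'
#' Whole-stack histogram with `n_bins` classes on `[x_min, x_max]`. In
#' `"relative"` mode the upper limit is the stack maximum, so the frequency
#' vector is invariant under exact multiplicative intensity scaling; in
#' `"fixed"` mode it is a constant (default 30000, the convention for
#' processed 16-bit stacks; 7300 suits unprocessed originals), so bleaching
#' shifts mass to lower classes. Values above `x_max` accumulate in the top
#' class.
#'
#' @param vol numeric array.
#' @param mode `"relative"` or `"fixed"`.
#' @param x_max upper grey limit (fixed mode; ignored in relative mode).
#' @param x_min lower grey limit (default 0).
#' @param n_bins number of classes (default 256).
#' @return object of class `grey_histogram`: `mode`, `x_min`, `x_max`,
#'   `width`, `counts`, `freq` (frequencies summing to 1).
#' @export
grey_histogram <- function(vol, mode = c("relative", "fixed"),
                           x_max = 30000, x_min = 0, n_bins = 256L) {
  mode <- match.arg(mode)
  stopifnot(length(vol) > 0)
  if (mode == "relative") x_max <- max(vol)
  if (x_max <= x_min) stop("x_max must exceed x_min")
  w <- (x_max - x_min) / n_bins
  bin <- pmin(pmax(floor((vol - x_min) / w), 0), n_bins - 1)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  structure(list(mode = mode, x_min = x_min, x_max = x_max, width = w,
                 n_bins = as.integer(n_bins), counts = counts,
                 freq = counts / sum(counts)),
            class = "grey_histogram")
}

#' @export
print.grey_histogram <- function(x, ...) {
  cat(sprintf("Grey histogram (%s): %d classes on [%g, %g], width %.4g\n",
              x$mode, x$n_bins, x$x_min, x$x_max, x$width))
  invisible(x)
}

#' Log-log regression of paired class frequencies
#'
#' Least-squares fit of `log10(freq_y) = a + b * log10(freq_x)` over the
#' classes where both frequencies are positive (zero-frequency classes are
#' excluded because their logarithm is undefined), followed by an
#' extra-sum-of-squares F-test of the null hypothesis b = 1 (the constrained
#' model keeps the intercept free). The conventional orientation puts the
#' earlier condition (e.g. metaphase) on x and the later one
#' (post-cytokinesis) on y, in which case photobleaching inflates b above 1
#' for fixed-range histograms.
#'
#' @param freq_x,freq_y frequency vectors of equal length (e.g. mean
#'   frequencies over divisions), or `grey_histogram` objects.
#' @return object of class `freq_regression`: `slope`, `intercept`,
#'   `f_statistic`, `df1` (= 1), `df2` (= classes used - 2), `p_value`,
#'   `n_bins_used`, and the underlying `lm` fit.
#' @export
log_frequency_regression <- function(freq_x, freq_y) {
  if (inherits(freq_x, "grey_histogram")) freq_x <- freq_x$freq
  if (inherits(freq_y, "grey_histogram")) freq_y <- freq_y$freq
  stopifnot(length(freq_x) == length(freq_y))
  use <- freq_x > 0 & freq_y > 0
  if (sum(use) < 3)
    stop("fewer than 3 usable classes after zero-frequency exclusion")
  lx <- log10(freq_x[use]); ly <- log10(freq_y[use])
  fit <- lm(ly ~ lx)
  rss1 <- sum(residuals(fit)^2)
  # constrained: slope fixed at 1, intercept free
  r0 <- ly - lx
  rss0 <- sum((r0 - mean(r0))^2)
  df2 <- as.integer(sum(use)) - 2L
  f <- (rss0 - rss1) / (rss1 / df2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 f_statistic = f, df1 = 1L, df2 = df2,
                 p_value = pf(f, 1, df2, lower.tail = FALSE),
                 n_bins_used = as.integer(sum(use)), fit = fit),
            class = "freq_regression")
}

#' @export
print.freq_regression <- function(x, ...) {
  cat(sprintf("log10-log10 frequency regression (%d classes)\n",
              x$n_bins_used))
  cat(sprintf("  slope %.4f, intercept %.4f\n", x$slope, x$intercept))
  cat(sprintf("  H0 slope = 1: F(%d,%d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  invisible(x)
}

# Fit a smooth curve to one histogram's log10 frequencies over its occupied
# classes and return a function of the class coordinate plus the support.
fit_log_curve <- function(hist, df = 6) {
  x <- which(hist$freq > 0) - 1
  y <- log10(hist$freq[hist$freq > 0])
  if (length(x) < 4) stop("fit non-convergence: fewer than 4 occupied classes")
  df <- min(df, length(x) - 1)
  sp <- smooth.spline(x, y, df = df)
  list(predict = function(xx) 10^predict(sp, xx)$y,
       support = range(x))
}

#' Area-under-curve contrast between two histograms
#'
#' Fits a smooth curve (penalised spline in log10-frequency space, the
#' default family) to each frequency distribution over its occupied
#' classes, integrates each curve numerically (composite trapezoid over the
#' class axis), and returns the difference in area with the sign convention
#' `delta = area_a - area_b` (first condition minus second, e.g. metaphase
#' minus post-cytokinesis) plus the percent difference
#' `100 * (area_b - area_a) / area_a`.
#'
#' @param hist_a,hist_b `grey_histogram` objects sharing mode and binning.
#' @param df spline degrees of freedom (curve-family parameter).
#' @param n_grid integration grid points per curve.
#' @return object of class `delta_area`: `area_a`, `area_b`, `delta`,
#'   `percent_difference`.
#' @export
delta_auc <- function(hist_a, hist_b, df = 6, n_grid = 1024) {
  stopifnot(inherits(hist_a, "grey_histogram"),
            inherits(hist_b, "grey_histogram"))
  if (hist_a$mode != hist_b$mode || hist_a$n_bins != hist_b$n_bins)
    stop("histograms must share mode and binning")
  auc <- function(h) {
    cv <- fit_log_curve(h, df = df)
    xx <- seq(cv$support[1], cv$support[2], length.out = n_grid)
    yy <- cv$predict(xx)
    sum((yy[-1] + yy[-n_grid]) / 2 * diff(xx))
  }
  a <- auc(hist_a); b <- auc(hist_b)
  structure(list(area_a = a, area_b = b, delta = a - b,
                 percent_difference = 100 * (b - a) / a),
            class = "delta_area")
}

#' @export
print.delta_area <- function(x, ...) {
  cat(sprintf("delta area: %.4g (areas %.4g vs %.4g; %+.2f%%)\n",
              x$delta, x$area_a, x$area_b, x$percent_difference))
  invisible(x)
}

#' Class position of a threshold on a histogram
#'
#' `floor((t - x_min) / width)` clamped to the class range; a threshold at
#' an exact bin edge belongs to the higher class (floor convention).
#' Thresholds outside `[x_min, x_max]` are clamped with a warning.
#'
#' @param threshold grey value (or a `threshold_result`).
#' @param hist a [grey_histogram()].
#' @return integer class index in 0..n_bins-1.
#' @export
threshold_class_position <- function(threshold, hist) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$value
  stopifnot(inherits(hist, "grey_histogram"))
  if (threshold < hist$x_min || threshold > hist$x_max) {
    warning("threshold outside histogram range; clamped")
    threshold <- min(max(threshold, hist$x_min), hist$x_max)
  }
  as.integer(min(floor((threshold - hist$x_min) / hist$width),
                 hist$n_bins - 1))
}

#' Correlation between normalised thresholds and normalised intensities
#'
#' Pearson and Spearman correlation of paired series of normalised
#' threshold values (e.g. post/metaphase ratios) against normalised
#' fluorescence intensities; the expected strong positive correlation
#' reflects thresholds tracking photobleaching.
#'
#' @param thresholds,intensities paired numeric vectors, length >= 3.
#' @return list of class `threshold_correlation`: `pearson`, `spearman`
#'   (both `cor.test` results), and the linear `fit`.
#' @export
threshold_bleach_correlation <- function(thresholds, intensities) {
  stopifnot(length(thresholds) == length(intensities),
            length(thresholds) >= 3)
  if (sd(thresholds) == 0 || sd(intensities) == 0)
    stop("zero-variance series: correlation undefined")
  structure(list(
    pearson = cor.test(thresholds, intensities, method = "pearson"),
    spearman = cor.test(thresholds, intensities, method = "spearman",
                        exact = FALSE),
    fit = lm(thresholds ~ intensities)),
    class = "threshold_correlation")
}

#' @export
print.threshold_correlation <- function(x, ...) {
  cat(sprintf("threshold vs intensity: Pearson r = %.4f (p = %.3g), Spearman rho = %.4f (p = %.3g)\n",
              unname(x$pearson$estimate), x$pearson$p.value,
              unname(x$spearman$estimate), x$spearman$p.value))
  invisible(x)
}

#' Plot a grey-value histogram
#'
#' Class frequencies on a log10 y-axis against the 256 class indices.
#'
#' @param x a `grey_histogram`.
#' @param ... passed to [plot()].
#' @export
plot.grey_histogram <- function(x, ...) {
  i <- which(x$freq > 0) - 1
  plot(i, log10(x$freq[x$freq > 0]), type = "h",
       xlab = sprintf("grey value class (%s, x_max = %g)", x$mode, x$x_max),
       ylab = "log10 frequency", ...)
  invisible(x)
}
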