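# Photobleaching and quantity-invariance analysis across time series:
# integrated-density traces, linear decay fitting, normalised quantities,
# and the statistical battery (normality-gated one-sample tests, omnibus
# rank tests across threshold algorithms).

#' Integrated-density trace over a time series
#'
#' For each timepoint, sums the integrated density (mean grey value x area
#' = pixel sum) over all slices within the cell ROIs, then normalises to
#' the first timepoint.
#'
#' @param stack 5D array (t, c, z, y, x) or a list of 3D volumes.
#' @param rois a single [roi_set()] recycled across timepoints, or a list
#'   with one `roi_set` per timepoint.
#' @param channel channel index used when `stack` is 5D (default 2, the
#'   green channel).
#' @param interval_s acquisition interval, seconds.
#' @return object of class `bleach_series`: data.frame `trace` with
#'   `time_min`, `integrated_density`, `normalised`; plus
#'   `max_step_fluctuation`.
#' @export
integrated_density_trace <- function(stack, rois, channel = 2L,
                                     interval_s = 60) {
  vols <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[1]), function(t) {
      v <- stack[t, channel, , , , drop = TRUE]
      if (length(dim(v)) != 3) dim(v) <- dim(stack)[3:5]
      v
    })
  nt <- length(vols)
  per_t <- !inherits(rois, "roi_set")
  if (per_t && length(rois) < nt)
    stop("missing ROI for timepoint ", length(rois) + 1)
  intden <- numeric(nt)
  for (t in seq_len(nt)) {
    r <- if (per_t) rois[[t]] else rois
    if (is.null(r)) stop("missing ROI for timepoint ", t)
    v <- vols[[t]]
    d <- dim(v)
    s <- 0
    for (z in r$slices) {
      m <- roi_slice_mask(r, z, d[2], d[3])
      s <- s + sum(v[z, , ][m])
    }
    intden[t] <- s
  }
  norm <- intden / intden[1]
  fluct <- if (nt >= 2) max(abs(norm[-1] / norm[-nt] - 1)) else 0
  structure(list(trace = data.frame(time_min = (seq_len(nt) - 1) *
                                      interval_s / 60,
                                    integrated_density = intden,
                                    normalised = norm),
                 interval_s = interval_s,
                 max_step_fluctuation = fluct),
            class = "bleach_series")
}

#' @export
print.bleach_series <- function(x, ...) {
  cat(sprintf("Bleach series: %d timepoints, final normalised intensity %.3f\n",
              nrow(x$trace), tail(x$trace$normalised, 1)))
  cat(sprintf("  max consecutive-step fluctuation %.1f%%\n",
              100 * x$max_step_fluctuation))
  invisible(x)
}

#' Fit a linear photobleaching decay
#'
#' Ordinary least squares of the normalised trace against time in minutes.
#' The decay rate in percent per minute is `-100 * slope`.
#'
#' @param series a [integrated_density_trace()] result, or a numeric vector
#'   of normalised intensities with `time_min` supplied.
#' @param time_min acquisition times in minutes (when `series` is numeric).
#' @return list of class `decay_fit`: `slope` (per minute), `intercept`,
#'   `ci95` (slope confidence interval), `rate_pct_per_min`, `fit`.
#' @export
fit_decay <- function(series, time_min = NULL) {
  if (inherits(series, "bleach_series")) {
    y <- series$trace$normalised
    time_min <- series$trace$time_min
  } else y <- series
  if (length(y) < 3) stop("need at least 3 timepoints to fit a decay")
  fit <- lm(y ~ time_min)
  # a perfect fit (zero residual) makes confint warn; the CI is then a point
  ci <- suppressWarnings(suppressMessages(confint(fit)[2, ]))
  if (any(is.na(ci))) ci <- c(coef(fit)[2], coef(fit)[2])  # perfect fit
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 ci95 = unname(ci),
                 rate_pct_per_min = -100 * unname(coef(fit)[2]),
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Linear decay: slope %.5f/min (95%% CI %.5f to %.5f) = %.2f%%/min\n",
              x$slope, x$ci95[1], x$ci95[2], x$rate_pct_per_min))
  invisible(x)
}

#' Convert a per-step slope to a per-minute rate
#'
#' @param slope_per_step fitted slope per acquisition step (negative for
#'   decay).
#' @param interval_s sampling interval, seconds.
#' @return decay rate in percent per minute, e.g. a slope of -0.0310 at
#'   45-s sampling gives 4.13%/min.
#' @export
step_slope_to_rate_per_min <- function(slope_per_step, interval_s) {
  -100 * slope_per_step / (interval_s / 60)
}

signif_stars <- function(p) {
  if (is.na(p)) return("")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' One-sample invariance test of normalised quantities
#'
#' Tests whether normalised quantities (post-cytokinesis / metaphase
#' ratios) differ from 1. Normality is assessed with the Shapiro-Wilk test;
#' a one-sample t test is used when normality is not rejected, a one-sample
#' Wilcoxon signed-rank test otherwise. Degenerate all-identical samples
#' yield a report without a p value.
#'
#' @param ratios numeric vector of normalised quantities (> 0), n >= 3.
#' @param mu null value (default 1).
#' @return list of class `invariance_test`: `n`, `mean`, `sd`, `median`,
#'   `normality_p`, `test` ("t" or "wilcoxon"), `statistic`, `p_value`,
#'   `stars`, `verdict`.
#' @export
invariance_test <- function(ratios, mu = 1) {
  stopifnot(length(ratios) >= 3, all(ratios > 0))
  if (sd(ratios) == 0) {
    return(structure(list(n = length(ratios), mean = mean(ratios),
                          sd = 0, median = median(ratios),
                          normality_p = NA_real_, test = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          stars = "",
                          verdict = if (ratios[1] == mu) "no change"
                                    else "constant shift"),
                     class = "invariance_test"))
  }
  swp <- shapiro.test(ratios)$p.value
  if (swp >= 0.05) {
    tt <- t.test(ratios, mu = mu)
    test <- "t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    tt <- wilcox.test(ratios, mu = mu, exact = FALSE)
    test <- "wilcoxon"; stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(n = length(ratios), mean = mean(ratios), sd = sd(ratios),
                 median = median(ratios), normality_p = swp, test = test,
                 statistic = stat, p_value = p, stars = signif_stars(p),
                 verdict = if (p < 0.05) {
                   if (mean(ratios) < mu) "significant decrease"
                   else "significant increase"
                 } else "no significant change"),
            class = "invariance_test")
}

#' @export
print.invariance_test <- function(x, ...) {
  cat(sprintf("Invariance test (n = %d): mean %.3f +/- %.3f, median %.3f\n",
              x$n, x$mean, x$sd, x$median))
  if (x$test == "none") {
    cat("  degenerate sample:", x$verdict, "\n")
  } else {
    cat(sprintf("  Shapiro-Wilk p = %.3g -> %s test: p = %.4g %s (%s)\n",
                x$normality_p, x$test, x$p_value, x$stars, x$verdict))
  }
  invisible(x)
}

#' Compare global-threshold algorithms across division pairs
#'
#' For each algorithm and each metaphase/post-cytokinesis volume pair:
#' threshold both volumes, count foreground voxels, and form the
#' post/metaphase quantity ratio. An omnibus Kruskal-Wallis rank test
#' compares the ratio distributions across algorithms. Per-pair algorithm
#' failures (e.g. a constant sub-image) are recorded, not fatal.
#'
#' @param pairs list of `list(meta = vol, post = vol)` volume pairs.
#' @param algorithms character vector of algorithms for
#'   [global_threshold()] (>= 2 for the omnibus test).
#' @return list of class `algorithm_comparison`: `table` (long data.frame
#'   with algorithm, pair, metaphase quantity, ratio), `kruskal`
#'   (`htest` or NULL), `failures`.
#' @export
compare_threshold_algorithms <- function(pairs,
                                         algorithms = c("isodata",
                                                        "imagej_default")) {
  stopifnot(length(pairs) >= 1, length(algorithms) >= 1)
  rows <- list()
  failures <- character(0)
  for (alg in algorithms) {
    for (i in seq_along(pairs)) {
      res <- tryCatch({
        tm <- global_threshold(pairs[[i]]$meta, algorithm = alg)
        tp <- global_threshold(pairs[[i]]$post, algorithm = alg)
        data.frame(algorithm = alg, pair = i,
                   meta_quantity = tm$foreground_count,
                   post_quantity = tp$foreground_count,
                   ratio = tp$foreground_count / tm$foreground_count)
      }, error = function(e) {
        failures <<- c(failures, sprintf("%s/pair %d: %s", alg, i,
                                         conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  kw <- NULL
  if (length(unique(tab$algorithm)) >= 2)
    kw <- kruskal.test(ratio ~ factor(algorithm), data = tab)
  structure(list(table = tab, kruskal = kw, failures = failures),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  agg <- aggregate(ratio ~ algorithm, data = x$table, FUN = mean)
  cat("Mean post/metaphase quantity ratio per algorithm:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-16s %.4f\n", agg$algorithm[i], agg$ratio[i]))
  if (!is.null(x$kruskal))
    cat(sprintf("Kruskal-Wallis across algorithms: chi^2 = %.3f, p = %.4g\n",
                unname(x$kruskal$statistic), x$kruskal$p.value))
  if (length(x$failures))
    cat("Failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Benjamini-Krieger-Yekutieli adaptive two-stage FDR adjustment
#'
#' Two-stage linear step-up procedure: a first BH pass at level
#' `q / (1 + q)` estimates the number of true nulls, which then sharpens a
#' second BH pass. Returns adjusted p values comparable against `q`.
#'
#' @param p numeric vector of p values.
#' @param q target false-discovery rate (default 0.05).
#' @return adjusted p values.
#' @export
p_adjust_bky <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, "BH") <= q1)
  if (r1 == 0) return(rep(1, m))
  if (r1 == m) return(stats::p.adjust(p, "BH") * 1)
  m0 <- m - r1
  pmin(stats::p.adjust(p, "BH") * m0 / m, 1)
}

#' Plot a photobleaching trace
#'
#' Normalised integrated density against time, with the fitted linear
#' decay overlaid.
#'
#' @param x a `bleach_series`.
#' @param ... passed to [plot()].
#' @export
plot.bleach_series <- function(x, ...) {
  plot(x$trace$time_min, x$trace$normalised, type = "b", pch = 16,
       xlab = "time (min)", ylab = "normalised integrated density", ...)
  if (nrow(x$trace) >= 3) {
    f <- fit_decay(x)
    graphics::abline(f$intercept, f$slope, lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("%.2f%%/min", f$rate_pct_per_min))
  }
  invisible(x)
}
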