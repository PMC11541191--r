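# Stack I/O (multi-page TIFF with a JSON sidecar carrying axes and voxel
# metadata), ROI-set JSON, pipeline configuration and the pipeline driver.

#' Multi-dimensional image stack container
#'
#' Normalises an array to the canonical (t, c, z, y, x) axis order by
#' inserting singleton axes on the left: a 2D matrix becomes
#' (1, 1, 1, Y, X), a 3D volume (1, 1, Z, Y, X), and so on.
#'
#' @param data numeric array with 2 to 5 dimensions.
#' @param voxel_size physical voxel size (z, y, x), um.
#' @return object of class `image_stack` with fields `data` (5D array) and
#'   `voxel_size`.
#' @export
image_stack <- function(data, voxel_size = c(0.130, 0.0425, 0.0425)) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array")
  if (length(d) < 2 || length(d) > 5) stop("need 2 to 5 dimensions")
  dim(data) <- c(rep(1L, 5 - length(d)), d)
  structure(list(data = data, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack (t, c, z, y, x) = (%s); voxel %s um\n",
              paste(d, collapse = ", "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Extract one 3D volume from a stack
#' @param stack an [image_stack()].
#' @param t,c timepoint and channel indices.
#' @return 3D array (z, y, x).
#' @export
get_volume <- function(stack, t = 1L, c = 1L) {
  v <- stack$data[t, c, , , , drop = TRUE]
  if (length(dim(v) %||% 1) != 3) dim(v) <- dim(stack$data)[3:5]
  v
}

#' Write / read an image stack as multi-page TIFF + JSON sidecar
#'
#' Pages are the flattened (t, c, z) planes in that order; 16-bit samples.
#' A `<path>.json` sidecar records the axis lengths and voxel size so the
#' round trip is lossless; without a sidecar, pages are interpreted as a
#' single-channel z-stack.
#'
#' @param stack an [image_stack()] (integers in 0..65535).
#' @param path file path (`.tif`).
#' @param voxel_size optional override used when the sidecar is missing or
#'   to force a voxel size (a notice is emitted when it overrides
#'   metadata).
#' @return `read_stack` returns an `image_stack`; `write_stack` the path,
#'   invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[k]] <- matrix(stack$data[t, ch, z, , ] / 65535, d[4], d[5])
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(axes = "TCZYX", shape = d,
                            voxel_size_um = stack$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    vs <- as.numeric(meta$voxel_size_um)
    if (!is.null(voxel_size)) {
      message("voxel size override: using (",
              paste(voxel_size, collapse = ", "), ") um instead of metadata")
      vs <- voxel_size
    }
  } else {
    d <- c(1L, 1L, length(pages), dim(pages[[1]]))
    vs <- voxel_size %||% c(1, 1, 1)
  }
  arr <- array(0, d)
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    arr[t, ch, z, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  image_stack(arr, voxel_size = vs)
}

#' Write / read a ROI set as JSON
#'
#' Polygons are stored with 0-based pixel coordinates and 0-based slice
#' indices on disk (converted to 1-based slice indices in R).
#'
#' @param rois a [roi_set()].
#' @param path file path.
#' @return `read_roi_set` returns a `roi_set`; `write_roi_set` the path,
#'   invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  out <- lapply(seq_along(rois$slices), function(i) {
    list(slice = rois$slices[i] - 1L,
         polygons = lapply(rois$polygons[[i]], function(p)
           list(x = unname(p[, 1]), y = unname(p[, 2]))))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- vapply(raw, function(e) as.integer(e$slice) + 1L, 1L)
  polys <- lapply(raw, function(e)
    lapply(e$polygons, function(p)
      cbind(x = unlist(p$x), y = unlist(p$y))))
  roi_set(slices, polys)
}

#' Pipeline configuration
#'
#' Collects every stage toggle, parameter and seed of the simulate ->
#' preprocess -> segment -> analyse chain; round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed master seed; every random draw in the pipeline flows from
#'   it.
#' @param n_divisions number of simulated division pairs.
#' @param subtract_fraction bleedthrough subtraction fraction (1.0 or a
#'   calibrated value such as 0.12).
#' @param rl_iterations Richardson-Lucy iterations (0 disables
#'   deconvolution).
#' @param align logical: run per-slice alignment (needed when jitter is
#'   simulated).
#' @param threshold_algorithm segmentation algorithm.
#' @param histogram_x_max fixed-mode histogram upper limit.
#' @param decay_rate_per_min,interval_s,n_timepoints,fluctuation_sd green
#'   bleach-schedule parameters.
#' @param bleedthrough_fraction simulated red-into-green fraction.
#' @param psf_wavelength_nm emission wavelength for the theoretical PSF.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_divisions = 30L,
                            subtract_fraction = 0.08, rl_iterations = 0L,
                            align = FALSE, threshold_algorithm = "isodata",
                            histogram_x_max = 30000,
                            decay_rate_per_min = 0.0175, interval_s = 60,
                            n_timepoints = 13L, fluctuation_sd = 0.05,
                            bleedthrough_fraction = 0.08,
                            psf_wavelength_nm = 510) {
  structure(list(seed = as.integer(seed),
                 n_divisions = as.integer(n_divisions),
                 subtract_fraction = subtract_fraction,
                 rl_iterations = as.integer(rl_iterations),
                 align = align,
                 threshold_algorithm = threshold_algorithm,
                 histogram_x_max = histogram_x_max,
                 decay_rate_per_min = decay_rate_per_min,
                 interval_s = interval_s,
                 n_timepoints = as.integer(n_timepoints),
                 fluctuation_sd = fluctuation_sd,
                 bleedthrough_fraction = bleedthrough_fraction,
                 psf_wavelength_nm = psf_wavelength_nm),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Simulate and analyse a batch of division pairs
#'
#' The workhorse behind [run_pipeline()] and the acceptance analyses. For
#' each replicate it generates a fresh scene, divides it, simulates the
#' multi-step series (materialising the metaphase and post-cytokinesis
#' endpoints) and a two-step series, preprocesses (bleedthrough
#' subtraction, optional alignment and deconvolution), then measures
#' integrated densities within cell ROIs and Isodata-segmented quantities.
#'
#' @param config a [pipeline_config()].
#' @param spec optional [scene_spec()] template (the seed field is
#'   replaced per replicate).
#' @param keep_volumes retain the preprocessed endpoint volumes (memory!).
#' @return list of class `division_batch` with `measurements` (data.frame,
#'   one row per replicate), and optionally `volumes`, `histogram pairs`.
#' @export
simulate_division_batch <- function(config, spec = NULL,
                                    keep_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  psf <- if (config$psf_wavelength_nm > 0)
    theoretical_psf(config$psf_wavelength_nm, shape = c(7L, 15L, 15L))
  else NULL
  n <- config$n_divisions
  rows <- vector("list", n)
  vols <- if (keep_volumes) vector("list", n) else NULL
  hists <- vector("list", n)
  base_seed <- config$seed

  for (i in seq_len(n)) {
    seed_i <- (base_seed * 1000L + i) %% .Machine$integer.max
    if (is.null(spec)) {
      # per-replicate biological variability: lateral cell diameter 5-7 um
      # (thickness fixed at 3 um), tubule count 12-18
      set.seed(seed_i)
      u <- runif(1, 5, 7) / 6
      sp <- scene_spec(cell_semi_axes = c(3.0 * u, 2.5 * u, 1.5),
                       n_mitochondria = sample(12:18, 1),
                       rng_seed = seed_i)
    } else {
      sp <- spec
      sp$rng_seed <- seed_i
    }
    scene <- generate_scene(sp)
    post <- simulate_division(scene)
    sched <- bleach_schedule(config$decay_rate_per_min, config$interval_s,
                             config$n_timepoints, config$fluctuation_sd)
    sim <- simulate_timeseries(scene, sched, psf = psf,
                               bleedthrough_fraction =
                                 config$bleedthrough_fraction,
                               noise = noise_model(), rng_seed = seed_i,
                               materialise = c(1L, config$n_timepoints),
                               post_scene = post,
                               division_time = config$n_timepoints)
    # two-step acquisition: bleach accrues per acquisition event, so only
    # two exposures separate the endpoints
    sched2 <- bleach_schedule(config$decay_rate_per_min, config$interval_s,
                              2L, config$fluctuation_sd)
    sim2 <- simulate_timeseries(scene, sched2, psf = psf,
                                bleedthrough_fraction =
                                  config$bleedthrough_fraction,
                                noise = noise_model(), rng_seed = (seed_i + 500009L) %% .Machine$integer.max,
                                materialise = c(1L, 2L),
                                post_scene = post, division_time = 2L)

    prep <- function(sim_out, k) {
      g <- sim_out$stack[k, 2, , , ]
      r <- sim_out$stack[k, 1, , , ]
      g <- subtract_bleedthrough(g, r, config$subtract_fraction)
      if (config$rl_iterations > 0 && !is.null(psf))
        g <- rl_deconvolve(g, psf, config$rl_iterations)
      g
    }
    g_meta <- prep(sim, 1); g_post <- prep(sim, 2)
    g2_meta <- prep(sim2, 1); g2_post <- prep(sim2, 2)

    roi_meta <- scene_rois(scene)
    roi_post <- scene_rois(post)
    id_meta <- integrated_density_trace(list(g_meta), roi_meta)
    id_post <- integrated_density_trace(list(g_post), roi_post)
    id2_meta <- integrated_density_trace(list(g2_meta), roi_meta)
    id2_post <- integrated_density_trace(list(g2_post), roi_post)

    thr_meta <- global_threshold(g_meta, config$threshold_algorithm)
    thr_post <- global_threshold(g_post, config$threshold_algorithm)

    hists[[i]] <- list(
      fixed_meta = grey_histogram(g_meta, "fixed",
                                  x_max = config$histogram_x_max),
      fixed_post = grey_histogram(g_post, "fixed",
                                  x_max = config$histogram_x_max),
      rel_meta = grey_histogram(g_meta, "relative"),
      rel_post = grey_histogram(g_post, "relative"),
      thr_meta = thr_meta$value, thr_post = thr_post$value)

    rows[[i]] <- data.frame(
      replicate = i, seed = seed_i,
      fluor_meta = id_meta$trace$integrated_density[1],
      fluor_post = id_post$trace$integrated_density[1],
      fluor_ratio = id_post$trace$integrated_density[1] /
        id_meta$trace$integrated_density[1],
      twostep_ratio = id2_post$trace$integrated_density[1] /
        id2_meta$trace$integrated_density[1],
      thr_meta = thr_meta$value, thr_post = thr_post$value,
      thr_ratio = thr_post$value / thr_meta$value,
      quantity_meta = thr_meta$foreground_count,
      quantity_post = thr_post$foreground_count,
      quantity_ratio = thr_post$foreground_count / thr_meta$foreground_count,
      bleach_truth = sim$truth$multipliers_green[config$n_timepoints],
      true_fg_meta = scene$true_foreground_voxels,
      true_fg_post = post$true_foreground_voxels)
    if (keep_volumes)
      vols[[i]] <- list(meta = g_meta, post = g_post)
  }
  structure(list(measurements = do.call(rbind, rows),
                 histograms = hists, volumes = vols, config = config),
            class = "division_batch")
}

#' Run the full pipeline and write a report bundle
#'
#' Simulates `config$n_divisions` ground-truthed division pairs, runs the
#' preprocessing/segmentation/histogram/time-series analyses, and writes
#' per-stage outputs: the per-replicate measurement table (CSV), the
#' invariance test report and histogram regression summaries (JSON), and a
#' provenance log. Deterministic for a fixed config: the report files
#' depend only on config and seeds (timestamps go to the log only).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param spec optional [scene_spec()] template.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, spec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  batch <- simulate_division_batch(config, spec = spec)
  m <- batch$measurements

  fixed_meta <- rowMeans(sapply(batch$histograms, function(h) h$fixed_meta$freq))
  fixed_post <- rowMeans(sapply(batch$histograms, function(h) h$fixed_post$freq))
  rel_meta <- rowMeans(sapply(batch$histograms, function(h) h$rel_meta$freq))
  rel_post <- rowMeans(sapply(batch$histograms, function(h) h$rel_post$freq))
  reg_fixed <- log_frequency_regression(fixed_meta, fixed_post)
  reg_rel <- log_frequency_regression(rel_meta, rel_post)

  tests <- list(
    fluorescence = unclass(invariance_test(m$fluor_ratio))[
      c("n", "mean", "sd", "test", "p_value", "verdict")],
    two_step = unclass(invariance_test(m$twostep_ratio))[
      c("n", "mean", "sd", "test", "p_value", "verdict")],
    segmented_quantity = unclass(invariance_test(m$quantity_ratio))[
      c("n", "mean", "sd", "test", "p_value", "verdict")],
    regression_fixed = list(slope = reg_fixed$slope,
                            p_value = reg_fixed$p_value),
    regression_relative = list(slope = reg_rel$slope,
                               p_value = reg_rel$p_value))

  write.csv(m, file.path(out_dir, "measurements.csv"), row.names = FALSE)
  jsonlite::write_json(tests, file.path(out_dir, "invariance_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  writeLines(c(sprintf("mitoquant %s", as.character(utils::packageVersion("mitoquant"))),
               sprintf("R %s", R.version.string),
               sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(out_dir, "provenance.log"))
  invisible(list(measurements = m, tests = tests, batch = batch))
}
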