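# Ground-truthed synthetic two-channel scenes: tubular mitochondria
# (capsules swept along bounded-curvature random-walk centrelines) inside an
# ellipsoidal cell, a membrane + chromatin channel, photobleaching schedules,
# per-slice rigid jitter, diffraction blur and detector noise.

#' Specification of a synthetic cell scene
#'
#' Defaults emulate a small dividing neuroblast: a 6 x 5 x 3 um ellipsoidal
#' cell containing 15 tubular mitochondria with diameters 0.10-0.30 um and
#' lengths 0.5-2.0 um, sampled on an anisotropic voxel grid (0.130 um
#' z-step, 0.0425 um pixels).
#'
#' @param cell_semi_axes ellipsoid semi-axes (x, y, z), um.
#' @param n_mitochondria number of tubules.
#' @param mito_diameter_range diameter range, um.
#' @param mito_length_range centreline length range, um.
#' @param membrane_thickness shell thickness of the membrane marker, um.
#' @param chromatin_radius radius of the central chromatin blob, um.
#' @param voxel_size voxel size (z, y, x), um.
#' @param fov_shape field of view (z, y, x) in voxels.
#' @param mito_amplitude mean noise-free grey value inside a tubule.
#' @param membrane_amplitude,chromatin_amplitude red-channel amplitudes.
#' @param rng_seed integer seed used by [generate_scene()].
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(cell_semi_axes = c(3.0, 2.5, 1.5),
                       n_mitochondria = 15,
                       mito_diameter_range = c(0.10, 0.30),
                       mito_length_range = c(0.5, 2.0),
                       membrane_thickness = 0.15,
                       chromatin_radius = 1.0,
                       voxel_size = c(0.130, 0.0425, 0.0425),
                       fov_shape = c(26L, 152L, 256L),
                       mito_amplitude = 20000,
                       membrane_amplitude = 4000,
                       chromatin_amplitude = 3000,
                       rng_seed = 1L) {
  stopifnot(all(voxel_size > 0), all(cell_semi_axes > 0),
            n_mitochondria >= 0, length(fov_shape) == 3,
            mito_diameter_range[1] > 0,
            mito_diameter_range[2] >= mito_diameter_range[1],
            mito_diameter_range[2] < 2 * min(cell_semi_axes),
            mito_length_range[1] > 0,
            mito_length_range[2] >= mito_length_range[1])
  fov_um <- fov_shape * voxel_size   # (z, y, x)
  if (2 * cell_semi_axes[3] > fov_um[1] || 2 * cell_semi_axes[2] > fov_um[2] ||
      2 * cell_semi_axes[1] > fov_um[3])
    stop("cell does not fit inside the field of view")
  structure(list(cell_semi_axes = cell_semi_axes,
                 n_mitochondria = as.integer(n_mitochondria),
                 mito_diameter_range = mito_diameter_range,
                 mito_length_range = mito_length_range,
                 membrane_thickness = membrane_thickness,
                 chromatin_radius = chromatin_radius,
                 voxel_size = voxel_size,
                 fov_shape = as.integer(fov_shape),
                 mito_amplitude = mito_amplitude,
                 membrane_amplitude = membrane_amplitude,
                 chromatin_amplitude = chromatin_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# physical coordinates (um) of voxel centres along one axis
axis_coords <- function(n, vox) (seq_len(n) - 0.5) * vox

# squared normalised ellipsoid coordinate of points (x, y, z) vs centre/semi
ellipsoid_q <- function(x, y, z, centre, semi) {
  ((x - centre[1]) / semi[1])^2 + ((y - centre[2]) / semi[2])^2 +
    ((z - centre[3]) / semi[3])^2
}

# random unit vector
runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Bounded-curvature random-walk centreline inside a shrunken ellipsoid.
# Returns a dense matrix of points (columns x, y, z) spaced ~ds_fine, or NULL
# if the walk could not be kept inside the ellipsoid.
walk_centreline <- function(start, length_um, centre, semi_inner,
                            step_um = 0.15, max_turn_deg = 25,
                            ds_fine = 0.04) {
  n_steps <- max(1L, ceiling(length_um / step_um))
  pts <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3)
  pts[1, ] <- start
  dir <- runit3()
  for (i in seq_len(n_steps)) {
    ok <- FALSE
    for (try in 1:12) {
      # perturb direction by a bounded random rotation
      ax <- runit3()
      ang <- runif(1, 0, deg2rad(max_turn_deg))
      d2 <- dir * cos(ang) + pracma_cross(ax, dir) * sin(ang) +
        ax * sum(ax * dir) * (1 - cos(ang))
      d2 <- d2 / sqrt(sum(d2^2))
      cand <- pts[i, ] + d2 * step_um
      if (ellipsoid_q(cand[1], cand[2], cand[3], centre, semi_inner) <= 1) {
        dir <- d2; pts[i + 1, ] <- cand; ok <- TRUE; break
      }
      dir <- runit3()  # stuck near the boundary: re-draw heading
    }
    if (!ok) return(NULL)
  }
  # densify for voxelisation
  fine <- lapply(seq_len(n_steps), function(i) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    k <- max(2L, ceiling(step_um / ds_fine))
    t <- seq(0, 1, length.out = k)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          a[3] + t * (b[3] - a[3]))
  })
  unique(do.call(rbind, fine))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Voxelise a capsule (dilated polyline) into label/green arrays by distance
# to the dense centreline point set, restricted to a bounding box.
voxelise_capsule <- function(pts, radius, dims, vox, labels, green,
                             label_id, amplitude) {
  lo <- apply(pts, 2, min) - radius - vox[c(3, 2, 1)]
  hi <- apply(pts, 2, max) + radius + vox[c(3, 2, 1)]
  zi <- which(axis_coords(dims[1], vox[1]) >= lo[3] &
              axis_coords(dims[1], vox[1]) <= hi[3])
  yi <- which(axis_coords(dims[2], vox[2]) >= lo[2] &
              axis_coords(dims[2], vox[2]) <= hi[2])
  xi <- which(axis_coords(dims[3], vox[3]) >= lo[1] &
              axis_coords(dims[3], vox[3]) <= hi[1])
  if (!length(zi) || !length(yi) || !length(xi))
    return(list(labels = labels, green = green, count = 0L))
  g <- expand.grid(z = axis_coords(dims[1], vox[1])[zi],
                   y = axis_coords(dims[2], vox[2])[yi],
                   x = axis_coords(dims[3], vox[3])[xi])
  # min squared distance to the centreline point set
  d2 <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(pts))) {
    dd <- (g$x - pts[i, 1])^2 + (g$y - pts[i, 2])^2 + (g$z - pts[i, 3])^2
    d2 <- pmin(d2, dd)
  }
  inside <- d2 <= radius^2
  if (!any(inside)) return(list(labels = labels, green = green, count = 0L))
  idx <- expand.grid(z = zi, y = yi, x = xi)
  lin <- idx$z[inside] + dims[1] * ((idx$y[inside] - 1) +
                                      dims[2] * (idx$x[inside] - 1))
  fresh <- labels[lin] == 0L
  labels[lin[fresh]] <- label_id
  green[lin] <- pmax(green[lin], amplitude)
  list(labels = labels, green = green, count = sum(fresh))
}

#' Generate a noise-free two-channel scene with ground truth
#'
#' Channel 1 (red) holds the plasma-membrane shell and a central chromatin
#' blob; channel 2 (green) holds the mitochondrial tubules, rendered as
#' capsules swept along bounded-curvature random-walk centrelines that stay
#' inside the cell ellipsoid. Tubules are placed with a minimum mutual
#' clearance so each remains a distinct connected object.
#'
#' @param spec a [scene_spec()].
#' @param max_attempts placement attempts per tubule before giving up.
#' @return object of class `mito_scene`: arrays `green`, `red`, `labels`
#'   (all (z, y, x)), the `cells` list (one ellipsoid: centre/semi-axes in
#'   um), per-tubule parameters `mito`, `true_foreground_voxels`, and the
#'   generating `spec`.
#' @export
generate_scene <- function(spec, max_attempts = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$rng_seed)
  dims <- spec$fov_shape
  vox <- spec$voxel_size
  fov_um <- dims * vox
  centre <- c(fov_um[3] / 2, fov_um[2] / 2, fov_um[1] / 2)  # (x, y, z)
  semi <- spec$cell_semi_axes

  labels <- integer(prod(dims))
  green <- numeric(prod(dims))
  mito <- list()
  placed_pts <- NULL   # dense points of already-placed tubules
  placed_r <- numeric(0)

  k <- 0L
  while (k < spec$n_mitochondria) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      diam <- runif(1, spec$mito_diameter_range[1], spec$mito_diameter_range[2])
      len <- runif(1, spec$mito_length_range[1], spec$mito_length_range[2])
      r <- diam / 2
      semi_inner <- pmax(semi - r - 0.05, 0.1)
      # rejection-sample a start point inside the shrunken ellipsoid
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      start <- centre + u * semi_inner
      pts <- walk_centreline(start, len, centre, semi_inner)
      if (is.null(pts)) next
      # clearance to previously placed tubules
      if (!is.null(placed_pts)) {
        mind <- min_pairwise_dist(pts, placed_pts)
        if (mind < r + max(placed_r) + 0.08) next
      }
      amp <- spec$mito_amplitude * runif(1, 0.85, 1.15)
      res <- voxelise_capsule(pts, r, dims, vox, labels, green,
                              label_id = k + 1L, amplitude = amp)
      if (res$count == 0L) next
      labels <- res$labels; green <- res$green
      placed_pts <- rbind(placed_pts, pts)
      placed_r <- c(placed_r, r)
      mito[[k + 1L]] <- list(radius = r, length = len, amplitude = amp,
                             centreline = pts)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place mitochondrion ", k + 1L, " after ", max_attempts,
           " attempts (rng_seed = ", spec$rng_seed, ")")
    k <- k + 1L
  }

  dim(labels) <- dims
  dim(green) <- dims
  red <- render_red_channel(dims, vox,
                            cells = list(list(centre = centre, semi = semi)),
                            spec = spec)

  structure(list(green = green, red = red, labels = labels,
                 cells = list(list(centre = centre, semi = semi)),
                 mito = mito,
                 true_foreground_voxels = sum(labels > 0L),
                 spec = spec),
            class = "mito_scene")
}

min_pairwise_dist <- function(a, b) {
  # min distance between two point sets (rows = points, cols = x,y,z)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# membrane shells + chromatin blobs for a list of cell ellipsoids
render_red_channel <- function(dims, vox, cells, spec,
                               chromatin_offsets = NULL) {
  cz <- axis_coords(dims[1], vox[1])
  cy <- axis_coords(dims[2], vox[2])
  cx <- axis_coords(dims[3], vox[3])
  g <- expand.grid(z = cz, y = cy, x = cx)
  red <- numeric(nrow(g))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    q <- ellipsoid_q(g$x, g$y, g$z, cell$centre, cell$semi)
    # shell: between the ellipsoid and one shrunk by the membrane thickness
    frac <- spec$membrane_thickness / min(cell$semi)
    shell <- q <= 1 & q >= (1 - frac)^2
    red[shell] <- red[shell] + spec$membrane_amplitude
    cen <- cell$centre
    if (!is.null(chromatin_offsets)) cen <- cen + chromatin_offsets[[i]]
    d2 <- (g$x - cen[1])^2 + (g$y - cen[2])^2 + (g$z - cen[3])^2
    blob <- d2 <= spec$chromatin_radius^2
    red[blob] <- red[blob] + spec$chromatin_amplitude
  }
  array(red, dims)
}

#' Simulate cell division by splitting a scene into two daughters
#'
#' Tubules are partitioned into two groups at the median x-centroid and each
#' group's voxels are moved by an integer voxel offset along x, so the total
#' mitochondrial foreground is conserved exactly (no biogenesis or
#' mitophagy). The membrane channel is re-rendered as two daughter
#' ellipsoids of half the mother volume each.
#'
#' @param scene a `mito_scene` from [generate_scene()].
#' @param separation_um distance each daughter centre moves from the mother
#'   centre along x, um.
#' @return a new `mito_scene` with two `cells` and identical
#'   `true_foreground_voxels`.
#' @export
simulate_division <- function(scene, separation_um = 1.4) {
  stopifnot(inherits(scene, "mito_scene"))
  spec <- scene$spec
  dims <- spec$fov_shape
  vox <- spec$voxel_size
  mother <- scene$cells[[1]]
  if (length(scene$cells) != 1)
    stop("scene has already divided")

  n <- length(scene$mito)
  if (n > 0) {
    cen_x <- vapply(scene$mito, function(m) mean(m$centreline[, 1]), 0)
    grp <- ifelse(rank(cen_x, ties.method = "first") <= n / 2, 1L, 2L)
  } else grp <- integer(0)
  shift_vx <- round(separation_um / vox[3])
  offs <- c(-shift_vx, shift_vx)

  labels <- array(0L, dims)
  green <- array(0, dims)
  dscale <- (1 / 2)^(1 / 3)
  cells <- vector("list", 2)
  for (gx in 1:2) {
    ids <- which(grp == gx)
    if (!length(ids)) {
      cells[[gx]] <- list(centre = mother$centre +
                            c(offs[gx] * vox[3], 0, 0),
                          semi = mother$semi * dscale)
      next
    }
    sel <- array(scene$labels %in% ids, dims)
    idx <- which(sel, arr.ind = TRUE)
    # clamp the shift (preserving its sign) so the group stays in frame
    off <- offs[gx]
    off <- max(off, 1L - min(idx[, 3]))
    off <- min(off, dims[3] - max(idx[, 3]))
    if (gx == 1L) off <- min(off, 0L) else off <- max(off, 0L)
    nx <- idx[, 3] + off
    lin_old <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
    lin_new <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (nx - 1))
    if (any(labels[lin_new] != 0L))
      stop("daughter groups overlap after the division shift")
    labels[lin_new] <- scene$labels[lin_old]
    green[lin_new] <- scene$green[lin_old]
    offs[gx] <- off
    # daughter ellipsoid: half the mother volume, grown if needed so the
    # shifted group (plus a margin) fits inside
    ext <- rbind(x = range(axis_coords(dims[3], vox[3])[range(nx)]),
                 y = range(axis_coords(dims[2], vox[2])[range(idx[, 2])]),
                 z = range(axis_coords(dims[1], vox[1])[range(idx[, 1])]))
    cen <- c(mean(ext[1, ]), mother$centre[2], mother$centre[3])
    half <- c((ext[1, 2] - ext[1, 1]) / 2,
              max(abs(ext[2, ] - mother$centre[2])),
              max(abs(ext[3, ] - mother$centre[3])))
    cells[[gx]] <- list(centre = cen,
                        semi = pmax(mother$semi * dscale, half + 0.25))
  }
  red <- render_red_channel(dims, vox, cells, spec)

  out <- scene
  out$green <- green
  out$red <- red
  out$labels <- labels
  out$cells <- cells
  out$true_foreground_voxels <- sum(labels > 0L)
  out$division <- list(groups = grp, shift_voxels = offs)
  out
}

#' Photobleaching schedule
#'
#' Linear mean decay per acquisition event: the expected intensity
#' multiplier at acquisition t is `1 - decay_rate_per_min * interval_min *
#' (t - 1)`. Multiplicative lognormal fluctuations around the trend emulate
#' the timepoint-to-timepoint swings seen in live recordings; consecutive
#' multipliers are capped so no step changes by more than `step_cap`.
#'
#' @param decay_rate_per_min fractional decay per minute (green marker
#'   default 0.0175; a red outer-membrane marker bleaches at about 0.0413).
#' @param interval_s acquisition interval, seconds.
#' @param n_timepoints number of acquisitions.
#' @param fluctuation_sd lognormal sd of the per-timepoint jitter.
#' @param step_cap maximum fractional change between consecutive multipliers.
#' @return object of class `bleach_schedule`.
#' @export
bleach_schedule <- function(decay_rate_per_min = 0.0175, interval_s = 60,
                            n_timepoints = 13, fluctuation_sd = 0.05,
                            step_cap = 0.30) {
  stopifnot(decay_rate_per_min >= 0, interval_s > 0, n_timepoints >= 1,
            fluctuation_sd >= 0, step_cap > 0)
  structure(list(decay_rate_per_min = decay_rate_per_min,
                 interval_s = interval_s,
                 n_timepoints = as.integer(n_timepoints),
                 fluctuation_sd = fluctuation_sd,
                 step_cap = step_cap),
            class = "bleach_schedule")
}

#' Draw bleach multipliers from a schedule
#'
#' @param schedule a [bleach_schedule()].
#' @param fluctuate draw lognormal fluctuations (TRUE) or return the exact
#'   linear trend (FALSE).
#' @return numeric vector of multipliers, one per acquisition; the trend at
#'   the first acquisition is exactly 1. Uses the current RNG stream.
#' @export
bleach_multipliers <- function(schedule, fluctuate = TRUE) {
  stopifnot(inherits(schedule, "bleach_schedule"))
  t <- seq_len(schedule$n_timepoints)
  trend <- 1 - schedule$decay_rate_per_min * (schedule$interval_s / 60) * (t - 1)
  bad <- which(trend <= 0)
  if (length(bad))
    stop("bleach schedule drives the mean multiplier to <= 0 at timepoint ",
         bad[1])
  if (!fluctuate || schedule$fluctuation_sd == 0) return(trend)
  # the trend stays in (0, 1]; the realised multipliers may exceed 1, as
  # observed normalised traces do
  m <- trend * exp(rnorm(length(t), 0, schedule$fluctuation_sd))
  # cap consecutive-step swings
  for (i in seq_along(m)[-1]) {
    lo <- m[i - 1] * (1 - schedule$step_cap)
    hi <- m[i - 1] * (1 + schedule$step_cap)
    m[i] <- min(max(m[i], lo), hi)
  }
  m
}

#' Detector noise model
#'
#' Grey values are treated as expected photon counts: Poisson shot noise on
#' `gain * expected`, additive Gaussian read noise, a constant offset, then
#' quantisation to 16-bit integers. The offset and read noise are a noise
#' floor and are never bleached.
#'
#' Defaults (zero offset, small read noise) reflect processed
#' super-resolution stacks whose camera baseline has already been removed.
#'
#' @param offset constant detector offset, grey values.
#' @param read_sd Gaussian read-noise standard deviation.
#' @param gain photons per grey value.
#' @return object of class `noise_model`; pass `NULL` for noise-free output.
#' @export
noise_model <- function(offset = 0, read_sd = 10, gain = 1) {
  stopifnot(offset >= 0, read_sd >= 0, gain > 0)
  structure(list(offset = offset, read_sd = read_sd, gain = gain),
            class = "noise_model")
}

apply_noise <- function(expected, noise) {
  if (is.null(noise)) return(expected)
  n <- length(expected)
  counts <- rpois(n, lambda = pmax(noise$gain * expected, 0)) / noise$gain
  v <- counts + rnorm(n, noise$offset, noise$read_sd)
  v <- round(pmin(pmax(v, 0), 65535))
  array(v, dim(expected))
}

#' Per-slice rigid motion jitter model
#'
#' @param max_translation_px maximum |translation| per axis, pixels.
#' @param max_rotation_deg maximum |rotation|, degrees.
#' @return object of class `jitter_model`; `NULL` disables jitter.
#' @export
jitter_model <- function(max_translation_px = 5, max_rotation_deg = 2) {
  stopifnot(max_translation_px >= 0, max_rotation_deg >= 0)
  structure(list(max_translation_px = max_translation_px,
                 max_rotation_deg = max_rotation_deg),
            class = "jitter_model")
}

draw_jitter <- function(jitter, n_slices) {
  data.frame(
    rotation = runif(n_slices, -jitter$max_rotation_deg,
                     jitter$max_rotation_deg),
    ty = runif(n_slices, -jitter$max_translation_px,
               jitter$max_translation_px),
    tx = runif(n_slices, -jitter$max_translation_px,
               jitter$max_translation_px))
}

#' Simulate a two-channel bleaching time series
#'
#' For each materialised acquisition t the noise-free channels are scaled by
#' their bleach multipliers, the red channel bleeds into the green one by
#' `bleedthrough_fraction`, per-slice rigid jitter is applied (identically
#' to both channels), the result is blurred with the PSF and corrupted by
#' the detector noise model. When `post_scene` is given, acquisitions at or
#' after `division_time` use the divided geometry.
#'
#' @param scene a `mito_scene`.
#' @param schedule green-channel [bleach_schedule()].
#' @param psf optional unit-sum PSF kernel (z, y, x).
#' @param bleedthrough_fraction fraction of red excited into the green
#'   channel (default 0.08).
#' @param jitter optional [jitter_model()].
#' @param noise optional [noise_model()].
#' @param red_schedule optional red-channel schedule (defaults to the green
#'   schedule's timing with a 0.0413/min rate).
#' @param rng_seed integer; fixes every random draw.
#' @param materialise integer vector of acquisition indices to render
#'   (default all). Multipliers are always drawn for the full schedule so a
#'   subset is consistent with the full series.
#' @param post_scene optional divided `mito_scene` used from
#'   `division_time` on.
#' @param division_time acquisition index at which division has completed
#'   (default the last).
#' @return list with `stack` (array t, c, z, y, x over materialised
#'   acquisitions; channel 1 red, channel 2 green), `time_min`,
#'   `timepoints`, and `truth` (multipliers, per-slice transforms, label
#'   volumes and foreground counts per materialised acquisition, seed).
#' @export
simulate_timeseries <- function(scene, schedule, psf = NULL,
                                bleedthrough_fraction = 0.08,
                                jitter = NULL, noise = noise_model(),
                                red_schedule = NULL, rng_seed = 1L,
                                materialise = NULL, post_scene = NULL,
                                division_time = NULL) {
  stopifnot(inherits(scene, "mito_scene"), inherits(schedule, "bleach_schedule"),
            bleedthrough_fraction >= 0, bleedthrough_fraction < 1)
  if (!is.null(psf)) {
    stopifnot(abs(sum(psf) - 1) < 1e-6, all(psf >= 0))
  }
  set.seed(as.integer(rng_seed))
  nt <- schedule$n_timepoints
  if (is.null(materialise)) materialise <- seq_len(nt)
  stopifnot(all(materialise >= 1), all(materialise <= nt))
  if (is.null(division_time)) division_time <- nt
  if (is.null(red_schedule))
    red_schedule <- bleach_schedule(0.0413, schedule$interval_s, nt,
                                    schedule$fluctuation_sd, schedule$step_cap)

  mult_g <- bleach_multipliers(schedule)
  mult_r <- bleach_multipliers(red_schedule)

  dims <- scene$spec$fov_shape
  nz <- dims[1]
  out <- array(0, c(length(materialise), 2L, dims))
  transforms <- vector("list", length(materialise))
  label_list <- vector("list", length(materialise))
  fg <- integer(length(materialise))

  for (i in seq_along(materialise)) {
    t <- materialise[i]
    geo <- if (!is.null(post_scene) && t >= division_time) post_scene else scene
    green <- mult_g[t] * geo$green + bleedthrough_fraction * mult_r[t] * geo$red
    red <- mult_r[t] * geo$red
    lab <- geo$labels
    if (!is.null(jitter)) {
      tf <- draw_jitter(jitter, nz)
      green <- apply_transforms(green, tf, interp = "linear")
      red <- apply_transforms(red, tf, interp = "linear")
      lab <- apply_transforms(lab, tf, interp = "nearest")
      transforms[[i]] <- tf
    } else {
      transforms[[i]] <- data.frame(rotation = numeric(nz), ty = numeric(nz),
                                    tx = numeric(nz))
    }
    if (!is.null(psf)) {
      green <- fft_convolve(green, psf)
      red <- fft_convolve(red, psf)
    }
    out[i, 1, , , ] <- apply_noise(red, noise)
    out[i, 2, , , ] <- apply_noise(green, noise)
    label_list[[i]] <- lab
    fg[i] <- sum(lab > 0L)
  }

  list(stack = out,
       timepoints = materialise,
       time_min = (materialise - 1) * schedule$interval_s / 60,
       truth = list(multipliers_green = mult_g, multipliers_red = mult_r,
                    transforms = transforms, labels = label_list,
                    true_foreground_voxels = fg, rng_seed = as.integer(rng_seed)))
}

#' Per-slice cell outline ROIs for a scene
#'
#' Builds, for every z slice intersecting each cell ellipsoid, a polygon
#' approximating the cell cross-section (slightly dilated so blurred signal
#' near the membrane stays inside).
#'
#' @param scene a `mito_scene` (one or two cells).
#' @param dilate_um outward margin added to the cross-section radii, um.
#' @param n_vertices polygon vertices.
#' @return a `roi_set`: list with `slices` (1-based z indices) and
#'   `polygons` (for each slice, a list of polygon matrices with columns
#'   x, y in 0-based pixel coordinates).
#' @export
scene_rois <- function(scene, dilate_um = 0.3, n_vertices = 48) {
  spec <- scene$spec
  dims <- spec$fov_shape
  vox <- spec$voxel_size
  zc <- axis_coords(dims[1], vox[1])
  slices <- integer(0)
  polys <- list()
  for (zi in seq_len(dims[1])) {
    pl <- list()
    for (cell in scene$cells) {
      dz <- (zc[zi] - cell$centre[3]) / cell$semi[3]
      if (abs(dz) >= 1) next
      sc <- sqrt(1 - dz^2)
      rx <- cell$semi[1] * sc + dilate_um
      ry <- cell$semi[2] * sc + dilate_um
      pl[[length(pl) + 1]] <-
        ellipse_polygon(cell$centre[1] / vox[3] - 0.5,
                        cell$centre[2] / vox[2] - 0.5,
                        rx / vox[3], ry / vox[2], n = n_vertices)
    }
    if (length(pl)) {
      slices <- c(slices, zi)
      polys[[length(polys) + 1]] <- pl
    }
  }
  roi_set(slices, polys)
}
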