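# Global-threshold segmentation (Isodata / legacy ImageJ Default / Otsu /
# mean), an Imaris-Surface-like chain, polygonal ROI masking, connected
# components, and object quantification in 2D and 3D.

#' Global threshold of a histogram
#'
#' Operates on a grey-level histogram whose bin i spans
#' `[x_min + i*width, x_min + (i+1)*width)`, i = 0..n-1. Algorithms:
#' \describe{
#'   \item{isodata}{Ridler-Calvard iterated intermeans: starting from the
#'     midpoint bin, iterate `t <- round((mu_below + mu_above) / 2)` (means
#'     of bin indices at or below / above t, round half up) to its fixed
#'     point.}
#'   \item{imagej_default}{the legacy ImageJ variant: the extreme end bins
#'     are ignored, then the intermeans condition is swept upward from the
#'     lowest occupied bin until the moving index passes the intermean.}
#'   \item{otsu}{maximiser of the between-class variance.}
#'   \item{mean}{the histogram mean.}
#' }
#' The returned grey value is `x_min + t * width`, which makes the
#' threshold exactly equivariant under multiplicative intensity scaling
#' when the histogram range scales with the data.
#'
#' @param counts numeric vector of bin counts.
#' @param x_min grey value of the lower edge of bin 0.
#' @param width bin width in grey values.
#' @param algorithm one of `"isodata"`, `"imagej_default"`, `"otsu"`,
#'   `"mean"`.
#' @return list of class `threshold_result`: `algorithm`, `value` (grey
#'   value), `bin` (index, 0-based).
#' @export
global_threshold_hist <- function(counts, x_min = 0, width = 1,
                                  algorithm = c("isodata", "imagej_default",
                                                "otsu", "mean")) {
  algorithm <- match.arg(algorithm)
  n <- length(counts)
  occ <- which(counts > 0)
  if (length(occ) < 2)
    stop("no threshold exists: fewer than two occupied grey levels")
  i <- seq_len(n) - 1  # bin indices
  t <- switch(algorithm,
    isodata = {
      lo <- occ[1] - 1; hi <- occ[length(occ)] - 1
      tt <- floor((lo + hi) / 2)
      for (k in 1:1000) {
        below <- counts[i <= tt]; ib <- i[i <= tt]
        above <- counts[i > tt]; ia <- i[i > tt]
        if (sum(below) == 0) { tt <- tt + 1; next }
        if (sum(above) == 0) { tt <- tt - 1; next }
        mb <- sum(ib * below) / sum(below)
        ma <- sum(ia * above) / sum(above)
        t_new <- floor((mb + ma) / 2 + 0.5)  # round half up
        if (t_new == tt) break
        tt <- t_new
      }
      tt
    },
    imagej_default = {
      cc <- counts
      cc[1] <- 0; cc[n] <- 0         # ignore count-dominant end bins
      occ2 <- which(cc > 0)
      if (length(occ2) < 2)
        stop("no threshold exists: fewer than two occupied grey levels")
      mn <- occ2[1] - 1; mx <- occ2[length(occ2)] - 1
      mov <- mn
      res <- NA_real_
      repeat {
        s1 <- sum(i[i >= mn & i <= mov] * cc[i >= mn & i <= mov])
        s2 <- sum(cc[i >= mn & i <= mov])
        s3 <- sum(i[i > mov & i <= mx] * cc[i > mov & i <= mx])
        s4 <- sum(cc[i > mov & i <= mx])
        res <- (if (s2 > 0) s1 / s2 else mov) / 2 +
          (if (s4 > 0) s3 / s4 else mov) / 2
        mov <- mov + 1
        if (!((mov + 1) <= res && mov < mx - 1)) break
      }
      floor(res + 0.5)
    },
    otsu = {
      p <- counts / sum(counts)
      omega <- cumsum(p)
      mu <- cumsum(p * i)
      mu_t <- mu[n]
      sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
      sb2[!is.finite(sb2)] <- -Inf
      cand <- seq_len(n - 1)
      cand[which.max(sb2[cand])] - 1
    },
    mean = sum(i * counts) / sum(counts)
  )
  structure(list(algorithm = algorithm, value = x_min + t * width, bin = t),
            class = "threshold_result")
}

#' Global threshold of an image stack
#'
#' Builds a whole-stack histogram with `n_bins` classes over the stack's
#' min-max range (the "stack histogram" convention) and thresholds it with
#' [global_threshold_hist()]. Foreground is every voxel strictly above the
#' returned grey value.
#'
#' @param vol numeric array (any shape).
#' @param algorithm threshold algorithm, see [global_threshold_hist()].
#' @param n_bins number of histogram classes (default 256).
#' @return `threshold_result` with extra fields `x_min`, `x_max`, `width`,
#'   `foreground_count`.
#' @export
global_threshold <- function(vol, algorithm = "isodata", n_bins = 256L) {
  rng <- range(vol)
  if (rng[1] == rng[2])
    stop("no threshold exists: constant image")
  w <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((vol - rng[1]) / w), n_bins - 1)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  res <- global_threshold_hist(counts, x_min = rng[1], width = w,
                               algorithm = algorithm)
  res$x_min <- rng[1]; res$x_max <- rng[2]; res$width <- w
  res$foreground_count <- sum(vol > res$value)
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Global threshold (%s): %.4g", x$algorithm, x$value))
  if (!is.null(x$foreground_count))
    cat(sprintf("  [%d foreground voxels]", x$foreground_count))
  cat("\n")
  invisible(x)
}

#' Label connected components
#'
#' @param mask logical/0-1 array, 2D or 3D (z, y, x).
#' @param connectivity 26 (3D, default) or 6; a single-slice input with 26
#'   reduces to 8-connectivity in 2D.
#' @return integer array of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(1L, d)
  lab <- label_components_cpp(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  n <- attr(lab, "n_labels")
  dim(lab) <- dim(mask)
  attr(lab, "n_labels") <- n
  lab
}

# Surface area of a binary object via the coarea formula: smooth the
# indicator and integrate the gradient magnitude (physical units).
surface_area_coarea <- function(mask, voxel_size, sigma_vox = 1.2) {
  d <- dim(mask)
  pad <- pmin(4L, d - 1L)
  f <- pad_array(array(as.numeric(mask), d), pad, mode = "zero")
  f <- gauss_blur3d(f, sigma_um = sigma_vox * min(voxel_size),
                    voxel_size = voxel_size)
  dd <- dim(f)
  gz <- (f[c(2:dd[1], dd[1]), , ] - f[c(1, 1:(dd[1] - 1)), , ]) /
    (2 * voxel_size[1])
  gy <- (f[, c(2:dd[2], dd[2]), ] - f[, c(1, 1:(dd[2] - 1)), ]) /
    (2 * voxel_size[2])
  gx <- (f[, , c(2:dd[3], dd[3])] - f[, , c(1, 1:(dd[3] - 1))]) /
    (2 * voxel_size[3])
  sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(voxel_size)
}

#' Measure labelled objects
#'
#' 3D mode: 26-connected objects with voxel counts, physical volumes,
#' centroids, surface areas (coarea estimate on the smoothed indicator) and
#' sphericity `pi^(1/3) (6V)^(2/3) / A`. 2D mode: per-slice 8-connected
#' particle areas, summed into the total pixel quantity and converted with
#' the pixel content of a square micrometre (`(1/pixel)^2`, i.e. 553.63
#' pixels at 42.5 nm).
#'
#' @param x binary mask or integer label array (z, y, x); masks are
#'   labelled internally.
#' @param voxel_size numeric triple (z, y, x), um.
#' @param mode `"3d"` or `"2d"`.
#' @return list of class `segmentation_result`: `objects` (data.frame),
#'   `total_quantity` (voxels or pixels), `total_volume_um3` or
#'   `total_area_um2`, `pixels_per_um2` (2D), `mode`.
#' @export
measure_objects <- function(x, voxel_size = c(0.130, 0.0425, 0.0425),
                            mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (length(d) == 2) { dim(x) <- c(1L, d); d <- dim(x) }
  is_labels <- is.integer(x) && max(x) > 1

  if (mode == "3d") {
    labels <- if (is_labels) x else label_components(x != 0, 26)
    ids <- sort(unique(labels[labels > 0]))
    vv <- prod(voxel_size)
    rows <- lapply(ids, function(id) {
      sel <- labels == id
      cnt <- sum(sel)
      idx <- which(sel, arr.ind = TRUE)
      area <- surface_area_coarea(sel, voxel_size)
      vol <- cnt * vv
      data.frame(label = id, voxel_count = cnt, volume_um3 = vol,
                 surface_um2 = area,
                 sphericity = min(pi^(1 / 3) * (6 * vol)^(2 / 3) / area, 1),
                 centroid_z = mean(idx[, 1]), centroid_y = mean(idx[, 2]),
                 centroid_x = mean(idx[, 3]))
    })
    objects <- if (length(rows)) do.call(rbind, rows) else
      data.frame(label = integer(), voxel_count = integer(),
                 volume_um3 = numeric(), surface_um2 = numeric(),
                 sphericity = numeric(), centroid_z = numeric(),
                 centroid_y = numeric(), centroid_x = numeric())
    structure(list(objects = objects,
                   total_quantity = sum(objects$voxel_count),
                   total_volume_um3 = sum(objects$volume_um3),
                   mode = "3d", voxel_size = voxel_size),
              class = "segmentation_result")
  } else {
    px <- voxel_size[3]
    ppu <- pixels_per_um2(px)
    rows <- list()
    total_px <- 0L
    for (z in seq_len(d[1])) {
      sl <- x[z, , ]
      if (!any(sl != 0)) next
      lab <- label_components(sl != 0, 26)  # 8-connectivity in 2D
      for (id in seq_len(attr(lab, "n_labels"))) {
        a <- sum(lab == id)
        total_px <- total_px + a
        rows[[length(rows) + 1]] <-
          data.frame(slice = z, label = id, pixel_count = a,
                     area_um2 = a / ppu)
      }
    }
    objects <- if (length(rows)) do.call(rbind, rows) else
      data.frame(slice = integer(), label = integer(),
                 pixel_count = integer(), area_um2 = numeric())
    structure(list(objects = objects, total_quantity = total_px,
                   total_area_um2 = total_px / ppu,
                   pixels_per_um2 = ppu, mode = "2d",
                   voxel_size = voxel_size),
              class = "segmentation_result")
  }
}

#' Pixel content of a square micrometre
#' @param pixel_size_um pixel edge, um.
#' @return `(1 / pixel_size_um)^2`, e.g. 553.63 pixels at 0.0425 um.
#' @export
pixels_per_um2 <- function(pixel_size_um) (1 / pixel_size_um)^2

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation (%s): %d objects, total quantity %d %s\n",
              x$mode, nrow(x$objects), x$total_quantity,
              if (x$mode == "3d") "voxels" else "pixels"))
  if (x$mode == "3d")
    cat(sprintf("  total volume %.4f um^3\n", x$total_volume_um3))
  else
    cat(sprintf("  total area %.4f um^2 (%.2f px/um^2)\n",
                x$total_area_um2, x$pixels_per_um2))
  invisible(x)
}

#' Imaris-Surface-like segmentation chain
#'
#' Mirrors the Surface-creation pipeline: (1) Gaussian smoothing with a
#' sigma tied to the surface grain size, skipped when the grain size is
#' sub-voxel; (2) background elimination by subtracting a Gaussian baseline
#' whose sigma is the diameter of the largest imaged sphere; (3) automatic
#' global threshold (Isodata family) inside the region of interest;
#' (4) 26-connected labelling; (5) per-object statistics.
#'
#' @param vol 3D array (z, y, x).
#' @param voxel_size numeric triple (z, y, x), um.
#' @param grain_size surface grain size, um (default 0.001: sub-voxel,
#'   hence smoothing is off).
#' @param largest_sphere_diameter baseline sigma, um (default 0.319).
#' @param roi_box optional crop box (see [crop_roi()]) applied before
#'   thresholding.
#' @param algorithm threshold algorithm.
#' @return list with `segmentation` (a `segmentation_result`), `threshold`
#'   (a `threshold_result`), and `mask`.
#' @export
imaris_like_surface <- function(vol, voxel_size = c(0.130, 0.0425, 0.0425),
                                grain_size = 0.001,
                                largest_sphere_diameter = 0.319,
                                roi_box = NULL, algorithm = "isodata") {
  stopifnot(length(dim(vol)) == 3, all(voxel_size > 0))
  work <- vol
  if (grain_size >= min(voxel_size) / 2)
    work <- gauss_blur3d(work, grain_size, voxel_size)
  baseline <- gauss_blur3d(work, largest_sphere_diameter, voxel_size)
  work <- pmax(work - baseline, 0)
  if (!is.null(roi_box)) work <- crop_roi(work, roi_box)
  thr <- global_threshold(work, algorithm = algorithm)
  mask <- work > thr$value
  seg <- measure_objects(label_components(mask, 26), voxel_size, mode = "3d")
  list(segmentation = seg, threshold = thr, mask = mask)
}

#' Per-slice polygonal ROI set
#'
#' @param slices 1-based z indices carrying ROIs.
#' @param polygons for each slice, a list of polygon matrices (columns x, y
#'   in 0-based pixel coordinates).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(slices, polygons) {
  stopifnot(length(slices) == length(polygons), length(slices) >= 1)
  structure(list(slices = as.integer(slices), polygons = polygons),
            class = "roi_set")
}

roi_slice_mask <- function(rois, slice, ny, nx) {
  k <- match(slice, rois$slices)
  if (is.na(k)) return(matrix(FALSE, ny, nx))
  m <- matrix(FALSE, ny, nx)
  for (poly in rois$polygons[[k]])
    m <- m | rasterise_polygon(poly, ny, nx)
  m
}

#' Clear mask voxels outside per-slice ROIs
#'
#' Pixels outside the polygon(s) of their slice are set to background, and
#' slices outside the ROI slice range are dropped (the duplicate-by-range
#' convention).
#'
#' @param mask logical or numeric 3D array (z, y, x).
#' @param rois a [roi_set()].
#' @return the masked array restricted to `min(slices):max(slices)`, with
#'   attribute `slice_offset` (number of leading slices dropped).
#' @export
mask_outside_rois <- function(mask, rois) {
  if (!inherits(rois, "roi_set") || length(rois$slices) == 0)
    stop("empty ROI set")
  d <- dim(mask)
  stopifnot(length(d) == 3, all(rois$slices >= 1), all(rois$slices <= d[1]))
  zr <- range(rois$slices)
  out <- mask[zr[1]:zr[2], , , drop = FALSE]
  bg <- if (is.logical(mask)) FALSE else 0
  for (z in zr[1]:zr[2]) {
    m <- roi_slice_mask(rois, z, d[2], d[3])
    sl <- out[z - zr[1] + 1, , ]
    sl[!m] <- bg
    out[z - zr[1] + 1, , ] <- sl
  }
  attr(out, "slice_offset") <- zr[1] - 1L
  out
}
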