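# Internal numerical helpers shared across modules: FFT convolution with
# boundary padding, Gaussian kernels, and polygon rasterisation.

#' @useDynLib mitoquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate coef confint cor.test fft kruskal.test lm
#'   median optim p.adjust pf predict residuals rnorm rpois runif sd
#'   shapiro.test smooth.spline t.test wilcox.test quantile
#' @importFrom graphics abline legend plot
#' @importFrom utils head packageVersion read.table tail write.csv
#'   write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# reflect-pad an array by `pad` voxels per axis (vector, one entry per dim)
pad_array <- function(x, pad, mode = c("reflect", "zero")) {
  mode <- match.arg(mode)
  d <- dim(x)
  stopifnot(length(pad) == length(d), all(pad >= 0), all(pad < d))
  idx <- lapply(seq_along(d), function(k) {
    n <- d[k]; p <- pad[k]
    if (p == 0) return(seq_len(n))
    if (mode == "reflect") c(seq(p, 1), seq_len(n), seq(n, n - p + 1)) else NULL
  })
  if (mode == "reflect") {
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  } else {
    out <- array(0, d + 2 * pad)
    core <- lapply(seq_along(d), function(k) seq(pad[k] + 1, pad[k] + d[k]))
    out <- do.call(`[<-`, c(list(out), core, list(value = x)))
    out
  }
}

crop_core <- function(x, pad) {
  d <- dim(x)
  core <- lapply(seq_along(d), function(k) seq(pad[k] + 1, d[k] - pad[k]))
  do.call(`[`, c(list(x), core, list(drop = FALSE)))
}

# embed an odd-sized kernel into an array of dims `d` with its centre wrapped
# to the [1,1,...] corner, so that circular FFT convolution is centred
embed_kernel <- function(kernel, d) {
  kd <- dim(kernel)
  stopifnot(all(kd %% 2 == 1), all(kd <= d))
  out <- array(0, d)
  ctr <- (kd + 1) / 2
  idx_out <- lapply(seq_along(d), function(k) {
    off <- seq_len(kd[k]) - ctr[k]        # -h .. h
    ((off) %% d[k]) + 1
  })
  g <- as.matrix(expand.grid(idx_out))
  ko <- as.matrix(expand.grid(lapply(kd, seq_len)))
  out[g] <- kernel[ko]
  out
}

# circular convolution via FFT (kernel centred)
fft_convolve_circular <- function(x, kernel) {
  d <- dim(x)
  k0 <- embed_kernel(kernel, d)
  out <- Re(fft(fft(x) * fft(k0), inverse = TRUE)) / prod(d)
  out
}

#' Convolve a volume with a centred kernel
#'
#' FFT-based linear convolution with reflective (default) or zero boundary
#' padding by the kernel half-width. Kernel dimensions must be odd.
#'
#' @param x numeric array (any dimensionality matching `kernel`).
#' @param kernel numeric array with odd dimensions.
#' @param pad boundary handling, `"reflect"` or `"zero"`.
#' @return array of the same shape as `x`.
#' @keywords internal
fft_convolve <- function(x, kernel, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  h <- (dim(kernel) - 1) / 2
  h <- pmin(h, dim(x) - 1)
  xp <- pad_array(x, h, mode = pad)
  out <- fft_convolve_circular(xp, kernel)
  crop_core(out, h)
}

# 1D gaussian taps, sigma in voxels
gauss_taps <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian blur of a 3D volume with anisotropic voxels
#'
#' Sigma is given in physical units and converted per axis with the voxel
#' size, so the blur is isotropic in space. Axes where the converted sigma
#' is below 0.2 voxels are skipped.
#'
#' @param vol 3D array ordered (z, y, x).
#' @param sigma_um physical standard deviation in micrometres.
#' @param voxel_size numeric triple (z, y, x) in micrometres.
#' @param pad boundary handling passed to the convolution.
#' @return blurred array, same shape.
#' @export
gauss_blur3d <- function(vol, sigma_um, voxel_size, pad = "reflect") {
  stopifnot(length(dim(vol)) == 3, sigma_um >= 0, all(voxel_size > 0))
  if (sigma_um == 0) return(vol)
  sig_vox <- sigma_um / voxel_size
  taps <- lapply(seq_along(sig_vox), function(k) {
    s <- sig_vox[k]
    half <- (dim(vol)[k] - 1) %/% 2
    if (s < 0.2 || half < 1) array(1, 1L)
    else gauss_taps(s, radius = min(max(1L, ceiling(3 * s)), half))
  })
  kern <- outer(outer(taps[[1]], taps[[2]]), taps[[3]])
  dim(kern) <- c(length(taps[[1]]), length(taps[[2]]), length(taps[[3]]))
  fft_convolve(vol, kern, pad = pad)
}

# Even-odd (ray-casting) point-in-polygon, vectorised over points.
# poly: matrix with columns x, y; px, py: point coordinates (same units).
points_in_polygon <- function(px, py, poly) {
  n <- length(px)
  inside <- logical(n)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py))
    if (any(cross)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      hit <- cross & (px < xint)
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}

# Rasterise one polygon (0-based pixel coordinates, columns x,y) on an
# ny-by-nx pixel grid; returns a logical [y, x] matrix of pixel centres.
rasterise_polygon <- function(poly, ny, nx) {
  cc <- expand.grid(y = seq_len(ny) - 1, x = seq_len(nx) - 1)
  m <- points_in_polygon(cc$x, cc$y, poly)
  matrix(m, nrow = ny, ncol = nx)
}

# regular n-gon approximating an ellipse, 0-based pixel coords
ellipse_polygon <- function(cx, cy, rx, ry, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + rx * cos(th), y = cy + ry * sin(th))
}
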