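# Geometric and diffraction optics for the oil-immersion imaging geometry:
# Snell's-law longitudinal spherical aberration, Rayleigh resolution, and
# theoretical (aberration-free) point spread functions.

#' Optical geometry of the objective / coverglass / specimen system
#'
#' Bundles the constants of the imaging geometry. Defaults describe a 1.4 NA
#' oil-immersion objective (lens radius 198.5 um, working distance plus
#' coverglass 310 um) imaging a cell whose centre appears 2 um below the
#' coverglass, with refractive indices 1.518 (immersion oil), 1.52
#' (coverglass) and 1.37 (specimen).
#'
#' @param r_max objective lens radius, um.
#' @param ol_app working distance + coverglass thickness, um.
#' @param cg_app apparent coverglass-to-object distance, um.
#' @param n_oil,n_glass,n_specimen refractive indices (all > 1).
#' @return an object of class `optical_geometry`. Derived fields (angles in
#'   degrees, lengths in um) are filled by [refraction_chain()].
#' @export
optical_geometry <- function(r_max = 198.5, ol_app = 310, cg_app = 2,
                             n_oil = 1.518, n_glass = 1.52, n_specimen = 1.37) {
  stopifnot(r_max > 0, ol_app > 0, cg_app > 0,
            n_oil > 1, n_glass > 1, n_specimen > 1)
  structure(list(r_max = r_max, ol_app = ol_app, cg_app = cg_app,
                 n_oil = n_oil, n_glass = n_glass, n_specimen = n_specimen),
            class = "optical_geometry")
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Snell's-law chain for longitudinal spherical aberration
#'
#' Propagates the marginal ray through the coverglass/specimen interface to
#' derive the actual coverglass-to-object distance and the positive
#' longitudinal shift (LS) caused by the refractive-index mismatch. The chain
#' is: half-aperture angle theta = arctan(r_max / ol_app); refraction angle
#' theta_r = arcsin(sin(theta) * n_glass / n_specimen); complement angles
#' theta' = 90 - theta and theta'' = 90 - theta_r; hypotenuse H = cg_app /
#' sin(theta'); lateral offset L = H * sin(theta); refracted hypotenuse
#' H' = L / sin(theta_r); actual distance cg_act = H' * sin(theta''); and
#' LS = cg_app - cg_act.
#'
#' @param geom an [optical_geometry()].
#' @param rounded logical; when `TRUE`, each intermediate sine is rounded to
#'   two decimals (and the index ratio to four), reproducing the published
#'   worked-example arithmetic for regression purposes.
#' @param hprime `"computed"` derives H' = L / sin(theta_r); `"published"`
#'   (the default in rounded mode) substitutes the published intermediate
#'   value 2.137 um, which is slightly inconsistent with its own formula
#'   (1.286 / 0.60 = 2.143) but is what downstream published values
#'   propagate from. Only honoured for the default geometry scale.
#' @return the geometry with derived fields `theta`, `theta_r`, `theta_prime`,
#'   `theta_doubleprime` (degrees), `h`, `l`, `h_prime`, `cg_act`, `ls` (um)
#'   filled, plus `rounded`.
#' @export
refraction_chain <- function(geom, rounded = FALSE,
                             hprime = if (rounded) "published" else "computed") {
  stopifnot(inherits(geom, "optical_geometry"))
  hprime <- match.arg(hprime, c("computed", "published"))
  r2 <- function(x) if (rounded) round(x, 2) else x

  theta <- atan(geom$r_max / geom$ol_app)
  sin_t <- r2(sin(theta))
  ratio <- if (rounded) round(geom$n_glass / geom$n_specimen, 4) else
    geom$n_glass / geom$n_specimen
  s_r <- sin_t * ratio
  if (s_r >= 1)
    stop("total internal reflection regime: sin(theta) * n_glass/n_specimen >= 1")
  theta_r <- asin(s_r)
  theta_prime <- pi / 2 - theta
  theta_dd <- pi / 2 - theta_r

  h <- geom$cg_app / r2(sin(theta_prime))
  l <- h * sin_t
  h_prime <- l / r2(sin(theta_r))
  if (hprime == "published") {
    # published intermediate for the 2-um default; scales with cg_app
    h_prime <- 2.137 * geom$cg_app / 2
  }
  cg_act <- h_prime * r2(sin(theta_dd))
  ls <- geom$cg_app - cg_act

  geom$theta <- rad2deg(theta)
  geom$theta_r <- rad2deg(theta_r)
  geom$theta_prime <- rad2deg(theta_prime)
  geom$theta_doubleprime <- rad2deg(theta_dd)
  geom$h <- h
  geom$l <- l
  geom$h_prime <- h_prime
  geom$cg_act <- cg_act
  geom$ls <- ls
  geom$rounded <- rounded
  geom
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat("Optical geometry (oil/glass/specimen RI:",
      x$n_oil, "/", x$n_glass, "/", x$n_specimen, ")\n")
  cat(sprintf("  r_max %.1f um, OL-APP %.0f um, CG-APP %.3f um\n",
              x$r_max, x$ol_app, x$cg_app))
  if (!is.null(x$ls)) {
    cat(sprintf("  theta %.2f deg, theta_r %.2f deg\n", x$theta, x$theta_r))
    cat(sprintf("  H %.3f um, L %.3f um, H' %.3f um\n", x$h, x$l, x$h_prime))
    cat(sprintf("  CG-ACT %.3f um, LS %.3f um%s\n", x$cg_act, x$ls,
                if (isTRUE(x$rounded)) "  (rounded mode)" else ""))
  }
  invisible(x)
}

#' Longitudinal shift at a given depth
#'
#' The longitudinal spherical aberration grows proportionally with the
#' distance between the coverglass and the focal plane, so the shift at an
#' arbitrary depth is `ls * depth / cg_app`.
#'
#' @param geom an [optical_geometry()] with derived fields (the chain is run
#'   if missing).
#' @param depth depth(s) below the coverglass, um (>= 0).
#' @return shift in um, vectorised over `depth`.
#' @export
longitudinal_shift_at_depth <- function(geom, depth) {
  stopifnot(all(depth >= 0))
  if (is.null(geom$ls)) geom <- refraction_chain(geom)
  geom$ls * depth / geom$cg_app
}

#' Rayleigh resolution in pixels
#'
#' `coefficient * lambda / NA` converted to detector pixels. The default
#' coefficient 0.6 (rather than the textbook 0.61) reproduces the reference
#' instrument's predicted radii of 5.14 px at 510 nm and 6.15 px at 610 nm
#' with 42.5 nm pixels.
#'
#' @param wavelength_nm emission wavelength, nm.
#' @param na numerical aperture.
#' @param pixel_nm pixel size, nm.
#' @param coefficient Rayleigh prefactor.
#' @return radius in pixels.
#' @export
rayleigh_radius_px <- function(wavelength_nm, na = 1.4, pixel_nm = 42.5,
                               coefficient = 0.6) {
  stopifnot(wavelength_nm > 0, na > 0, pixel_nm > 0, coefficient > 0)
  coefficient * wavelength_nm / na / pixel_nm
}

#' Theoretical aberration-free 3D point spread function
#'
#' Scalar paraxial (Born-Wolf without aberration terms) diffraction kernel:
#' the intensity at lateral radius r and defocus z is
#' `|int_0^1 J0(k NA r rho) exp(-i k NA^2 z rho^2 / (2 n)) rho drho|^2`
#' with `k = 2 pi / lambda`. At focus this is the Airy pattern; the kernel is
#' radially symmetric in xy, mirror-symmetric in z, and normalised to unit
#' sum.
#'
#' @param wavelength_nm emission wavelength, nm.
#' @param na numerical aperture.
#' @param voxel_size numeric triple (z, y, x), um.
#' @param shape odd integer triple (z, y, x) kernel size in voxels.
#' @param n_immersion refractive index used in the defocus term.
#' @param n_rho number of pupil-integration nodes.
#' @return array of dim `shape`, non-negative, summing to 1.
#' @export
theoretical_psf <- function(wavelength_nm, na = 1.4,
                            voxel_size = c(0.130, 0.0425, 0.0425),
                            shape = c(9L, 25L, 25L),
                            n_immersion = 1.518, n_rho = 96) {
  stopifnot(length(shape) == 3, all(shape %% 2 == 1), all(shape >= 1),
            all(voxel_size > 0), na < n_immersion)
  lambda <- wavelength_nm / 1000   # um
  airy_r <- 0.61 * lambda / na
  if ((shape[3] - 1) / 2 * voxel_size[3] < airy_r ||
      (shape[2] - 1) / 2 * voxel_size[2] < airy_r)
    warning("kernel extent smaller than the first Airy minimum (",
            round(airy_r, 3), " um); PSF will be truncated")

  hz <- (shape[1] - 1) / 2; hy <- (shape[2] - 1) / 2; hx <- (shape[3] - 1) / 2
  z <- (-hz:hz) * voxel_size[1]
  y <- (-hy:hy) * voxel_size[2]
  x <- (-hx:hx) * voxel_size[3]
  g <- expand.grid(z = z, y = y, x = x)
  r <- sqrt(g$y^2 + g$x^2)
  k <- 2 * pi / lambda

  rho <- seq(0, 1, length.out = n_rho)
  w <- rep(1, n_rho); w[c(1, n_rho)] <- 0.5
  w <- w * (rho[2] - rho[1])          # trapezoid weights

  # J0 depends only on (r, rho); defocus phase only on (z, rho)
  Jr <- outer(r, rho, function(rr, p) besselJ(k * na * rr * p, 0))
  Pz <- exp(-1i * k * na^2 / (2 * n_immersion) * outer(g$z, rho^2))
  amp <- (Jr * Pz) %*% (w * rho)
  psf <- Mod(amp)^2
  psf <- array(psf, dim = shape)
  psf / sum(psf)
}

#' Apparent axial inflation from depth-dependent longitudinal shift
#'
#' Models the cell as an ellipsoid whose apparent axial extent spans depths
#' `[d0, d0 + thickness_apparent]` below the coverglass. Because the
#' longitudinal shift grows with depth, the bottom surface is displaced more
#' than the top, so the actual axial extent is the apparent one minus the LS
#' span, and the apparent volume overestimates the actual volume by the
#' ratio of the axial semi-axes.
#'
#' @param thickness_apparent apparent axial extent, um.
#' @param geom an [optical_geometry()] (chain run if needed).
#' @param depth_top depth of the top surface below the coverglass, um;
#'   default places the cell centre at `cg_app`.
#' @return fractional volume inflation (apparent/actual - 1).
#' @export
apparent_inflation <- function(thickness_apparent, geom, depth_top = NULL) {
  stopifnot(thickness_apparent > 0)
  if (is.null(geom$ls)) geom <- refraction_chain(geom)
  if (is.null(depth_top)) depth_top <- geom$cg_app - thickness_apparent / 2
  stopifnot(depth_top >= 0)
  depth_bottom <- depth_top + thickness_apparent
  span <- longitudinal_shift_at_depth(geom, depth_bottom) -
    longitudinal_shift_at_depth(geom, depth_top)
  if (span >= thickness_apparent)
    stop("longitudinal-shift span (", round(span, 3),
         " um) is not smaller than the apparent thickness")
  thickness_apparent / (thickness_apparent - span) - 1
}
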