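# Planar normal sections: the vertical cutting-plane construction used to
# evaluate stress-fiber paths at an azimuth theta around the surface normal.

#' Construct a section profile
#'
#' A planar normal-section curve through a surface point: the intersection of
#' the surface with a vertical plane at azimuth `theta`. Stress fibers are
#' modelled as following these planar sections.
#'
#' @param center Length-2 numeric, the (x, y) point the section passes
#'   through (um).
#' @param theta_deg Azimuth of the cutting plane (deg, measured from +x).
#' @param t In-plane horizontal coordinate of samples, centred on 0 (um).
#' @param z Elevation along the section (um).
#' @param kappa Signed curvature at the samples (1/um); ridge tops positive.
#' @param s Arc length at the samples (um), `s = 0` at the centre sample.
#' @return Object of class `section_profile` with the above fields plus
#'   `chord` (3D end-to-end distance, um) and `contour` (arc length, um).
#' @export
section_profile <- function(center, theta_deg, t, z, kappa, s) {
  stopifnot(length(t) == length(z), length(z) == length(kappa),
            length(s) == length(z))
  chord <- sqrt((t[length(t)] - t[1])^2 + (z[length(z)] - z[1])^2)
  contour <- s[length(s)] - s[1]
  if (contour < chord - 1e-9 * max(1, chord))
    stop("section_profile: contour length below chord length")
  structure(list(center = center, theta_deg = theta_deg, t = t, z = z,
                 kappa = kappa, s = s, chord = chord, contour = contour),
            class = "section_profile")
}

#' @export
print.section_profile <- function(x, ...) {
  cat(sprintf(
    "section_profile at (%.4g, %.4g) um, theta = %g deg\n  %d samples, contour %.4g um, chord %.4g um, kappa(0) = %.4g 1/um\n",
    x$center[1], x$center[2], x$theta_deg, length(x$s), x$contour, x$chord,
    profile_center_curvature(x)))
  invisible(x)
}

#' Signed curvature of a profile at its centre sample
#'
#' @param profile A `section_profile`.
#' @return Curvature (1/um) at `s = 0`.
#' @export
profile_center_curvature <- function(profile) {
  profile$kappa[which.min(abs(profile$s))]
}

#' Extract a planar normal-section profile from a height field
#'
#' Samples elevation by bilinear interpolation along the line through `center`
#' at azimuth `theta_deg`, computes the signed in-plane curvature
#' `kappa = -z'' / (1 + z'^2)^(3/2)` (positive on ridge tops, negative in
#' troughs) with a 3-sample moving-average smoothing to suppress bilinear
#' interpolation noise, and carries the arc-length parameterization.
#'
#' @param surface A [height_field()].
#' @param center Length-2 numeric (x, y) in um.
#' @param theta_deg Azimuth of the cutting plane (deg).
#' @param half_length Half the horizontal extent of the section (um).
#' @param step Sample spacing along the horizontal coordinate (um).
#' @return A [section_profile()].
#' @examples
#' gr <- make_groove_surface(A = 10, lambda = 80, grid_n = 161, spacing = 1)
#' pr <- normal_section_profile(gr, center = c(80, 80), theta_deg = 90,
#'                              half_length = 20, step = 0.5)
#' profile_center_curvature(pr)  # ~ A (2 pi / lambda)^2 at a ridge top
#' @export
normal_section_profile <- function(surface, center, theta_deg, half_length,
                                   step = 0.5) {
  stopifnot(inherits(surface, "height_field"), half_length > 0, step > 0)
  th <- theta_deg * pi / 180
  t <- seq(-half_length, half_length, by = step)
  if (length(t) < 5L) stop("normal_section_profile: too few samples; reduce step")
  x <- center[1] + t * cos(th)
  y <- center[2] + t * sin(th)
  z <- height_field_interp(surface, x, y)  # errors "section out of bounds"

  # Central differences with a stride of one full grid cell: bilinearly
  # interpolated elevations are piecewise linear, so second differences at
  # sub-grid strides alias toward zero, while at a one-cell stride the
  # interpolation bias cancels. A 3-sample moving average then suppresses
  # the residual sub-cell ripple.
  nst <- max(1L, ceiling(max(surface$dx, surface$dy) / step - 1e-9))
  h <- nst * step
  n <- length(t)
  lo <- function(i) pmax(i - nst, 1L)
  hi <- function(i) pmin(i + nst, n)
  i <- seq_len(n)
  dz <- (z[hi(i)] - z[lo(i)]) / ((hi(i) - lo(i)) * step)
  d2z <- (z[hi(i)] - 2 * z[i] + z[lo(i)]) / h^2
  edge <- i - nst < 1L | i + nst > n
  d2z[edge] <- d2z[which(!edge)[1]] * NA_real_
  # clamp edges to nearest interior estimate
  interior <- which(!edge)
  d2z[i < interior[1]] <- d2z[interior[1]]
  d2z[i > interior[length(interior)]] <- d2z[interior[length(interior)]]
  kappa <- -d2z / (1 + dz^2)^1.5
  kappa <- stats::filter(kappa, rep(1 / 3, 3), sides = 2)
  kappa[1] <- kappa[2]; kappa[length(kappa)] <- kappa[length(kappa) - 1]
  kappa <- as.numeric(kappa)

  ds <- sqrt(diff(t)^2 + diff(z)^2)
  s <- c(0, cumsum(ds))
  s <- s - s[which.min(abs(t))]
  section_profile(center = center, theta_deg = theta_deg, t = t, z = z,
                  kappa = kappa, s = s)
}

#' Constant-curvature arc profile
#'
#' Builds the section profile of a circular arc with uniform signed curvature
#' `kappa` and contour length `length`, used to evaluate layer energies as a
#' function of a single curvature value (energy-versus-curvature curves).
#'
#' @param kappa Signed curvature (1/um); 0 gives a flat segment.
#' @param length Contour length of the arc (um).
#' @param step Arc-length sample spacing (um).
#' @return A [section_profile()] (centre point and azimuth are nominal).
#' @export
arc_profile <- function(kappa, length, step = 0.25) {
  s <- seq(-length / 2, length / 2, by = step)
  if (abs(kappa) < 1e-12) {
    t <- s
    z <- rep(0, length(s))
  } else {
    t <- sin(s * kappa) / kappa
    z <- (cos(s * kappa) - 1) / kappa  # apex at z = 0; convex-up for kappa > 0
  }
  section_profile(center = c(0, 0), theta_deg = 0, t = t, z = z,
                  kappa = rep(kappa, length(s)), s = s)
}

#' Parabolic cap profile of prescribed apex curvature
#'
#' Osculating-paraboloid section `z = -kappa t^2 / 2` over a span, used for
#' isotropic spherical-cap substrates where the normal curvature equals
#' `kappa` in every direction.
#'
#' @param kappa Apex curvature (1/um, positive convex up).
#' @param span Horizontal extent (um); samples cover `[-span/2, span/2]`.
#' @param step Horizontal sample spacing (um).
#' @return A [section_profile()].
#' @export
cap_profile <- function(kappa, span, step = 0.25) {
  t <- seq(-span / 2, span / 2, by = step)
  z <- -kappa * t^2 / 2
  dz <- -kappa * t
  kap <- kappa / (1 + dz^2)^1.5
  ds <- sqrt(diff(t)^2 + diff(z)^2)
  s <- c(0, cumsum(ds))
  s <- s - s[which.min(abs(t))]
  section_profile(center = c(0, 0), theta_deg = 0, t = t, z = z,
                  kappa = kap, s = s)
}
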