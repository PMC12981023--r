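# Synthetic substrate topographies.
#
# The wrinkle generator emulates the morphology produced by solvent-induced
# curvature engineering (dehydration/rehydration buckling of ultrasoft
# gelatin-based hydrogels) statistically, by random-phase spectral synthesis;
# it does not simulate the buckling mechanics. Groove and multiaxial-wave
# surfaces are deterministic analytic constructions used for model
# evaluation.

#' Uniaxial groove surface
#'
#' Sinusoidal grooves running along the x axis (`theta = 0` is the groove /
#' axial direction): `z = A cos(2 pi y / lambda)`, optionally superposed on a
#' gentle parabolic bow `z += -axial_curvature * x^2 / 2` that curves the
#' groove axis. On ridge tops the circumferential curvature is
#' `K_perp = A (2 pi / lambda)^2` (when `axial_curvature = 0`) and the axial
#' curvature is `K_par = axial_curvature`.
#'
#' @param A Groove amplitude (um); peak-to-trough depth is `2 A`.
#' @param lambda Groove wavelength (um); must be at least 4 grid spacings.
#' @param axial_curvature Curvature of the groove axis (1/um, >= 0).
#' @param grid_n Number of grid nodes per side.
#' @param spacing Grid spacing (um).
#' @param name Optional preset tag.
#' @return A [height_field()]; attribute `"center"` holds a ridge-top point
#'   centred in the grid, suitable for landscape evaluation.
#' @examples
#' gr <- make_groove_surface(A = groove_amplitude_for_curvature(0.011, 60),
#'                           lambda = 60)
#' attr(gr, "center")
#' @export
make_groove_surface <- function(A, lambda, axial_curvature = 0,
                                grid_n = 161, spacing = 1, name = NULL) {
  stopifnot(A >= 0, lambda > 0, axial_curvature >= 0)
  if (lambda < 4 * spacing)
    stop("make_groove_surface: lambda unresolvable on this grid (< 4 spacings)")
  x <- (seq_len(grid_n) - 1) * spacing
  y <- (seq_len(grid_n) - 1) * spacing
  xc <- x[ceiling(grid_n / 2)]
  # shift the phase so a ridge top lies on the central grid node
  yc <- y[ceiling(grid_n / 2)]
  z <- outer(y, x, function(yy, xx)
    A * cos(2 * pi * (yy - yc) / lambda) - axial_curvature * (xx - xc)^2 / 2)
  hf <- height_field(z, dx = spacing, dy = spacing, name = name)
  attr(hf, "center") <- c(xc, yc)
  hf
}

#' Groove amplitude for a target ridge-top circumferential curvature
#'
#' Inverts `K_perp = A (2 pi / lambda)^2`.
#'
#' @param K_perp Target ridge-top curvature (1/um).
#' @param lambda Groove wavelength (um).
#' @return Amplitude `A` (um).
#' @export
groove_amplitude_for_curvature <- function(K_perp, lambda) {
  K_perp / (2 * pi / lambda)^2
}

#' Wrinkle-field specification
#'
#' Parameters of the random-phase spectral wrinkle generator.
#'
#' @param lambda_c Characteristic wavelength (um); spectral energy is
#'   concentrated on the annulus `|k| = 2 pi / lambda_c`.
#' @param A Amplitude (um); the surface is rescaled so its peak-to-trough
#'   depth equals `2 A`.
#' @param anisotropy In `[0, 1]`: 0 gives an isotropic labyrinth, 1 perfectly
#'   parallel grooves along `direction_deg`.
#' @param bandwidth Relative radial bandwidth of the spectral annulus.
#' @param direction_deg Groove/axial direction for anisotropic fields (deg).
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param grid_n Grid nodes per side.
#' @param spacing Grid spacing (um).
#' @param name Optional preset tag.
#' @return Object of class `wrinkle_spec`.
#' @export
wrinkle_spec <- function(lambda_c, A, anisotropy = 0, bandwidth = 0.25,
                         direction_deg = 0, seed = 1, grid_n = 128,
                         spacing = 2, name = NULL) {
  stopifnot(lambda_c > 0, A >= 0, anisotropy >= 0, anisotropy <= 1,
            bandwidth > 0, grid_n >= 8)
  if (lambda_c < 4 * spacing)
    stop("wrinkle_spec: lambda_c unresolvable (< 4 grid spacings)")
  structure(list(lambda_c = lambda_c, A = A, anisotropy = anisotropy,
                 bandwidth = bandwidth, direction_deg = direction_deg,
                 seed = seed, grid_n = grid_n, spacing = spacing,
                 name = name),
            class = "wrinkle_spec")
}

# von Mises concentration used to focus spectral energy about one direction;
# smooth map from anisotropy in [0, 1), a = 1 is handled as a hard selection
vm_concentration <- function(a) (2 * a / max(1 - a, 1e-6))^2

#' Random wrinkle surface by spectral synthesis
#'
#' Filters seeded white noise through an annular Gaussian band centred at
#' `2 pi / lambda_c` with relative width `bandwidth`. Anisotropy `a`
#' concentrates spectral energy about `direction_deg` through a von Mises
#' weight `exp(kappa_vm (cos 2(phi - phi0) - 1))` with
#' `kappa_vm = (2 a / (1 - a))^2` (at `a = 1` only the modes propagating
#' perpendicular to the groove direction are kept, giving parallel grooves).
#' The field is rescaled to peak-to-trough depth `2 A` and mean 0.
#'
#' @param spec A [wrinkle_spec()].
#' @return A [height_field()] (deterministic for a fixed spec).
#' @examples
#' hf <- make_wrinkle_surface(wrinkle_spec(lambda_c = 60, A = 5, seed = 7))
#' max(hf$z) - min(hf$z)  # = 10
#' @export
make_wrinkle_surface <- function(spec) {
  stopifnot(inherits(spec, "wrinkle_spec"))
  n <- spec$grid_n
  L <- n * spec$spacing
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / L  # cycles/um
  kx <- matrix(2 * pi * f, n, n, byrow = TRUE)
  ky <- matrix(2 * pi * f, n, n)
  kr <- sqrt(kx^2 + ky^2)
  kc <- 2 * pi / spec$lambda_c
  filt <- exp(-(kr - kc)^2 / (2 * (spec$bandwidth * kc)^2))
  filt[1, 1] <- 0
  phi <- atan2(ky, kx)
  phi0 <- deg2rad(spec$direction_deg)
  if (spec$anisotropy >= 1) {
    # grooves along direction_deg: keep only waves propagating perpendicular
    dphi <- (phi - (phi0 + pi / 2)) %% pi
    sel <- pmin(dphi, pi - dphi) < (pi / 180) / 2
    filt <- filt * sel
  } else if (spec$anisotropy > 0) {
    kap <- vm_concentration(spec$anisotropy)
    filt <- filt * exp(kap * (cos(2 * (phi - (phi0 + pi / 2))) - 1))
  }
  z <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * n), n, n)
    Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (n * n)
  })
  z <- z - mean(z)
  ptt <- max(z) - min(z)
  if (ptt > 0 && spec$A > 0) z <- z * (2 * spec$A / ptt) else z[] <- 0
  height_field(z, dx = spec$spacing, dy = spec$spacing, name = spec$name)
}

#' Constructed multiaxial test surface
#'
#' Superposition of oblique cosine waves
#' `z = sum_i A_i cos(2 pi (x cos d_i + y sin d_i) / lambda_i + phase_i)`.
#' With the default `phases = NULL` the phases are chosen so that every wave
#' crests at the grid centre, which is returned as the designed evaluation
#' point (attribute `"center"`): there the normal curvature at azimuth
#' `theta` is `sum_i A_i (2 pi / lambda_i)^2 cos^2(theta - d_i)`.
#'
#' @param amplitudes Wave amplitudes (um).
#' @param directions_deg Wave propagation directions (deg); at least two
#'   non-orthogonal directions give a genuinely multiaxial surface (a warning
#'   is issued otherwise).
#' @param wavelengths Wavelengths (um), same length.
#' @param phases Optional phases (rad); `NULL` crests all waves at centre.
#' @param grid_n,spacing Grid size and spacing.
#' @param name Optional preset tag.
#' @return A [height_field()] with attribute `"center"`.
#' @export
make_multiaxial_test_surface <- function(amplitudes, directions_deg,
                                         wavelengths, phases = NULL,
                                         grid_n = 161, spacing = 1,
                                         name = NULL) {
  m <- length(amplitudes)
  stopifnot(length(directions_deg) == m, length(wavelengths) == m, m >= 1)
  if (m >= 2) {
    dd <- outer(directions_deg, directions_deg, function(a, b)
      abs(((a - b + 90) %% 180) - 90))
    off <- dd[upper.tri(dd)]
    if (all(abs(off - 90) < 1e-6 | off < 1e-6))
      warning("degenerate: effectively uniaxial/biaxial (all directions mutually orthogonal)")
  }
  x <- (seq_len(grid_n) - 1) * spacing
  xc <- x[ceiling(grid_n / 2)]
  center <- c(xc, xc)
  z <- matrix(0, grid_n, grid_n)
  for (i in seq_len(m)) {
    d <- deg2rad(directions_deg[i])
    k <- 2 * pi / wavelengths[i]
    ph <- if (is.null(phases)) -k * (center[1] * cos(d) + center[2] * sin(d))
          else phases[i]
    z <- z + amplitudes[i] *
      outer(x, x, function(yy, xx) cos(k * (xx * cos(d) + yy * sin(d)) + ph))
  }
  hf <- height_field(z, dx = spacing, dy = spacing, name = name)
  attr(hf, "center") <- center
  hf
}

#' Microgel specification
#'
#' @param diameter Microgel diameter (um).
#' @param amplitude Radial perturbation amplitude (um, max |dr|); must be
#'   below `diameter / 4` (self-intersection guard). 0 gives a smooth sphere.
#' @param l_min,l_max Spherical-harmonic degree band of the perturbation.
#' @param seed Integer seed.
#' @param subdiv Icosphere subdivision level (4 gives 2562 vertices).
#' @param name Optional preset tag.
#' @return Object of class `microgel_spec`.
#' @export
microgel_spec <- function(diameter, amplitude = 0, l_min = 6, l_max = 12,
                          seed = 1, subdiv = 4, name = NULL) {
  stopifnot(diameter > 0, amplitude >= 0, l_min >= 1, l_max >= l_min,
            subdiv >= 1)
  if (amplitude >= diameter / 4)
    stop("microgel_spec: amplitude >= diameter/4 risks self-intersection")
  structure(list(diameter = diameter, amplitude = amplitude, l_min = l_min,
                 l_max = l_max, seed = seed, subdiv = subdiv, name = name),
            class = "microgel_spec")
}

# unit icosphere by repeated edge-midpoint subdivision of an icosahedron
icosphere <- function(subdiv) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_cache[[key]]
      if (!is.null(m)) return(m)
      p <- (vlist[[1]][i, ] + vlist[[1]][j, ]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[1]] <<- rbind(vlist[[1]], p)
      m <- nrow(vlist[[1]])
      mid_cache[[key]] <- m
      m
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; cc <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- vlist[[1]]
    f <- nf
  }
  list(vertices = v, faces = f)
}

# random real spherical-harmonic band sample at directions (theta:
# colatitude, phi: longitude); coefficients i.i.d. normal with
# orthonormalizing weights so every mode contributes comparably
random_sh_band <- function(theta, phi, l_min, l_max) {
  acc <- numeric(length(theta))
  ct <- cos(theta)
  for (l in l_min:l_max) {
    P <- pracma::legendre(l, ct)  # (l+1) x n, rows are m = 0..l
    cf <- stats::rnorm(2 * l + 1)
    acc <- acc + cf[1] * P[1, ]
    for (m in seq_len(l)) {
      nrm <- 1 / sqrt(prod(seq(l - m + 1, l + m)))  # ~ sqrt((l-m)!/(l+m)!)
      acc <- acc + nrm * (cf[2 * m] * P[m + 1, ] * cos(m * phi) +
                            cf[2 * m + 1] * P[m + 1, ] * sin(m * phi))
    }
  }
  acc
}

#' Wrinkled microgel mesh
#'
#' Icosphere of the requested diameter with a seeded random radial
#' perturbation drawn from a spherical-harmonic degree band, rescaled so the
#' maximum radial displacement equals `amplitude`. Emulates the wrinkled
#' surface of solvent-treated microgels; `amplitude = 0` returns the smooth
#' sphere.
#'
#' @param spec A [microgel_spec()].
#' @return A [tri_mesh()] (closed, outward-wound).
#' @examples
#' mg <- make_microgel(microgel_spec(diameter = 100, subdiv = 3))
#' mg$closed
#' @export
make_microgel <- function(spec) {
  stopifnot(inherits(spec, "microgel_spec"))
  ico <- icosphere(spec$subdiv)
  v <- ico$vertices
  R <- spec$diameter / 2
  if (spec$amplitude > 0) {
    theta <- acos(pmin(pmax(v[, 3], -1), 1))
    phi <- atan2(v[, 2], v[, 1])
    dr <- with_seed(spec$seed,
                    random_sh_band(theta, phi, spec$l_min, spec$l_max))
    dr <- dr / max(abs(dr)) * spec$amplitude
    r <- R + dr
  } else {
    r <- rep(R, nrow(v))
  }
  tri_mesh(v * r, ico$faces, closed = TRUE, name = spec$name)
}

# (l+|m|)!/(l-|m|)! without overflow for moderate l
factorial_ratio <- function(l, m) {
  if (m == 0) return(1)
  prod(seq(l - m + 1, l + m))
}
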