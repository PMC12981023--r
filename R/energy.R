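# Two-layer stress-fiber energy model.
#
# Basal stress fibers are Euler-Bernoulli beams with active contractile force
# F_a0 that conform to the substrate section and anchor through focal
# adhesions at both ends; convex sections press the fiber onto the gel and
# recruit adhesion units. Apical fibers form an actin cap spanning the
# nucleus as a parabolic arc; its deflection is set by nucleus height plus
# the substrate sagitta, and the vertical component of cap tension compresses
# the nucleus (a quadratic effective spring).
#
# Layer energies:
#   basal : U_total = U_bending + U_active + U_FA
#   apical: U_total = U_bending + U_active + U_FA + U_nuc
# with U_bending, U_active >= 0, U_FA <= 0, U_nuc >= 0 (all pN*um).

#' Mechanical model parameters
#'
#' All parameters of the two-layer stress-fiber energy model, with defaults
#' calibrated so that (C1) basal total energy decreases with curvature over
#' the physiological range [0, 0.04] 1/um, and (C2) the apical
#' focal-adhesion term dominates bending on flat substrates. Both
#' inequalities are checked at construction.
#'
#' @param B_f_b Basal fiber bending rigidity (pN um^2).
#' @param B_f_a Apical fiber (actin-cap bundle) bending rigidity (pN um^2).
#' @param L_f Basal fiber contour length (um).
#' @param W Apical span between the cap's adhesion ends (um).
#' @param F_a0 Active contractile force per fiber (pN).
#' @param N_f_a Number of apical fibers in the cap.
#' @param N_f_b Number of basal fibers.
#' @param h_N Nucleus height above the substrate (um).
#' @param k_nuc Effective nuclear compression stiffness (pN/um).
#' @param eps_FA Binding energy per adhesion unit (pN um).
#' @param N0_b,N0_a Baseline adhesion unit counts per basal/apical fiber.
#' @param f_c Pressing force recruiting one adhesion unit (pN).
#' @param check Set `FALSE` to skip the calibration inequalities (a warning
#'   is emitted instead of an error when they fail).
#' @return Object of class `model_params`.
#' @examples
#' p <- model_params()
#' p$F_a0
#' @export
model_params <- function(B_f_b = 2, B_f_a = 20, L_f = 20, W = 30,
                         F_a0 = 10, N_f_a = 10, N_f_b = 5.5,
                         h_N = 5, k_nuc = 5000,
                         eps_FA = 0.1, N0_b = 10, N0_a = 10, f_c = 0.05,
                         check = TRUE) {
  p <- list(B_f_b = B_f_b, B_f_a = B_f_a, L_f = L_f, W = W, F_a0 = F_a0,
            N_f_a = N_f_a, N_f_b = N_f_b, h_N = h_N, k_nuc = k_nuc,
            eps_FA = eps_FA, N0_b = N0_b, N0_a = N0_a, f_c = f_c)
  pos <- setdiff(names(p), c("N_f_a", "N_f_b"))
  bad <- pos[vapply(p[pos], function(v) !is.numeric(v) || v <= 0, logical(1))]
  if (length(bad))
    stop("model_params: strictly positive value required for ",
         paste(bad, collapse = ", "))
  if (N_f_a < 0 || N_f_b < 0)
    stop("model_params: fiber counts must be >= 0")
  p <- structure(p, class = "model_params")
  cal <- check_calibration(p)
  msg <- character(0)
  if (!cal$C1)
    msg <- c(msg, "C1 violated: basal energy not guaranteed decreasing up to kappa = 0.04 1/um")
  if (!cal$C2)
    msg <- c(msg, "C2 violated: apical FA term does not dominate bending on flat substrate")
  if (length(msg)) {
    if (check) stop("model_params: ", paste(msg, collapse = "; "),
                    " (use check = FALSE to override)")
    warning("model_params: ", paste(msg, collapse = "; "))
  }
  p
}

#' Calibration inequalities of the default parameter regime
#'
#' C1 (basal decrease): `eps_FA / f_c > kappa_max (L_f^2/12 + B_f_b/F_a0)`
#' with `kappa_max = 0.04` 1/um guarantees that adhesion recruitment outpaces
#' bending plus contraction penalties, so basal fibers favour high-curvature
#' directions. C2 (apical FA dominance at zero curvature):
#' `N0_a eps_FA > 32 B_f_a h_N^2 / W^3`.
#'
#' @param p A [model_params()] (possibly built with `check = FALSE`).
#' @param kappa_max Upper end of the curvature range (1/um).
#' @return List with logicals `C1`, `C2`.
#' @export
check_calibration <- function(p, kappa_max = 0.04) {
  list(C1 = p$eps_FA / p$f_c >
         kappa_max * (p$L_f^2 / 12 + p$B_f_b / p$F_a0),
       C2 = p$N0_a * p$eps_FA > 32 * p$B_f_a * p$h_N^2 / p$W^3)
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params (pN, um):\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-7s = %g\n", nm, x[[nm]]))
  invisible(x)
}

trapz_ <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Basal stress-fiber energy on a section profile
#'
#' The fiber conforms to the substrate section (contour length ~ `L_f`).
#' Components: bending `U_b = (B_f_b / 2) * int kappa(s)^2 ds`; active
#' contraction `U_a = F_a0 * (contour - chord)` (work stored in the excess
#' path length against the contractile force); focal adhesion
#' `U_FA = -N_FA * eps_FA` with `N_FA = max(N0_b + P / f_c, 0)` and pressing
#' load `P = F_a0 * int kappa(s) ds` (signed: convex sections press the fiber
#' onto the gel and recruit adhesion units, concave sections peel it).
#'
#' @param profile A [section_profile()] extracted with
#'   `half_length = L_f / 2` (contour within 10% of `L_f`).
#' @param p A [model_params()].
#' @return Object of class `energy_breakdown` with fields `layer`,
#'   `U_bending`, `U_active`, `U_FA`, `U_nuc` (0 for basal), `U_total`,
#'   `N_FA`, `theta_deg`.
#' @export
basal_energy <- function(profile, p) {
  stopifnot(inherits(profile, "section_profile"), inherits(p, "model_params"))
  if (abs(profile$contour - p$L_f) > 0.1 * p$L_f)
    stop("basal_energy: profile contour length differs from L_f by more than 10%")
  U_b <- p$B_f_b / 2 * trapz_(profile$s, profile$kappa^2)
  U_a <- p$F_a0 * (profile$contour - profile$chord)
  P <- p$F_a0 * trapz_(profile$s, profile$kappa)
  N_FA <- max(p$N0_b + P / p$f_c, 0)
  U_FA <- -N_FA * p$eps_FA
  energy_breakdown("basal", U_b, U_a, U_FA, 0, N_FA = N_FA,
                   theta_deg = profile$theta_deg)
}

#' Apical (actin-cap) stress-fiber energy on a section profile
#'
#' The cap spans `W` between two adhesions and arches over the nucleus as a
#' parabolic arc. The substrate sagitta `g = z(center) - mean(z(ends))`
#' raises (convex) or lowers (concave) the required deflection
#' `delta = max(h_N + g, 0)`. Components: `U_bending = 32 B_f_a delta^2/W^3`;
#' `U_active = F_a0 * 8 delta^2 / (3 W)` (parabolic excess length); nuclear
#' compression from the vertical component of cap tension,
#' `F_v = 8 F_a0 delta / W` per fiber, `U_nuc = (N_f_a F_v)^2 / (2 k_nuc)`
#' for the whole cap (`whole_cap = FALSE` reports the per-fiber share
#' `U_nuc / N_f_a`); `U_FA = -N0_a * eps_FA`.
#'
#' @param profile A [section_profile()] spanning at least `W` horizontally.
#' @param p A [model_params()].
#' @param whole_cap Report the nuclear term for the whole cap (default) or
#'   the per-fiber share.
#' @return An `energy_breakdown` (fields as in [basal_energy()], plus
#'   `delta`, `g`).
#' @export
apical_energy <- function(profile, p, whole_cap = TRUE) {
  stopifnot(inherits(profile, "section_profile"), inherits(p, "model_params"))
  tr <- range(profile$t)
  if (tr[1] > -p$W / 2 + 1e-9 || tr[2] < p$W / 2 - 1e-9)
    stop("apical_energy: W exceeds profile span")
  z_end <- (stats::approx(profile$t, profile$z, xout = c(-p$W / 2, p$W / 2),
                          rule = 1)$y)
  z_c <- stats::approx(profile$t, profile$z, xout = 0)$y
  g <- z_c - mean(z_end)
  delta <- max(p$h_N + g, 0)
  U_b <- 32 * p$B_f_a * delta^2 / p$W^3
  U_a <- p$F_a0 * 8 * delta^2 / (3 * p$W)
  F_v <- 8 * p$F_a0 * delta / p$W
  U_nuc <- (p$N_f_a * F_v)^2 / (2 * p$k_nuc)
  if (!whole_cap) U_nuc <- if (p$N_f_a > 0) U_nuc / p$N_f_a else 0
  U_FA <- -p$N0_a * p$eps_FA
  out <- energy_breakdown("apical", U_b, U_a, U_FA, U_nuc,
                          theta_deg = profile$theta_deg)
  out$delta <- delta
  out$g <- g
  out
}

energy_breakdown <- function(layer, U_bending, U_active, U_FA, U_nuc,
                             N_FA = NA_real_, theta_deg = NA_real_) {
  structure(list(layer = layer, U_bending = U_bending, U_active = U_active,
                 U_FA = U_FA, U_nuc = U_nuc,
                 U_total = U_bending + U_active + U_FA + U_nuc,
                 N_FA = N_FA, theta_deg = theta_deg),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "%s energy (pN um): total %.4g = bending %.4g + active %.4g + FA %.4g + nuc %.4g\n",
    x$layer, x$U_total, x$U_bending, x$U_active, x$U_FA, x$U_nuc))
  invisible(x)
}

#' Orientation energy landscape at a surface point
#'
#' Evaluates basal and apical layer energies on planar normal sections at
#' azimuths `theta = 0, theta_step, ..., 180 - theta_step` around the surface
#' normal at `point`, and locates the local minima of each layer under
#' 180-degree periodicity. Basal sections span `L_f`, apical sections `W`.
#'
#' @param surface A [height_field()].
#' @param point Length-2 numeric (x, y) in um.
#' @param p A [model_params()].
#' @param theta_step Azimuth grid step (deg).
#' @param step Sample spacing along sections (um).
#' @param degeneracy_tol Landscape relief (pN um) below which a layer is
#'   flagged degenerate (effectively orientation-free, e.g. on flat gel).
#' @return Object of class `orientation_landscape`: `theta_deg`, data frame
#'   `basal` and `apical` (columns U_bending, U_active, U_FA, U_nuc,
#'   U_total), per-layer `minima` (data frame theta_deg, U), `relief`,
#'   `degenerate` flags.
#' @examples
#' gr <- make_groove_surface(A = 0.9, lambda = 44.3, grid_n = 161, spacing = 1)
#' ol <- orientation_landscape(gr, point = c(80, 80), p = model_params(),
#'                             theta_step = 5)
#' ol$basal_argmin_deg  # 90: basal fibers run circumferentially
#' @export
orientation_landscape <- function(surface, point, p = model_params(),
                                  theta_step = 1, step = 0.5,
                                  degeneracy_tol = 1e-3) {
  stopifnot(theta_step > 0, 180 %% theta_step == 0)
  thetas <- seq(0, 180 - theta_step, by = theta_step)
  half_b <- p$L_f / 2
  half_a <- p$W / 2 + 2 * step
  comp <- function(th) {
    pr_b <- tryCatch(
      normal_section_profile(surface, point, th, half_b, step),
      error = function(e) stop("orientation_landscape: theta = ", th, " deg: ",
                               conditionMessage(e)))
    pr_a <- tryCatch(
      normal_section_profile(surface, point, th, half_a, step),
      error = function(e) stop("orientation_landscape: theta = ", th, " deg: ",
                               conditionMessage(e)))
    b <- basal_energy(pr_b, p)
    a <- apical_energy(pr_a, p)
    c(b$U_bending, b$U_active, b$U_FA, 0, b$U_total,
      a$U_bending, a$U_active, a$U_FA, a$U_nuc, a$U_total)
  }
  m <- vapply(thetas, comp, numeric(10))
  basal <- data.frame(theta_deg = thetas, U_bending = m[1, ],
                      U_active = m[2, ], U_FA = m[3, ], U_nuc = m[4, ],
                      U_total = m[5, ])
  apical <- data.frame(theta_deg = thetas, U_bending = m[6, ],
                       U_active = m[7, ], U_FA = m[8, ], U_nuc = m[9, ],
                       U_total = m[10, ])
  mk <- function(df) {
    u <- df$U_total
    relief <- max(u) - min(u)
    minima <- periodic_local_minima(thetas, u)
    list(minima = minima, relief = relief,
         degenerate = relief < degeneracy_tol)
  }
  mb <- mk(basal); ma <- mk(apical)
  structure(list(theta_deg = thetas, basal = basal, apical = apical,
                 basal_minima = mb$minima, apical_minima = ma$minima,
                 basal_relief = mb$relief, apical_relief = ma$relief,
                 basal_degenerate = mb$degenerate,
                 apical_degenerate = ma$degenerate,
                 basal_argmin_deg = thetas[which.min(basal$U_total)],
                 apical_argmin_deg = thetas[which.min(apical$U_total)],
                 point = point, params = p),
            class = "orientation_landscape")
}

# local minima of u(theta) under 180-degree wrap, filtered by topographic
# prominence (barrier height to the nearest lower minimum) so that
# grid-sampling ripple does not spawn spurious orientations
periodic_local_minima <- function(theta, u, prom_frac = 0.1,
                                  prom_abs = 1e-3) {
  n <- length(u)
  prv <- u[c(n, seq_len(n - 1))]
  nxt <- u[c(seq_len(n)[-1], 1)]
  cand <- which(u < prv & u <= nxt)
  if (!length(cand)) cand <- which.min(u)
  relief <- max(u) - min(u)
  tol <- max(prom_frac * relief, prom_abs)
  prom <- vapply(cand, function(i) {
    barrier <- function(dirn) {
      b <- -Inf
      j <- i
      for (step in seq_len(n)) {
        j <- ((j - 1 + dirn) %% n) + 1
        b <- max(b, u[j])
        if (u[j] < u[i]) return(b)
      }
      b  # no lower minimum: barrier is the global max
    }
    min(barrier(1L), barrier(-1L)) - u[i]
  }, numeric(1))
  keep <- cand[prom >= tol | u[cand] == min(u)]
  data.frame(theta_deg = theta[keep], U = u[keep])
}

#' @export
print.orientation_landscape <- function(x, ...) {
  cat(sprintf("orientation_landscape at (%.4g, %.4g), %d angles\n",
              x$point[1], x$point[2], length(x$theta_deg)))
  cat(sprintf("  basal : argmin %g deg, relief %.4g pN um%s, %d minima\n",
              x$basal_argmin_deg, x$basal_relief,
              if (x$basal_degenerate) " (degenerate)" else "",
              nrow(x$basal_minima)))
  cat(sprintf("  apical: argmin %g deg, relief %.4g pN um%s, %d minima\n",
              x$apical_argmin_deg, x$apical_relief,
              if (x$apical_degenerate) " (degenerate)" else "",
              nrow(x$apical_minima)))
  invisible(x)
}

#' Landscape as a flat data frame
#'
#' @param x An `orientation_landscape`.
#' @param ... Unused.
#' @return data.frame with columns theta_deg, Ub_bend, Ub_act, Ub_FA, Ub_tot,
#'   Ua_bend, Ua_act, Ua_FA, Ua_nuc, Ua_tot (pN um).
#' @export
as.data.frame.orientation_landscape <- function(x, ...) {
  data.frame(theta_deg = x$theta_deg,
             Ub_bend = x$basal$U_bending, Ub_act = x$basal$U_active,
             Ub_FA = x$basal$U_FA, Ub_tot = x$basal$U_total,
             Ua_bend = x$apical$U_bending, Ua_act = x$apical$U_active,
             Ua_FA = x$apical$U_FA, Ua_nuc = x$apical$U_nuc,
             Ua_tot = x$apical$U_total)
}

#' Nuclear strain energy versus substrate curvature
#'
#' Evaluates the whole-cap nuclear strain energy on isotropic spherical-cap
#' substrates: at curvature `K` the normal curvature equals `K` in every
#' direction, the cap sagitta over the span `W` is `K W^2 / 8` (osculating
#' paraboloid), so the apical deflection is `delta = h_N + K W^2 / 8` and
#' `U_nuc = (N_f_a * 8 F_a0 delta / W)^2 / (2 k_nuc)`.
#'
#' @param K_grid Sorted non-negative curvatures (1/um).
#' @param p A [model_params()].
#' @return data.frame with columns `K` (1/um) and `U_nuc` (pN um).
#' @examples
#' nuclear_energy_curve(c(0, 0.02, 0.04), model_params())
#' @export
nuclear_energy_curve <- function(K_grid, p = model_params()) {
  stopifnot(all(K_grid >= 0), !is.unsorted(K_grid))
  U <- vapply(K_grid, function(K) {
    delta <- max(p$h_N + K * p$W^2 / 8, 0)
    F_v <- 8 * p$F_a0 * delta / p$W
    (p$N_f_a * F_v)^2 / (2 * p$k_nuc)
  }, numeric(1))
  data.frame(K = K_grid, U_nuc = U)
}

#' Cytoskeletal drug perturbations as parameter maps
#'
#' Returns a modified copy of the parameter set according to a fixed mapping:
#' \describe{
#'   \item{CN03 (Rho activator)}{`F_a0` doubled; the basal fiber fraction
#'     `N_f_b / (N_f_b + N_f_a)` is set to 0.68 (from ~0.35 at defaults),
#'     holding the total fiber count fixed.}
#'   \item{Y27632 (ROCK inhibitor)}{apical cap ablated (`N_f_a = 0`),
#'     `F_a0` halved.}
#'   \item{blebbistatin (myosin II inhibitor)}{`F_a0` x 0.1.}
#'   \item{latrunculinB (actin polymerization inhibitor)}{`N_f_a` and
#'     `N_f_b` x 0.05.}
#'   \item{none}{identity.}
#' }
#'
#' @param p A [model_params()].
#' @param drug One of `"none"`, `"CN03"`, `"Y27632"`, `"blebbistatin"`,
#'   `"latrunculinB"`.
#' @return A `model_params` copy with the mapped fields changed.
#' @export
apply_perturbation <- function(p, drug = c("none", "CN03", "Y27632",
                                           "blebbistatin", "latrunculinB")) {
  stopifnot(inherits(p, "model_params"))
  drug <- match.arg(drug)
  q <- unclass(p)
  if (drug != "none") {
    map <- drug_map()[[drug]]
    if (is.null(map)) stop("apply_perturbation: no committed map for ", drug)
    for (nm in names(map)) {
      val <- map[[nm]]
      if (nm == "basal_fraction_set") {
        tot <- q$N_f_b + q$N_f_a
        q$N_f_b <- val * tot
        q$N_f_a <- (1 - val) * tot
      } else if (endsWith(nm, "_factor")) {
        fld <- sub("_factor$", "", nm)
        q[[fld]] <- q[[fld]] * val
      } else if (endsWith(nm, "_set")) {
        fld <- sub("_set$", "", nm)
        q[[fld]] <- val
      } else {
        stop("apply_perturbation: unrecognised map entry '", nm, "'")
      }
    }
  }
  do.call(model_params, c(q, list(check = FALSE)))
}
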