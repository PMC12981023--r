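# Scalar curvature statistics and local curvature-regime classification.

#' Area-weighted absolute mean curvature
#'
#' The statistic reported for wrinkled substrates and microgels: the
#' area-weighted mean of |H| over valid nodes. The absolute value matters --
#' a signed mean would be near zero on wrinkles whose ridges and troughs
#' cancel. Set `statistic = "kmax"` to average the dominant principal
#' curvature magnitude `max(|k1|, |k2|)` instead.
#'
#' @param field A [curvature_field()].
#' @param statistic `"mean_H"` (default) or `"kmax"`.
#' @return Scalar (1/um).
#' @examples
#' ax <- seq(-30, 30)
#' cap <- height_field(outer(ax, ax, function(y, x) sqrt(50^2 - x^2 - y^2)),
#'                     dx = 1)
#' mean_abs_curvature(height_field_curvature(cap))  # ~ 0.02
#' @export
mean_abs_curvature <- function(field, statistic = c("mean_H", "kmax")) {
  stopifnot(inherits(field, "curvature_field"))
  statistic <- match.arg(statistic)
  ok <- field$valid
  if (!any(ok)) stop("mean_abs_curvature: no valid nodes")
  v <- if (statistic == "mean_H") abs(field$H[ok])
       else pmax(abs(field$k1[ok]), abs(field$k2[ok]))
  sum(v * field$area[ok]) / sum(field$area[ok])
}

#' Classify local curvature regimes
#'
#' Per node, let `k_perp` be the principal curvature of larger magnitude
#' (signed, convex-toward-cell positive) and `k_par` the other (the curvature
#' along the local "groove axis"). Labels:
#' \itemize{
#'   \item `concave` -- `k_perp < -tau_flat` (trough-dominated);
#'   \item `flat` -- `|k_perp| <= tau_flat`;
#'   \item `uniaxial_low` / `uniaxial_high` -- `k_par <= tau_flat < k_perp`,
#'     split at `k_perp <= kappa_split`;
#'   \item `multiaxial` -- both `k_par` and `k_perp` above `tau_flat`.
#' }
#' Cells adhere to convex regions, so the headline areal proportions
#' (`adhesive_proportions`) are taken over the convex non-flat labels only;
#' the full breakdown over all valid nodes is also returned.
#'
#' @param field A [curvature_field()].
#' @param tau_flat Flatness threshold (1/um).
#' @param kappa_split Uniaxial low/high split (1/um); default midway between
#'   the low (0.011) and high (0.018) groove exemplars.
#' @return Object of class `region_classification`: per-node `label`,
#'   `proportions` (area fractions over valid nodes, sums to 1),
#'   `adhesive_proportions` (over uniaxial_low/uniaxial_high/multiaxial),
#'   `multiaxial_fraction` (shortcut), thresholds.
#' @export
classify_regions <- function(field, tau_flat = 0.003, kappa_split = 0.0145) {
  stopifnot(inherits(field, "curvature_field"), tau_flat > 0, kappa_split > 0)
  n <- length(field$k1)
  a1 <- abs(field$k1); a2 <- abs(field$k2)
  k_perp <- ifelse(a2 >= a1, field$k2, field$k1)
  k_par <- ifelse(a2 >= a1, field$k1, field$k2)
  label <- rep(NA_character_, n)
  label[k_perp < -tau_flat] <- "concave"
  label[is.na(label) & abs(k_perp) <= tau_flat] <- "flat"
  uni <- is.na(label) & k_par <= tau_flat
  label[uni & k_perp <= kappa_split] <- "uniaxial_low"
  label[uni & k_perp > kappa_split] <- "uniaxial_high"
  label[is.na(label)] <- "multiaxial"
  label[!field$valid] <- NA_character_

  lv <- c("flat", "uniaxial_low", "uniaxial_high", "multiaxial", "concave")
  ok <- field$valid
  w <- field$area[ok]
  fl <- factor(label[ok], levels = lv)
  tot <- vapply(lv, function(l) sum(w[fl == l]), numeric(1))
  proportions <- tot / sum(w)
  adh <- tot[c("uniaxial_low", "uniaxial_high", "multiaxial")]
  adhesive_proportions <- if (sum(adh) > 0) adh / sum(adh) else adh * NA
  structure(list(label = label,
                 proportions = proportions,
                 adhesive_proportions = adhesive_proportions,
                 multiaxial_fraction = unname(adhesive_proportions["multiaxial"]),
                 tau_flat = tau_flat, kappa_split = kappa_split),
            class = "region_classification")
}

#' @export
print.region_classification <- function(x, ...) {
  cat(sprintf("region_classification (tau_flat = %g, kappa_split = %g 1/um)\n",
              x$tau_flat, x$kappa_split))
  cat("  all valid nodes: ",
      paste(sprintf("%s %.1f%%", names(x$proportions),
                    100 * x$proportions), collapse = ", "), "\n")
  cat("  convex (cell-adhesive) regions: ",
      paste(sprintf("%s %.1f%%", names(x$adhesive_proportions),
                    100 * x$adhesive_proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Groove morphometry of a height field
#'
#' Detects the dominant texture direction (area- and curvature-weighted
#' circular mean of the dominant principal direction), samples transects
#' perpendicular to the groove axis, and measures each trough flanked by two
#' prominence-filtered ridges: depth is the mean adjacent ridge-to-trough
#' elevation difference, width is measured where the transect crosses the
#' half-depth level.
#'
#' @param surface A [height_field()].
#' @param n_transects Number of transects sampled across the field.
#' @param min_prominence Minimum ridge/trough prominence as a fraction of the
#'   global elevation range.
#' @return Object of class `groove_morphometry`: per-groove data frame
#'   `grooves` (depth_um, width_um), `count`, `depth_mean`, `depth_sd`,
#'   `width_mean`, `width_sd`, `axis_deg` (groove axis direction).
#' @examples
#' gr <- make_groove_surface(A = 10, lambda = 80, grid_n = 201)
#' gm <- groove_morphometry(gr)
#' c(gm$depth_mean, gm$width_mean)  # ~ 20 and ~ 40
#' @export
groove_morphometry <- function(surface, n_transects = 9,
                               min_prominence = 0.2) {
  stopifnot(inherits(surface, "height_field"))
  rng <- max(surface$z) - min(surface$z)
  empty <- structure(list(grooves = data.frame(depth_um = numeric(0),
                                               width_um = numeric(0)),
                          count = 0L, depth_mean = NA_real_,
                          depth_sd = NA_real_, width_mean = NA_real_,
                          width_sd = NA_real_, axis_deg = NA_real_),
                     class = "groove_morphometry")
  if (rng < 1e-9) return(empty)

  cf <- height_field_curvature(surface)
  ok <- cf$valid
  # direction of the dominant (larger |kappa|) principal curvature is the
  # cross-groove direction; weight its axial circular mean by area * |kappa|
  dom2 <- ifelse(abs(cf$k2) >= abs(cf$k1), cf$dir1 + pi / 2, cf$dir1)
  wgt <- cf$area[ok] * pmax(abs(cf$k1[ok]), abs(cf$k2[ok]))
  cmean <- atan2(sum(wgt * sin(2 * dom2[ok])), sum(wgt * cos(2 * dom2[ok]))) / 2
  axis_deg <- (rad2deg(cmean) + 90) %% 180  # groove axis = perpendicular

  ext <- c((ncol(surface$z) - 1) * surface$dx,
           (nrow(surface$z) - 1) * surface$dy)
  ctr <- surface$origin + ext / 2
  th <- deg2rad((axis_deg + 90) %% 180)     # transect: cross-groove
  u <- c(cos(th), sin(th))                  # along transect
  vperp <- c(-sin(th), cos(th))             # across transects
  half <- half_span_in_box(ctr, u, ext, surface$origin)
  step <- min(surface$dx, surface$dy) / 2
  offs <- seq(-0.35, 0.35, length.out = n_transects) * min(ext)

  grooves <- list()
  for (o in offs) {
    c0 <- ctr + o * vperp
    hl <- half_span_in_box(c0, u, ext, surface$origin)
    if (hl < 4 * step) next
    t <- seq(-hl, hl, by = step)
    zz <- height_field_interp(surface, c0[1] + t * u[1], c0[2] + t * u[2])
    grooves <- c(grooves, list(transect_grooves(t, zz, min_prominence * rng)))
  }
  g <- do.call(rbind, grooves)
  if (is.null(g) || nrow(g) == 0L) { empty$axis_deg <- axis_deg; return(empty) }
  structure(list(grooves = g, count = nrow(g),
                 depth_mean = mean(g$depth_um), depth_sd = stats::sd(g$depth_um),
                 width_mean = mean(g$width_um), width_sd = stats::sd(g$width_um),
                 axis_deg = axis_deg),
            class = "groove_morphometry")
}

#' @export
print.groove_morphometry <- function(x, ...) {
  if (x$count == 0L) {
    cat("groove_morphometry: no grooves detected\n")
  } else {
    cat(sprintf(
      "groove_morphometry: %d grooves, axis %.1f deg\n  depth %.3g +/- %.3g um, width %.3g +/- %.3g um\n",
      x$count, x$axis_deg, x$depth_mean, x$depth_sd, x$width_mean, x$width_sd))
  }
  invisible(x)
}

# largest half-length of a segment through c0 along u staying inside the grid
half_span_in_box <- function(c0, u, ext, origin) {
  lim <- Inf
  for (d in 1:2) {
    if (abs(u[d]) > 1e-12) {
      lim <- min(lim, (origin[d] + ext[d] - c0[d]) / abs(u[d]),
                 (c0[d] - origin[d]) / abs(u[d]))
    }
  }
  max(lim - 1e-9, 0)
}

# troughs between adjacent prominent ridges on one transect
transect_grooves <- function(t, z, min_prom) {
  pk <- pracma::findpeaks(z)
  tr <- pracma::findpeaks(-z)
  if (is.null(pk) || is.null(tr)) return(NULL)
  ridge_i <- prominent_extrema(z, sort(pk[, 2]), sort(tr[, 2]), min_prom)
  trough_i <- prominent_extrema(-z, sort(tr[, 2]), sort(pk[, 2]), min_prom)
  if (!length(ridge_i) || !length(trough_i)) return(NULL)
  out <- NULL
  for (ti in trough_i) {
    left <- ridge_i[ridge_i < ti]
    right <- ridge_i[ridge_i > ti]
    if (!length(left) || !length(right)) next
    rl <- max(left); rr <- min(right)
    depth <- mean(c(z[rl], z[rr])) - z[ti]
    if (depth <= 0) next
    half_level <- z[ti] + depth / 2
    iL <- crossing_before(t, z, ti, rl, half_level)
    iR <- crossing_after(t, z, ti, rr, half_level)
    if (is.na(iL) || is.na(iR)) next
    out <- rbind(out, data.frame(depth_um = depth, width_um = iR - iL))
  }
  out
}

# keep extrema of `v` (maxima at `idx`) whose drop to the deeper flanking
# counter-extremum (or segment end) exceeds `min_prom`
prominent_extrema <- function(v, idx, counter_idx, min_prom) {
  keep <- vapply(idx, function(i) {
    left <- counter_idx[counter_idx < i]
    right <- counter_idx[counter_idx > i]
    base_l <- if (length(left)) v[max(left)] else min(v[seq_len(i)])
    base_r <- if (length(right)) v[min(right)] else min(v[i:length(v)])
    (v[i] - max(base_l, base_r)) >= min_prom
  }, logical(1))
  idx[keep]
}

crossing_before <- function(t, z, i0, ilim, level) {
  for (i in seq(i0, ilim + 1L, by = -1L)) {
    if (z[i - 1L] >= level && z[i] < level) {
      f <- (level - z[i]) / (z[i - 1L] - z[i])
      return(t[i] + f * (t[i - 1L] - t[i]))
    }
  }
  NA_real_
}

crossing_after <- function(t, z, i0, ilim, level) {
  for (i in seq(i0, ilim - 1L)) {
    if (z[i + 1L] >= level && z[i] < level) {
      f <- (level - z[i]) / (z[i + 1L] - z[i])
      return(t[i] + f * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}
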