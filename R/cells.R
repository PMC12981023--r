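# Synthetic cells: fiber populations sampled from the orientation energy
# landscapes and rendered as grayscale images, closing the loop between the
# mechanical model and the image-based orientation analysis.

#' Synthesize a cell from the model's energy landscapes
#'
#' Computes the basal and apical orientation landscapes at `point`, then
#' draws fiber orientations from Boltzmann weights
#' `p(theta) proportional to exp(-(U(theta) - U_min) / U_scale)` on a
#' 1-degree grid per layer. `U_scale` is a disorder knob (pN um), not a
#' physical temperature: as `U_scale -> 0` every fiber sits at the layer's
#' energy minimum; as `U_scale -> Inf` orientations become uniform and the
#' cell is flagged isotropic (as it also is on a degenerate, flat
#' landscape). Fibers are rendered as anti-aliased line segments with a
#' Gaussian line-spread of sigma = 0.5 px.
#'
#' @param surface A [height_field()].
#' @param point Landscape evaluation point (x, y) in um.
#' @param params A [model_params()]; basal/apical fiber lengths follow
#'   `L_f` and `W`.
#' @param n_basal,n_apical Number of fibers per layer; defaults split
#'   `n_total` by the parameter set's basal fraction
#'   `N_f_b / (N_f_b + N_f_a)`.
#' @param n_total Total fiber count used when `n_basal`/`n_apical` are NULL.
#' @param U_scale Boltzmann scale (pN um).
#' @param seed Integer seed; the cell is a pure function of its arguments.
#' @param px_size Rendered pixel size (um).
#' @param img_um Rendered field of view (um, square).
#' @param center_sd Standard deviation of fiber midpoint scatter around the
#'   cell centre (um).
#' @param landscape Optionally a precomputed [orientation_landscape()] at
#'   `point` (avoids recomputation when synthesizing many cells).
#' @return Object of class `synthetic_cell`: `segments` (data frame: layer,
#'   theta_deg, length_um, width_um, cx_um, cy_um), `image` (matrix, peak-
#'   normalized), `mask` (logical footprint), `isotropic` flag, `landscape`,
#'   `params`, `seed`.
#' @examples
#' gr <- load_preset("uniaxial-high")
#' cell <- synthesize_cell(gr, attr(gr, "center"), model_params(),
#'                         n_total = 40, seed = 2)
#' table(cell$segments$layer)
#' @export
synthesize_cell <- function(surface, point, params = model_params(),
                            n_basal = NULL, n_apical = NULL, n_total = 200,
                            U_scale = 1, seed = 1, px_size = 0.5,
                            img_um = 100, center_sd = 6,
                            landscape = NULL) {
  stopifnot(U_scale > 0)
  if (is.null(landscape))
    landscape <- orientation_landscape(surface, point, params, theta_step = 1)
  frac_b <- if (params$N_f_b + params$N_f_a > 0)
    params$N_f_b / (params$N_f_b + params$N_f_a) else 0.5
  if (is.null(n_basal)) n_basal <- round(n_total * frac_b)
  if (is.null(n_apical)) n_apical <- n_total - round(n_total * frac_b)

  boltz <- function(u) {
    w <- exp(-(u - min(u)) / U_scale)
    w / sum(w)
  }
  iso_b <- landscape$basal_degenerate
  iso_a <- landscape$apical_degenerate
  pb <- if (iso_b) rep(1 / length(landscape$theta_deg),
                       length(landscape$theta_deg))
        else boltz(landscape$basal$U_total)
  pa <- if (iso_a) rep(1 / length(landscape$theta_deg),
                       length(landscape$theta_deg))
        else boltz(landscape$apical$U_total)
  # a flat Boltzmann weight (huge U_scale) is as isotropic as a degenerate
  # landscape
  iso_b <- iso_b || max(pb) < 2 / length(pb)
  iso_a <- iso_a || max(pa) < 2 / length(pa)

  n_tot <- n_basal + n_apical
  segments <- with_seed(seed, {
    draw <- function(n, prob, layer, len, wid) {
      if (n <= 0) return(NULL)
      th <- sample(landscape$theta_deg, n, replace = TRUE, prob = prob) +
        stats::runif(n, -0.5, 0.5)
      # fibers tile the cell body along their own axis: midpoint scatter
      # along the fiber orientation grows with the layer's population share,
      # so the footprint elongates along the dominant layer's direction
      frac <- n / n_tot
      sd_par <- center_sd * (0.5 + 1.5 * frac)
      sd_perp <- center_sd * 0.5
      thr <- deg2rad(th)
      along <- stats::rnorm(n, 0, sd_par)
      perp <- stats::rnorm(n, 0, sd_perp)
      data.frame(layer = layer, theta_deg = th %% 180,
                 length_um = len * stats::runif(n, 0.85, 1.15),
                 width_um = wid * stats::runif(n, 0.8, 1.2),
                 cx_um = img_um / 2 + along * cos(thr) - perp * sin(thr),
                 cy_um = img_um / 2 + along * sin(thr) + perp * cos(thr))
    }
    rbind(draw(n_basal, pb, "basal", params$L_f, 0.6),
          draw(n_apical, pa, "apical", params$W, 0.9))
  })
  if (is.null(segments))
    stop("synthesize_cell: no fibers requested")

  img <- render_segments(segments, px_size = px_size, img_um = img_um,
                         sigma_px = 0.5)
  mask <- img > 0.05 * max(img)
  structure(list(segments = segments, image = img, mask = mask,
                 isotropic = iso_b && iso_a, params = params, seed = seed,
                 landscape = landscape, px_size = px_size),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  n <- table(factor(x$segments$layer, levels = c("basal", "apical")))
  cat(sprintf(
    "synthetic_cell: %d basal + %d apical fibers, %d x %d px image%s\n",
    n["basal"], n["apical"], nrow(x$image), ncol(x$image),
    if (x$isotropic) " (isotropic)" else ""))
  invisible(x)
}

#' Render fiber segments as a grayscale image
#'
#' Draws each segment with a Gaussian line-spread profile (anti-aliased),
#' intensity proportional to segment width. Row 1 of the image is y = 0
#' (y up), matching the orientation-analysis convention.
#'
#' @param segments Data frame with columns theta_deg, length_um, width_um,
#'   cx_um, cy_um.
#' @param px_size Pixel size (um).
#' @param img_um Image side length (um).
#' @param sigma_px Gaussian line-spread (px).
#' @return Numeric matrix, peak-normalized to 1.
#' @export
render_segments <- function(segments, px_size = 0.5, img_um = 100,
                            sigma_px = 0.5) {
  n_px <- max(8L, round(img_um / px_size))
  img <- matrix(0, n_px, n_px)
  sig_um <- sigma_px * px_size
  ax <- (seq_len(n_px) - 0.5) * px_size
  for (i in seq_len(nrow(segments))) {
    th <- deg2rad(segments$theta_deg[i])
    hl <- segments$length_um[i] / 2
    cx <- segments$cx_um[i]; cy <- segments$cy_um[i]
    ux <- cos(th); uy <- sin(th)
    pad <- 3 * sig_um + segments$width_um[i]
    jr <- which(ax >= cx - hl - pad & ax <= cx + hl + pad)
    ir <- which(ax >= cy - hl - pad & ax <= cy + hl + pad)
    if (!length(jr) || !length(ir)) next
    X <- matrix(ax[jr], length(ir), length(jr), byrow = TRUE) - cx
    Y <- matrix(ax[ir], length(ir), length(jr)) - cy
    tpar <- X * ux + Y * uy                   # along-segment coordinate
    tcl <- pmin(pmax(tpar, -hl), hl)          # clamped to the endpoints
    d2 <- (X - tcl * ux)^2 + (Y - tcl * uy)^2 # squared distance to segment
    spread <- sig_um + segments$width_um[i] / 2.355  # FWHM-ish broadening
    img[ir, jr] <- img[ir, jr] +
      segments$width_um[i] * exp(-d2 / (2 * spread^2))
  }
  if (max(img) > 0) img <- img / max(img)
  img
}
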