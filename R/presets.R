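# Packaged study presets: named substrate and microgel conditions plus the
# default generator sweep, all committed as YAML so a run is reproducible
# from its preset name alone.

preset_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "presets.yaml",
                                            package = "curvmech",
                                            mustWork = TRUE))
    cache
  }
})

#' Names of packaged presets
#'
#' @return List with character vectors `surfaces` and `microgels`.
#' @export
preset_names <- function() {
  reg <- preset_registry()
  list(surfaces = names(reg$surfaces), microgels = names(reg$microgels))
}

#' Load a packaged surface or microgel preset
#'
#' Surface presets (`FLAT`, `C100`, `C70`, `uniaxial-low`, `uniaxial-high`,
#' `constructed-multiaxial`) return a [height_field()]; microgel presets
#' (`microgel-small`, `-moderate`, `-large`) return a [tri_mesh()]. Groove
#' and multiaxial presets carry a `"center"` attribute marking the designed
#' landscape evaluation point; wrinkle presets are seeded and fully
#' deterministic.
#'
#' @param name Preset name (see [preset_names()]).
#' @return A `height_field` or `tri_mesh` with `name` set.
#' @examples
#' gr <- load_preset("uniaxial-high")
#' attr(gr, "center")
#' @export
load_preset <- function(name) {
  reg <- preset_registry()
  if (name %in% names(reg$surfaces)) {
    s <- reg$surfaces[[name]]
    out <- switch(s$type,
      wrinkle = make_wrinkle_surface(wrinkle_spec(
        lambda_c = s$lambda_c, A = s$A, anisotropy = s$anisotropy,
        bandwidth = s$bandwidth, seed = s$seed, grid_n = s$grid_n,
        spacing = s$spacing, name = name)),
      groove = make_groove_surface(
        A = groove_amplitude_for_curvature(s$K_perp, s$lambda),
        lambda = s$lambda, grid_n = s$grid_n, spacing = s$spacing,
        name = name),
      multiaxial = make_multiaxial_test_surface(
        amplitudes = as.numeric(s$amplitudes),
        directions_deg = as.numeric(s$directions_deg),
        wavelengths = as.numeric(s$wavelengths),
        grid_n = s$grid_n, spacing = s$spacing, name = name),
      stop("load_preset: unknown surface type '", s$type, "'"))
    return(out)
  }
  if (name %in% names(reg$microgels)) {
    m <- reg$microgels[[name]]
    return(make_microgel(microgel_spec(
      diameter = m$diameter, amplitude = m$amplitude, l_min = m$l_min,
      l_max = m$l_max, seed = m$seed, subdiv = m$subdiv, name = name)))
  }
  stop("load_preset: unknown preset '", name, "'")
}

#' Default wrinkle-generator sweep
#'
#' The committed amplitude x wavelength grid emulating the ethanol-fraction
#' series of substrate treatments. Each combination gets a deterministic
#' seed derived from `base_seed`.
#'
#' @param base_seed Overrides the committed base seed (the sweep stays a
#'   pure function of this value).
#' @return List of [wrinkle_spec()] objects.
#' @export
wrinkle_sweep_specs <- function(base_seed = NULL) {
  sw <- preset_registry()$wrinkle_sweep
  if (is.null(base_seed)) base_seed <- sw$base_seed
  specs <- list()
  i <- 0L
  for (A in as.numeric(sw$amplitudes)) {
    for (lam in as.numeric(sw$wavelengths)) {
      i <- i + 1L
      specs[[i]] <- wrinkle_spec(
        lambda_c = lam, A = A, anisotropy = sw$anisotropy,
        bandwidth = sw$bandwidth, seed = (base_seed + 1000L * i) %% 2147483647L,
        grid_n = sw$grid_n, spacing = sw$spacing,
        name = sprintf("sweep-A%g-lam%g", A, lam))
    }
  }
  specs
}

#' Committed drug perturbation table
#'
#' @return Named list of perturbation descriptors as committed in the
#'   package YAML registry (multiplicative `*_factor`, assignment `*_set`,
#'   and `basal_fraction_set` entries).
#' @export
drug_map <- function() preset_registry()$drugs
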