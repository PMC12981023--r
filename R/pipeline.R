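# End-to-end analysis pipeline: substrate -> curvature -> classification ->
# energy landscapes -> synthetic cell -> orientation statistics, with every
# artifact written to a self-describing run directory.

#' Assemble a pipeline run configuration
#'
#' @param preset Packaged preset name (see [preset_names()]).
#' @param out_dir Output directory (created if needed).
#' @param drug Perturbation tag for [apply_perturbation()].
#' @param params A [model_params()] (before perturbation).
#' @param theta_step Landscape azimuth step (deg).
#' @param n_fibers Synthetic-cell fiber count.
#' @param U_scale Boltzmann scale (pN um).
#' @param seed Seed for the synthetic cell.
#' @param tau_flat,kappa_split Classification thresholds (1/um).
#' @param quiet Suppress stage messages.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(preset = "uniaxial-high", out_dir = tempfile("run_"),
                       drug = "none", params = model_params(),
                       theta_step = 2, n_fibers = 200, U_scale = 1,
                       seed = 1, tau_flat = 0.003, kappa_split = 0.0145,
                       quiet = FALSE) {
  structure(list(preset = preset, out_dir = out_dir, drug = drug,
                 params = params, theta_step = theta_step,
                 n_fibers = n_fibers, U_scale = U_scale, seed = seed,
                 tau_flat = tau_flat, kappa_split = kappa_split,
                 quiet = quiet),
            class = "run_config")
}

#' Run the full analysis pipeline on a preset
#'
#' Generates the preset substrate, computes its curvature field and regime
#' classification, evaluates the orientation energy landscape at the preset's
#' designed point (or the grid centre), the nuclear energy curve, synthesizes
#' a cell, and quantifies its orientations; writes all artifacts plus a
#' manifest (`manifest.json` with package version, configuration, seed and
#' md5 hashes of every artifact) to the run directory. Microgel presets run
#' the mesh branch (OBJ + curvature statistics only).
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; the parsed manifest as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!config$quiet) message("[curvmech] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  art <- list()
  put <- function(file) { art[[length(art) + 1L]] <<- file; file }
  p <- stage("perturb", apply_perturbation(config$params, config$drug))
  results <- list(preset = config$preset, drug = config$drug)

  is_mesh <- config$preset %in% preset_names()$microgels
  if (is_mesh) {
    say("stage generate-surface (microgel ", config$preset, ")")
    mesh <- stage("generate-surface", load_preset(config$preset))
    write_obj(mesh, put(file.path(config$out_dir, "surface.obj")))
    say("stage curvature")
    edges <- unique_mesh_edges(mesh$faces)
    el <- mean(sqrt(rowSums((mesh$vertices[edges[, 1], ] -
                               mesh$vertices[edges[, 2], ])^2)))
    cf <- stage("curvature", mesh_curvature(mesh, fit_radius = 2.6 * el))
    write_curvature_csv(cf, put(file.path(config$out_dir, "curvature.csv")))
    results$mean_abs_curvature <- mean_abs_curvature(cf)
  } else {
    say("stage generate-surface (", config$preset, ")")
    surf <- stage("generate-surface", load_preset(config$preset))
    center <- attr(surf, "center") %||%
      (surf$origin + c((ncol(surf$z) - 1) * surf$dx,
                       (nrow(surf$z) - 1) * surf$dy) / 2)
    write_height_field(surf, put(file.path(config$out_dir, "surface.tif")))
    put(file.path(config$out_dir, "surface.tif.json"))

    say("stage curvature")
    cf <- stage("curvature", height_field_curvature(surf))
    write_curvature_csv(cf, put(file.path(config$out_dir, "curvature.csv")))
    results$mean_abs_curvature <- mean_abs_curvature(cf)

    say("stage classify")
    cl <- stage("classify",
                classify_regions(cf, config$tau_flat, config$kappa_split))
    results$proportions <- as.list(cl$proportions)
    results$adhesive_proportions <- as.list(cl$adhesive_proportions)

    say("stage landscape")
    ol <- stage("landscape",
                orientation_landscape(surf, center, p,
                                      theta_step = config$theta_step))
    write_landscape_csv(ol, put(file.path(config$out_dir, "landscape.csv")))
    results$basal_argmin_deg <- ol$basal_argmin_deg
    results$apical_argmin_deg <- ol$apical_argmin_deg
    results$basal_minima_deg <- ol$basal_minima$theta_deg
    results$apical_minima_deg <- ol$apical_minima$theta_deg
    results$n_minima <- length(unique(c(ol$basal_minima$theta_deg,
                                        ol$apical_minima$theta_deg)))

    say("stage nuclear-curve")
    nc <- stage("nuclear-curve",
                nuclear_energy_curve(seq(0, 0.04, by = 0.002), p))
    utils::write.csv(nc, put(file.path(config$out_dir, "nuclear_curve.csv")),
                     row.names = FALSE)

    say("stage synthesize-cell")
    cell <- stage("synthesize-cell",
                  synthesize_cell(surf, center, p,
                                  n_total = config$n_fibers,
                                  U_scale = config$U_scale,
                                  seed = config$seed, landscape = ol))
    write_segments_csv(cell$segments,
                       put(file.path(config$out_dir, "cell_segments.csv")))
    write_image_tiff(cell$image,
                     put(file.path(config$out_dir, "cell_image.tif")))

    say("stage orientation-stats")
    pop <- stage("orientation-stats", layer_population_stats(cell$segments))
    cpi <- compute_cpi(cell$mask, axial_deg = 0, px_size = cell$px_size)
    hist_b <- orientation_histogram(
      cell$segments[cell$segments$layer == "basal", , drop = FALSE])
    results$population <- pop[c("basal_fraction", "apical_fraction")]
    results$CPI <- cpi$CPI
    results$circumferential_fraction <-
      alignment_fraction(hist_b, axis_deg = 90, band_deg = 15)
  }

  jsonlite::write_json(results, put(file.path(config$out_dir, "stats.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "curvmech",
    version = as.character(utils::packageVersion("curvmech")),
    config = config_as_list(config),
    results = results,
    artifacts = lapply(stats::setNames(art, basename(unlist(art))),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", config$out_dir)
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}

config_as_list <- function(config) {
  cl <- unclass(config)
  cl$params <- unclass(cl$params)
  cl
}
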