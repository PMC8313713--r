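# End-to-end pipelines. "membrane" mode: coordinate snapshots (or directly
# supplied perimeters) -> thickness/occupancy maps -> thinned-region
# segmentation -> perimeter change on complexation -> line-tension energy
# interval. "binding" mode: umbrella windows -> autocorrelation times ->
# WHAM -> bootstrap -> binding free energy. Reports are machine-readable
# JSON with the exact thresholds used, because the headline numbers are
# threshold-sensitive.

.analyze_system <- function(sys, cfg) {
  snaps <- if (!is.null(sys$snapshots)) sys$snapshots
  else if (!is.null(sys$gro)) read_snapshots_gro(
    sort(list.files(sys$gro, pattern = "\\.gro$", full.names = TRUE)),
    p_name = cfg$selections$phosphorus,
    protein_names = cfg$selections$protein)
  else if (!is.null(sys$pdb)) read_snapshots_pdb(
    sys$pdb, p_name = cfg$selections$phosphorus,
    protein_names = cfg$selections$protein)
  else stop("system needs one of: snapshots, gro, pdb")
  grid <- grid_spec(cfg$grid$nx, cfg$grid$ny,
                    snaps$box[1], snaps$box[2])
  surf <- map_leaflet_surfaces(snaps, grid)
  tmap <- thickness_map(surf$upper, surf$lower, h_bulk = cfg$h_bulk)
  omap <- suppressWarnings(occupancy_map(snaps, grid))
  region <- segment_perturbed_region(tmap, omap, delta = cfg$delta,
                                     min_cells = cfg$min_cells,
                                     smooth_sigma = cfg$smooth_sigma)
  mode <- if (identical(sys$perimeter_mode, "bulk_only")) "bulk_only"
  else "with_protein_interface"
  list(region = region, perimeter = region_perimeter(region, mode),
       mode = mode)
}

#' Run an end-to-end analysis pipeline
#'
#' `mode = "membrane"`: either takes precomputed perimeters from
#' `config$perimeters` (fields `isolated`, a numeric vector, and
#' `associated`, a scalar) or analyses `config$systems` (a list with
#' `isolated` = list of system inputs and `associated` = one system input,
#' each a list with `snapshots`, `gro` or `pdb` plus optional
#' `perimeter_mode`), then converts the perimeter change into a
#' line-tension free-energy interval.
#'
#' `mode = "binding"`: reads the window manifest (`config$manifest`) or
#' takes `config$systems$dataset` (an `umbrella_dataset`), runs
#' autocorrelation analysis, WHAM and bootstrap, and, if
#' `config$intervals` is set, a binding free energy.
#'
#' @param config A `mismatch_config` (see [analysis_config()]).
#' @param mode `"membrane"` or `"binding"`.
#' @param out Optional path for the JSON report.
#' @return The report list, invisibly written to `out` when given.
#' @export
run_pipeline <- function(config, mode = c("membrane", "binding"),
                         out = NULL) {
  stopifnot(inherits(config, "mismatch_config"))
  mode <- match.arg(mode)
  report <- list(mode = mode,
                 parameters = list(h_bulk = config$h_bulk,
                                   delta = config$delta,
                                   gamma = config$gamma,
                                   temperature = config$temperature),
                 package_version = as.character(utils::packageVersion("mismatchlab")))
  if (mode == "membrane") {
    if (!is.null(config$perimeters)) {
      iso <- as.numeric(config$perimeters$isolated)
      assoc <- as.numeric(config$perimeters$associated)
    } else {
      if (is.null(config$systems) || is.null(config$systems$isolated) ||
          is.null(config$systems$associated))
        stop("membrane mode: config needs perimeters or systems{isolated, associated}")
      iso_res <- lapply(config$systems$isolated,
                        function(s) .analyze_system(s, config))
      assoc_res <- .analyze_system(config$systems$associated, config)
      iso <- vapply(iso_res, `[[`, 0, "perimeter")
      assoc <- assoc_res$perimeter
      report$segmentation <- list(
        isolated = lapply(iso_res, function(r) list(
          perimeter = r$perimeter, mode = r$mode,
          bulk_facing = r$region$perimeter_bulk_facing,
          protein_facing = r$region$perimeter_protein_facing)),
        associated = list(
          perimeter = assoc, mode = assoc_res$mode,
          bulk_facing = assoc_res$region$perimeter_bulk_facing,
          protein_facing = assoc_res$region$perimeter_protein_facing))
    }
    dp <- perimeter_change(iso, assoc)
    ei <- mismatch_free_energy(dp, config$gamma[1], config$gamma[2])
    report$perimeters <- list(isolated = iso, associated = assoc)
    report$delta_p_nm <- dp
    report$dg_interval_kcal <- c(ei$dg_low, ei$dg_high)
  } else {
    ds <- if (!is.null(config$systems$dataset)) config$systems$dataset
    else if (!is.null(config$manifest))
      read_umbrella_dataset(config$manifest, temperature = config$temperature)
    else stop("binding mode: config needs manifest or systems$dataset")
    boot <- bootstrap_uncertainty(ds, n_boot = config$bootstrap$n,
                                  seed = config$bootstrap$seed,
                                  bins = config$wham$bins,
                                  temperature = config$temperature,
                                  tol = config$wham$tol,
                                  burn_in = config$wham$burn_in)
    report$tau_int <- boot$tau_int
    report$n_eff <- boot$n_eff
    report$profile <- list(x = boot$profile$x, F = boot$profile$F,
                           sigma_F = boot$sigma_F)
    if (!is.null(config$intervals)) {
      br <- binding_free_energy(boot$profile,
                                bound = as.numeric(config$intervals$bound),
                                reference = as.numeric(config$intervals$reference),
                                boot = boot)
      report$binding <- list(dg_kcal = br$dg, sigma_kcal = br$sigma,
                             formatted = .format_parenthetical(br$dg, br$sigma))
    }
  }
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(report)
}
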