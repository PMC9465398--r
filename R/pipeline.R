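#' Run the full edaphic modelling pipeline
#'
#' Executes every stage over one scenario: (optionally) generate synthetic
#' inputs, compose locations against the soil survey, fit the threshold
#' model on the training split, classify the landscape into a suitability
#' map with wetland/open-water exclusion, summarise land cover on suitable
#' soils, and validate by overlap with the held-out locations and the
#' occurrence points. All tabular artifacts plus a provenance sidecar
#' (seed, parameters, input checksums, per-stage counts) are written under
#' `out_dir`. Repeated runs with the same configuration and seed produce
#' byte-identical tabular outputs.
#'
#' @param config Either a [synthetic_config()] (the scenario is generated),
#'   a `synthetic_scenario`, or a path to a YAML file of
#'   [synthetic_config()] fields plus optional `fraction`, `cellsize`,
#'   `coverage_cutoff`.
#' @param out_dir Output directory; default `"edaphic_run"`.
#' @param fraction Training fraction for the split; default 0.7.
#' @param cellsize Suitability raster cell size (m); default 10.
#' @param coverage_cutoff Binarisation cutoff for held-out validation.
#' @param quicklook Also write a quick-look PNG of the fit.
#' @return Invisibly, a list with the fitted model, suitability map,
#'   cover summary, validation report and written paths.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = "edaphic_run",
                         fraction = 0.7, cellsize = 10,
                         coverage_cutoff = 0.5, quicklook = FALSE) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    fraction <- cfg$fraction %||% fraction
    cellsize <- cfg$cellsize %||% cellsize
    coverage_cutoff <- cfg$coverage_cutoff %||% coverage_cutoff
    cfg <- cfg[intersect(names(cfg), names(formals(synthetic_config)))]
    config <- do.call(synthetic_config, cfg)
  }
  scenario <- if (inherits(config, "synthetic_scenario")) config
  else generate_scenario(config, dir = file.path(out_dir, "inputs"))
  cfg <- scenario$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  comp <- compose_locations(scenario$locations, scenario$survey,
                            cap_depth = cfg$cap_depth)
  fit <- edaphic_fit(comp, fraction = fraction, seed = cfg$seed,
                     cap_depth = cfg$cap_depth)
  mask <- exclusion_mask(scenario$landcover)
  map <- suitability_map(scenario$survey, fit, exclusion = mask,
                         cellsize = cellsize, cap_depth = cfg$cap_depth)
  cover <- summarize_cover(map, scenario$landcover)
  heldout <- subset_layer(scenario$locations,
                          scenario$locations$data$location_id %in% fit$validation_ids)
  report <- validation_report(map, heldout = heldout,
                              species = scenario$occurrences,
                              coverage_cutoff = coverage_cutoff)

  paths <- c(
    locations = write_report(
      comp$summary, file.path(out_dir, "location_summary.csv"),
      c(location_id = "ecosystem location",
        mean_sand = "area-weighted mean percent sand (%)",
        mean_depth_cm = "area-weighted mean soil depth (cm)",
        total_area_m2 = "location area (m^2)")),
    calibration = write_report(
      calibration_table(fit), file.path(out_dir, "calibration.csv"),
      c(quantity = "calibrated quantity", value = "value")),
    cover = write_report(cover, file.path(out_dir, "cover_summary.csv")),
    validation = write_report(report, file.path(out_dir, "validation.csv")),
    suitability = write_ascii_grid(map$raster, file.path(out_dir, "suitability.asc"))
  )
  if (quicklook) {
    grDevices::png(file.path(out_dir, "fit.png"), width = 700, height = 600)
    plot(fit)
    grDevices::dev.off()
    paths <- c(paths, quicklook = file.path(out_dir, "fit.png"))
  }
  provenance <- list(
    seed = cfg$seed,
    fraction = fraction,
    cellsize = cellsize,
    cap_depth = cfg$cap_depth,
    n_locations_used = nrow(fit$training) + fit$n_validation,
    n_locations_excluded = length(fit$excluded_ids),
    n_train = fit$n_train,
    n_validation = fit$n_validation,
    sand_threshold = unname(fit$thresholds["sand"]),
    depth_threshold = unname(fit$thresholds["depth"]),
    suitable_area_km2 = suitable_area(map),
    outputs = as.list(tools::md5sum(unname(paths)))
  )
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  invisible(list(fit = fit, map = map, cover = cover, validation = report,
                 scenario = scenario, paths = paths,
                 provenance = provenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

calibration_table <- function(fit) {
  data.frame(
    quantity = c("n_train", "n_validation", "mean_sand", "sd_sand",
                 "mean_depth_cm", "sd_depth_cm", "sand_threshold",
                 "depth_threshold", "sand_threshold_raw", "depth_threshold_raw",
                 "split_fraction", "seed"),
    value = c(fit$n_train, fit$n_validation, fit$stats["mean_sand"],
              fit$stats["sd_sand"], fit$stats["mean_depth"],
              fit$stats["sd_depth"], fit$thresholds["sand"],
              fit$thresholds["depth"], fit$thresholds_raw["sand"],
              fit$thresholds_raw["depth"], fit$fraction, fit$seed),
    stringsAsFactors = FALSE
  )
}

# subset a vector_layer by a logical index
subset_layer <- function(layer, keep) {
  vector_layer(layer$geometry[keep], layer$data[keep, , drop = FALSE],
               crs = layer$crs)
}
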