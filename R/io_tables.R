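#' Soil survey datasets
#'
#' A `soil_survey` mirrors the nested structure of SSURGO-style soil surveys:
#' map-unit polygons, a component table (the "soil types" making up each map
#' unit with their areal fractions and depth to the nearest restrictive
#' layer) and a horizon table (depth-ordered layers of each component with
#' percent sand). Percent sand and restrictive depth may be missing; missing
#' values are `NA`, never 0, because 0 is a legal sand content.
#'
#' @param mapunits A [vector_layer()] of map-unit polygons with a
#'   `mapunit_id` attribute, or `NULL` for a purely tabular survey.
#' @param components Data frame with columns `mapunit_id`, `soil_type_id`,
#'   `areal_fraction` (0–1, summing to 1 per map unit) and
#'   `restrictive_depth_cm` (NA when no restrictive layer is reported).
#' @param horizons Data frame with columns `soil_type_id`, `top_cm`,
#'   `bottom_cm`, `percent_sand` (NA allowed).
#' @return An object of class `soil_survey`.
#' @export
soil_survey <- function(mapunits, components, horizons) {
  components <- as.data.frame(components)
  horizons <- as.data.frame(horizons)
  obj <- structure(list(mapunits = mapunits, components = components,
                        horizons = horizons),
                   class = "soil_survey")
  validate_soil_survey(obj)
  obj
}

#' @export
print.soil_survey <- function(x, ...) {
  cat(sprintf("<soil_survey> %d map unit(s), %d component(s), %d horizon(s)\n",
              length(unique(x$components$mapunit_id)),
              nrow(x$components), nrow(x$horizons)))
  invisible(x)
}

#' Validate a soil survey
#'
#' Checks the structural invariants: component fractions sum to 1 per map
#' unit, horizon depth intervals are positive and non-overlapping within a
#' component, and percent sand lies in \[0, 100\] where present. Violations
#' raise errors naming the offending map unit or soil type rather than
#' silently dropping rows.
#'
#' @param survey A [soil_survey()].
#' @return `survey`, invisibly, when valid.
#' @export
validate_soil_survey <- function(survey) {
  comp <- survey$components
  hz <- survey$horizons
  need_c <- c("mapunit_id", "soil_type_id", "areal_fraction", "restrictive_depth_cm")
  need_h <- c("soil_type_id", "top_cm", "bottom_cm", "percent_sand")
  miss <- setdiff(need_c, names(comp))
  if (length(miss)) stop("component table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_h, names(hz))
  if (length(miss)) stop("horizon table lacks column(s): ", paste(miss, collapse = ", "))

  fr_sum <- tapply(comp$areal_fraction, comp$mapunit_id, sum)
  bad <- names(fr_sum)[abs(fr_sum - 1) > 1e-6]
  if (length(bad)) {
    stop("component areal fractions do not sum to 1 for map unit(s): ",
         paste(bad, collapse = ", "))
  }
  sand <- hz$percent_sand
  if (any(!is.na(sand) & (sand < 0 | sand > 100))) {
    stop("percent sand outside [0, 100] for soil type(s): ",
         paste(unique(hz$soil_type_id[!is.na(sand) & (sand < 0 | sand > 100)]),
               collapse = ", "))
  }
  if (any(hz$bottom_cm <= hz$top_cm)) {
    stop("non-positive horizon thickness for soil type(s): ",
         paste(unique(hz$soil_type_id[hz$bottom_cm <= hz$top_cm]), collapse = ", "))
  }
  overlapping <- vapply(split(hz, hz$soil_type_id), function(h) {
    h <- h[order(h$top_cm), ]
    nrow(h) > 1 && any(h$top_cm[-1] < h$bottom_cm[-nrow(h)] - 1e-9)
  }, logical(1))
  if (any(overlapping)) {
    stop("overlapping horizons for soil type(s): ",
         paste(names(overlapping)[overlapping], collapse = ", "))
  }
  rd <- comp$restrictive_depth_cm
  if (any(!is.na(rd) & rd <= 0)) {
    stop("non-positive restrictive depth for soil type(s): ",
         paste(unique(comp$soil_type_id[!is.na(rd) & rd <= 0]), collapse = ", "))
  }
  if (!is.null(survey$mapunits)) {
    if (!"mapunit_id" %in% names(survey$mapunits$data)) {
      stop("map-unit layer lacks a mapunit_id attribute")
    }
  }
  invisible(survey)
}

# column dialects for delimited soil tables; "ssurgo" accepts the column
# names of a raw SSURGO/gSSURGO export (component, chorizon tables)
soil_dialects <- list(
  native = list(
    components = c(mapunit_id = "mapunit_id", soil_type_id = "soil_type_id",
                   areal_fraction = "areal_fraction",
                   restrictive_depth_cm = "restrictive_depth_cm"),
    horizons = c(soil_type_id = "soil_type_id", top_cm = "top_cm",
                 bottom_cm = "bottom_cm", percent_sand = "percent_sand"),
    fraction_scale = 1
  ),
  ssurgo = list(
    components = c(mapunit_id = "mukey", soil_type_id = "cokey",
                   areal_fraction = "comppct_r",
                   restrictive_depth_cm = "resdept_r"),
    horizons = c(soil_type_id = "cokey", top_cm = "hzdept_r",
                 bottom_cm = "hzdepb_r", percent_sand = "sandtotal_r"),
    fraction_scale = 0.01  # comppct_r is a percentage
  )
)

read_mapped_table <- function(path, colmap, what) {
  if (!file.exists(path)) stop("cannot read ", what, " table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(colmap), names(tab))
  if (length(miss)) {
    stop(what, " table ", basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- tab[, unname(colmap), drop = FALSE]
  names(out) <- names(colmap)
  out
}

#' Read soil-survey tables
#'
#' Reads the component and horizon CSV tables (and optionally a GeoJSON
#' map-unit layer) into a validated [soil_survey()]. Two column dialects are
#' understood: `"native"` (this package's column names) and `"ssurgo"`
#' (raw SSURGO export names: `mukey`/`cokey`/`comppct_r`/`resdept_r` and
#' `hzdept_r`/`hzdepb_r`/`sandtotal_r`). Under the `"ssurgo"` dialect the
#' component percentage is rescaled to a 0–1 fraction and renormalised per
#' map unit when the raw percentages do not total 100.
#'
#' A "soil type" is a SSURGO component; its area inside any polygon is the
#' polygon-intersection area times the component's areal fraction, the only
#' within-map-unit area information a soil survey carries.
#'
#' @param components_path,horizons_path CSV paths.
#' @param mapunits_path Optional GeoJSON path for map-unit polygons.
#' @param dialect `"native"` or `"ssurgo"`.
#' @return A validated [soil_survey()].
#' @export
read_soil_tables <- function(components_path, horizons_path,
                             mapunits_path = NULL,
                             dialect = c("native", "ssurgo")) {
  dialect <- match.arg(dialect)
  d <- soil_dialects[[dialect]]
  comp <- read_mapped_table(components_path, d$components, "component")
  hz <- read_mapped_table(horizons_path, d$horizons, "horizon")
  comp$areal_fraction <- comp$areal_fraction * d$fraction_scale
  if (dialect == "ssurgo") {
    tot <- stats::ave(comp$areal_fraction, comp$mapunit_id, FUN = sum)
    comp$areal_fraction <- comp$areal_fraction / tot
  }
  hz <- hz[order(match(hz$soil_type_id, unique(hz$soil_type_id)), hz$top_cm), ]
  mapunits <- if (!is.null(mapunits_path)) read_vector_layer(mapunits_path, quiet = TRUE)
  soil_survey(mapunits, comp, hz)
}

#' Write soil-survey tables
#'
#' Writes `components.csv`, `horizons.csv` and (when polygons are present)
#' `mapunits.geojson` under `dir`, in the native dialect. The written files
#' round-trip through [read_soil_tables()].
#'
#' @param survey A [soil_survey()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_soil_tables <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "components.csv")
  hpath <- file.path(dir, "horizons.csv")
  write_full_precision_csv(survey$components, cpath)
  write_full_precision_csv(survey$horizons, hpath)
  paths <- c(components = cpath, horizons = hpath)
  if (!is.null(survey$mapunits)) {
    mpath <- file.path(dir, "mapunits.geojson")
    write_vector_layer(survey$mapunits, mpath)
    paths <- c(paths, mapunits = mpath)
  }
  invisible(paths)
}

# CSV writer that survives a write->read round trip at full double precision
write_full_precision_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- formatC(out[[j]], format = "g", digits = 17)
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
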