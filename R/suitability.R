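#' Threshold rule
#'
#' A pair of inclusive lower bounds: a soil is suitable when its mean percent
#' sand and its capped restrictive depth are each at least the threshold
#' ("at least as sandy and deep").
#'
#' @param sand_threshold Percent sand threshold.
#' @param depth_threshold Depth threshold (cm).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(sand_threshold, depth_threshold) {
  stopifnot(is.finite(sand_threshold), is.finite(depth_threshold))
  structure(list(sand = as.numeric(sand_threshold),
                 depth = as.numeric(depth_threshold),
                 comparison = ">="),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> suitable iff sand >= %g %% and depth >= %g cm\n",
              x$sand, x$depth))
  invisible(x)
}

#' Classify soil properties against a threshold rule
#'
#' Inclusive comparison: a soil exactly on both thresholds is suitable.
#' Missing inputs yield `"nodata"`, never `"unsuitable"` — absence of a lab
#' value is not evidence of unsuitability.
#'
#' @param mean_sand,depth_cm Numeric vectors (recycled to common length).
#' @param rule A [threshold_rule()].
#' @return Character vector: `"suitable"`, `"unsuitable"` or `"nodata"`.
#' @export
classify_soil_type <- function(mean_sand, depth_cm, rule) {
  n <- max(length(mean_sand), length(depth_cm))
  mean_sand <- rep_len(as.numeric(mean_sand), n)
  depth_cm <- rep_len(as.numeric(depth_cm), n)
  out <- ifelse(mean_sand >= rule$sand & depth_cm >= rule$depth,
                "suitable", "unsuitable")
  out[is.na(mean_sand) | is.na(depth_cm)] <- "nodata"
  out
}

#' Classify every map unit of a survey
#'
#' Map-unit values are the component aggregates weighted by component areal
#' fraction (the same convention as location composition): mean sand over
#' components with sand data (fractions renormalised), depth over all
#' components.
#'
#' @param survey A [soil_survey()].
#' @param rule A [threshold_rule()].
#' @param cap_depth Maximum reported depth (cm).
#' @return Data frame with one row per map unit: `mapunit_id`, `mean_sand`,
#'   `depth_cm`, `state`.
#' @export
classify_survey <- function(survey, rule, cap_depth = 200) {
  prof <- aggregate_profiles(survey, cap_depth)
  comp <- survey$components
  comp$mean_sand <- prof$mean_sand[match(comp$soil_type_id, prof$soil_type_id)]
  comp$depth_cm <- prof$depth_cm[match(comp$soil_type_id, prof$soil_type_id)]
  ok <- !is.na(comp$mean_sand)
  sand_num <- rowsum((comp$areal_fraction * comp$mean_sand)[ok], comp$mapunit_id[ok])
  sand_den <- rowsum(comp$areal_fraction[ok], comp$mapunit_id[ok])
  depth_num <- rowsum(comp$areal_fraction * comp$depth_cm, comp$mapunit_id)
  depth_den <- rowsum(comp$areal_fraction, comp$mapunit_id)
  ids <- rownames(depth_num)
  sand <- stats::setNames(rep(NA_real_, length(ids)), ids)
  sand[rownames(sand_num)] <- sand_num / sand_den
  depth <- as.numeric(depth_num / depth_den)
  data.frame(
    mapunit_id = ids,
    mean_sand = unname(sand),
    depth_cm = depth,
    state = classify_soil_type(unname(sand), depth, rule),
    stringsAsFactors = FALSE
  )
}

state_codes <- c(unsuitable = 0, suitable = 1, excluded = 2, nodata = 255)

#' Build a suitability map
#'
#' Classifies every map unit of the survey against the rule, rasterises the
#' states onto a regular grid, and marks cells under the exclusion mask
#' (wetland / open water) as excluded regardless of their soil state. The
#' exclusion mask may be on a coarser grid (e.g. a 30 m land-cover product
#' against a 10 m soil grid); it is resampled to the soil grid by nearest
#' neighbour.
#'
#' @param survey A [soil_survey()] with map-unit polygons.
#' @param rule A [threshold_rule()] (or an [edaphic_fit()], whose thresholds
#'   are used).
#' @param exclusion Optional [grid_raster()]; cells with value 1 (or `TRUE`)
#'   are excluded. Use [exclusion_mask()] to derive one from land cover.
#' @param cellsize Output cell size in metres; default 10 (the resolution of
#'   gridded soil surveys).
#' @param cap_depth Maximum reported depth (cm).
#' @return An object of class `suitability_map`: the per-unit classification
#'   (`units`), the map-unit geometry, and a state raster coded
#'   1 = suitable, 0 = unsuitable, 2 = excluded, 255 = nodata.
#' @export
suitability_map <- function(survey, rule, exclusion = NULL, cellsize = 10,
                            cap_depth = 200) {
  if (inherits(rule, "edaphic_fit")) {
    rule <- threshold_rule(rule$thresholds["sand"], rule$thresholds["depth"])
  }
  if (is.null(survey$mapunits)) stop("survey has no map-unit polygons")
  units <- classify_survey(survey, rule, cap_depth)
  geom <- survey$mapunits$geometry
  mu_id <- as.character(survey$mapunits$data$mapunit_id)
  units <- units[match(mu_id, units$mapunit_id), , drop = FALSE]

  bbs <- vapply(geom, geom_bbox, numeric(4))
  xmin <- min(bbs[1, ]); ymin <- min(bbs[2, ])
  xmax <- max(bbs[3, ]); ymax <- max(bbs[4, ])
  template <- grid_raster(
    matrix(255, nrow = ceiling((ymax - ymin) / cellsize),
           ncol = ceiling((xmax - xmin) / cellsize)),
    xmin = xmin, ymin = ymin, cellsize = cellsize, nodata = 255,
    crs = survey$mapunits$crs
  )
  codes <- state_codes[units$state]
  r <- rasterize_features(geom, codes, template, background = 255)
  if (!is.null(exclusion)) {
    if (!identical(exclusion$crs, r$crs)) {
      stop("CRS mismatch between survey (", r$crs, ") and exclusion mask (",
           exclusion$crs, ")")
    }
    mask <- resample_nearest(exclusion, r)
    excl <- mask$values == 1 & !is.na(mask$values) & mask$values != mask$nodata
    r$values[excl] <- state_codes["excluded"]
  }
  structure(list(units = units, geometry = geom, mapunit_id = mu_id,
                 raster = r, rule = rule, cellsize = cellsize,
                 crs = template$crs),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  tab <- table(factor(x$raster$values, levels = state_codes,
                      labels = names(state_codes)))
  cat(sprintf("<suitability_map> %d map unit(s), %g m cells, CRS %s\n",
              length(x$geometry), x$cellsize, x$crs))
  cat(sprintf("  rule: sand >= %g %%, depth >= %g cm\n", x$rule$sand, x$rule$depth))
  a <- tab * x$cellsize^2 / 1e6
  cat(sprintf("  suitable %.1f km^2, unsuitable %.1f km^2, excluded %.1f km^2\n",
              a["suitable"], a["unsuitable"], a["excluded"]))
  invisible(x)
}

#' Suitable area of a suitability map
#'
#' @param map A [suitability_map()].
#' @param source `"raster"` (default; counts suitable cells, respecting the
#'   exclusion mask) or `"vector"` (sums suitable map-unit polygon areas,
#'   ignoring any exclusion mask).
#' @return Area in km^2.
#' @export
suitable_area <- function(map, source = c("raster", "vector")) {
  source <- match.arg(source)
  if (source == "raster") {
    n <- sum(map$raster$values == state_codes["suitable"], na.rm = TRUE)
    return(n * map$cellsize^2 / 1e6)
  }
  suit <- map$units$state == "suitable"
  sum(vapply(map$geometry[suit], geom_area, numeric(1))) / 1e6
}

#' Exclusion mask from categorical land cover
#'
#' Builds a 0/1 raster marking wetland and open-water cells, given a raw
#' land-cover raster and a [landcover_scheme()] (cells mapping to the
#' `"excluded"` category become 1).
#'
#' @param cover A [grid_raster()] of raw land-cover codes.
#' @param scheme A [landcover_scheme()]; default [nlcd_scheme()].
#' @return A 0/1 [grid_raster()].
#' @export
exclusion_mask <- function(cover, scheme = nlcd_scheme()) {
  cat_r <- reclassify_landcover(cover, scheme)
  excl_code <- match("excluded", attr(cat_r, "categories"))
  vals <- ifelse(cat_r$values == excl_code, 1, 0)
  vals[cat_r$values == cat_r$nodata] <- 0
  grid_raster(vals, cover$xmin, cover$ymin, cover$cellsize,
              nodata = -9999, crs = cover$crs)
}
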