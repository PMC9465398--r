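#' Location compositions
#'
#' A `location_composition` records which soil types make up one ecosystem
#' location and with what area: the geometric intersection of the location
#' polygon with the survey's map-unit polygons, with each map unit's area
#' shared among its components in proportion to their areal fractions.
#'
#' @param location_id Identifier of the location.
#' @param soil_type_id Character vector of member soil types.
#' @param area_m2 Member areas (m^2), all positive.
#' @param mean_sand Member depth-weighted mean percent sand (NA allowed).
#' @param depth_cm Member capped restrictive depths (cm); never NA after
#'   [profile_depth()] capping.
#' @return An object of class `location_composition`.
#' @export
location_composition <- function(location_id, soil_type_id, area_m2,
                                 mean_sand, depth_cm) {
  if (length(soil_type_id) < 1) {
    stop("location ", location_id, ": composition must have at least one member")
  }
  if (any(area_m2 <= 0)) {
    stop("location ", location_id, ": member areas must be positive")
  }
  structure(list(location_id = location_id,
                 members = data.frame(soil_type_id = soil_type_id,
                                      area_m2 = as.numeric(area_m2),
                                      mean_sand = as.numeric(mean_sand),
                                      depth_cm = as.numeric(depth_cm),
                                      stringsAsFactors = FALSE),
                 total_area_m2 = sum(area_m2)),
            class = "location_composition")
}

#' @export
print.location_composition <- function(x, ...) {
  cat(sprintf("<location_composition> %s: %d soil type(s), %.0f m^2\n",
              x$location_id, nrow(x$members), x$total_area_m2))
  invisible(x)
}

#' Intersect one location polygon with a soil survey
#'
#' Clips the location polygon against every candidate map-unit polygon
#' (bounding boxes prune the candidates), sums fragment areas per map unit,
#' distributes each map unit's area over its components by areal fraction,
#' and attaches the per-soil-type aggregates. Map-unit polygons must be
#' convex rings (grid and Voronoi tessellations are); the location polygon
#' itself may be any simple polygon. Sliver intersections below `min_area`
#' (default 1 m^2) are discarded as overlay noise.
#'
#' @param location_polygon Ring matrix (or list of rings) of the location.
#' @param survey A [soil_survey()] with map-unit polygons.
#' @param location_id Identifier used in the result and error messages.
#' @param cap_depth Maximum reported depth (cm) for [profile_depth()].
#' @param min_area Minimum intersection area kept (m^2).
#' @param profiles Optional precomputed [aggregate_profiles()] table (an
#'   optimisation when composing many locations against one survey).
#' @param mu_bbox Optional precomputed 4 x n matrix of map-unit bounding
#'   boxes (rows xmin, ymin, xmax, ymax), same optimisation.
#' @return A [location_composition()].
#' @export
compose_location <- function(location_polygon, survey, location_id = "location",
                             cap_depth = 200, min_area = 1, profiles = NULL,
                             mu_bbox = NULL) {
  if (is.numeric(location_polygon) && is.null(dim(location_polygon))) {
    stop("location ", location_id,
         ": point locations are not supported; supply a polygon")
  }
  if (is.null(survey$mapunits)) {
    stop("survey has no map-unit polygons; cannot compose locations")
  }
  if (is.null(profiles)) profiles <- aggregate_profiles(survey, cap_depth)
  mu_geom <- survey$mapunits$geometry
  mu_id <- survey$mapunits$data$mapunit_id
  if (is.null(mu_bbox)) mu_bbox <- vapply(mu_geom, geom_bbox, numeric(4))
  bb <- geom_bbox(location_polygon)
  candidates <- which(mu_bbox[1, ] <= bb["xmax"] & mu_bbox[3, ] >= bb["xmin"] &
                        mu_bbox[2, ] <= bb["ymax"] & mu_bbox[4, ] >= bb["ymin"])
  areas <- numeric(length(mu_geom))
  for (i in candidates) {
    rings <- geom_rings(mu_geom[[i]])
    if (!all(vapply(rings, is_convex_ring, logical(1)))) {
      stop("map unit ", mu_id[i], ": non-convex map-unit polygons are not supported")
    }
    areas[i] <- sum(vapply(rings, function(r) intersection_area(location_polygon, r),
                           numeric(1)))
  }
  hit <- which(areas >= min_area)
  if (!length(hit)) {
    stop("location ", location_id, " does not intersect any soil map unit")
  }
  mu_area <- rowsum(areas[hit], mu_id[hit])
  comp <- survey$components[survey$components$mapunit_id %in% rownames(mu_area), ]
  member_area <- comp$areal_fraction * mu_area[as.character(comp$mapunit_id), 1]
  keep <- member_area >= min_area
  comp <- comp[keep, , drop = FALSE]
  member_area <- member_area[keep]
  # one member per soil type, areas summed across map units
  agg <- rowsum(member_area, comp$soil_type_id)
  sid <- rownames(agg)
  prof <- profiles[match(sid, profiles$soil_type_id), ]
  location_composition(location_id, sid, as.numeric(agg),
                       prof$mean_sand, prof$depth_cm)
}

#' Area-weighted location mean percent sand
#'
#' Weights each constituent soil type's mean percent sand by its area within
#' the location. Members with missing sand are excluded from numerator and
#' denominator alike; if every member is missing the result is `NA` with
#' attribute `no_data = TRUE`.
#'
#' @param comp A [location_composition()].
#' @return Percent sand, or flagged `NA`.
#' @export
location_mean_sand <- function(comp) {
  m <- comp$members
  ok <- !is.na(m$mean_sand)
  if (!any(ok)) return(structure(NA_real_, no_data = TRUE))
  sum(m$area_m2[ok] * m$mean_sand[ok]) / sum(m$area_m2[ok])
}

#' Area-weighted location mean soil depth
#'
#' @param comp A [location_composition()].
#' @return Depth in cm.
#' @export
location_mean_depth <- function(comp) {
  m <- comp$members
  sum(m$area_m2 * m$depth_cm) / sum(m$area_m2)
}

#' Compose every location in a layer and summarise
#'
#' @param locations A [vector_layer()] of location polygons with a
#'   `location_id` attribute (row numbers are used when absent).
#' @param survey A [soil_survey()].
#' @param cap_depth,min_area Passed to [compose_location()].
#' @return A list with `compositions` (list of [location_composition()]) and
#'   `summary`, a data frame of `location_id`, `mean_sand`, `mean_depth_cm`
#'   and `total_area_m2` — the per-location table behind threshold
#'   calibration.
#' @export
compose_locations <- function(locations, survey, cap_depth = 200, min_area = 1) {
  ids <- if ("location_id" %in% names(locations$data)) {
    as.character(locations$data$location_id)
  } else {
    as.character(seq_along(locations$geometry))
  }
  profiles <- aggregate_profiles(survey, cap_depth)
  mu_bbox <- vapply(survey$mapunits$geometry, geom_bbox, numeric(4))
  comps <- lapply(seq_along(locations$geometry), function(i) {
    compose_location(locations$geometry[[i]], survey, ids[i],
                     cap_depth = cap_depth, min_area = min_area,
                     profiles = profiles, mu_bbox = mu_bbox)
  })
  summary <- data.frame(
    location_id = ids,
    mean_sand = vapply(comps, function(cc) as.numeric(location_mean_sand(cc)), numeric(1)),
    mean_depth_cm = vapply(comps, location_mean_depth, numeric(1)),
    total_area_m2 = vapply(comps, function(cc) cc$total_area_m2, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(compositions = comps, summary = summary)
}
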