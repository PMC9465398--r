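#' Configuration for the synthetic soil-survey generator
#'
#' The generator emulates the statistical structure of a gridded soil survey
#' over a glaciated landscape: contiguous sandy, deep outwash patches
#' embedded in a loamier, shallower background; ecosystem locations placed
#' on those patches; occurrence points concentrated on suitable soil; and a
#' categorical land-cover raster whose class mix differs between patch and
#' background. Every quantity the pipeline later estimates is recorded as
#' ground truth from the same random draws.
#'
#' Defaults describe a 50 km x 50 km landscape of ~1 km^2 map units with
#' 156 known ecosystem locations; patch soils draw sand from a truncated
#' Normal(87, 11) and restrictive depth from Normal(193, 33) capped at
#' 200 cm, so that threshold calibration on the default scenario lands near
#' 76% sand and 160 cm depth.
#'
#' @param extent_m Side of the square landscape (m).
#' @param mapunit_m Side of the square map units (m); must divide `extent_m`.
#' @param patch_fraction Fraction of map units belonging to sandy patches.
#' @param n_patch_seeds Number of contiguous patches grown.
#' @param sand_patch,sand_background `c(mean, sd)` of component percent sand,
#'   truncated to \[0, 100\].
#' @param depth_patch,depth_background `c(mean, sd)` of component restrictive
#'   depth (cm); draws at or beyond `cap_depth` are written as "no
#'   restrictive layer reported" (NA).
#' @param cap_depth Maximum reported depth (cm).
#' @param horizons_range,components_range Integer ranges (min, max) of
#'   horizons per component and components per map unit.
#' @param horizon_sand_sd Within-profile SD of horizon sand around the
#'   component's level (percentage points).
#' @param missing_sand_rate Fraction of horizons with unreported sand.
#' @param n_locations Number of ecosystem locations.
#' @param location_area_range `c(min, max)` location area (m^2); log-uniform.
#' @param location_aspect_max Maximum side ratio of the (rotated)
#'   rectangular locations.
#' @param location_patch_bias Probability that a location is placed on a
#'   sandy-patch map unit. Known high-quality remnants sit on suitable soil
#'   by construction, so the default is 1.
#' @param n_species Number of species occurrence groups.
#' @param points_per_species Points per group.
#' @param high_affinity_fraction Fraction of groups labelled high-affinity.
#' @param affinity_high,affinity_other Probability that a point of a
#'   high-/other-affinity group is placed on a truly suitable map unit
#'   (otherwise uniform over the landscape).
#' @param landcover_cell_m Land-cover raster cell size (m); default 30.
#' @param landcover_patch,landcover_background Named category fractions
#'   (forest, open, agriculture, urban, water, wetland, other) conditional
#'   on patch membership; each must sum to 1.
#' @param seed Integer seed; a fixed seed reproduces the scenario exactly.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(extent_m = 50000,
                             mapunit_m = 1000,
                             patch_fraction = 0.12,
                             n_patch_seeds = 5,
                             sand_patch = c(mean = 87, sd = 11),
                             sand_background = c(mean = 45, sd = 15),
                             depth_patch = c(mean = 193, sd = 33),
                             depth_background = c(mean = 90, sd = 40),
                             cap_depth = 200,
                             horizons_range = c(2L, 5L),
                             components_range = c(1L, 3L),
                             horizon_sand_sd = 4,
                             missing_sand_rate = 0.02,
                             n_locations = 156,
                             location_area_range = c(5e4, 3e5),
                             location_aspect_max = 2,
                             location_patch_bias = 1,
                             n_species = 10,
                             points_per_species = 20,
                             high_affinity_fraction = 0.5,
                             affinity_high = 0.87,
                             affinity_other = 0.6,
                             landcover_cell_m = 30,
                             landcover_patch = c(forest = 0.55, open = 0.04,
                                                 agriculture = 0.12, urban = 0.25,
                                                 water = 0.015, wetland = 0.015,
                                                 other = 0.01),
                             landcover_background = c(forest = 0.45, open = 0.05,
                                                      agriculture = 0.25, urban = 0.15,
                                                      water = 0.04, wetland = 0.04,
                                                      other = 0.02),
                             seed = 1) {
  cfg <- as.list(environment())
  if (extent_m %% mapunit_m != 0) stop("mapunit_m must divide extent_m")
  n_units <- (extent_m / mapunit_m)^2
  if (patch_fraction > 0 && round(patch_fraction * n_units) < 1) {
    stop("patch_fraction too small: no map unit would be a patch")
  }
  for (f in c("patch_fraction", "location_patch_bias", "high_affinity_fraction",
              "affinity_high", "affinity_other", "missing_sand_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("landcover_patch", "landcover_background")) {
    if (abs(sum(cfg[[f]]) - 1) > 1e-8) stop(f, " fractions must sum to 1")
  }
  structure(cfg, class = "synthetic_config")
}

# inverse-CDF draw from Normal(mean, sd) truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# grow `n_patch` contiguous patch units from `n_seeds` seeds on an s x s grid
grow_patches <- function(s, n_patch, n_seeds) {
  n <- s * s
  patch <- logical(n)
  if (n_patch == 0) return(patch)
  seeds <- sample.int(n, min(n_seeds, n_patch))
  patch[seeds] <- TRUE
  frontier <- seeds
  while (sum(patch) < n_patch) {
    if (!length(frontier)) {
      frontier <- sample(which(!patch), 1)
      patch[frontier] <- TRUE
      next
    }
    cell <- frontier[sample.int(length(frontier), 1)]
    r <- (cell - 1) %% s + 1
    cidx <- (cell - 1) %/% s + 1
    nbr <- c(if (r > 1) cell - 1, if (r < s) cell + 1,
             if (cidx > 1) cell - s, if (cidx < s) cell + s)
    nbr <- nbr[!patch[nbr]]
    if (!length(nbr)) {
      frontier <- setdiff(frontier, cell)
      next
    }
    new <- nbr[sample.int(length(nbr), 1)]
    patch[new] <- TRUE
    frontier <- c(frontier, new)
  }
  patch
}

#' Generate a synthetic soil survey with ground truth
#'
#' Tessellates the landscape into square map units, grows contiguous sandy
#' patches, and samples components and horizons for every unit. The returned
#' ground-truth table records each map unit's true depth-weighted,
#' fraction-weighted mean sand and capped depth, computed from the very
#' draws written into the tables (bookkeeping, not re-estimation).
#'
#' @param config A [synthetic_config()].
#' @return List with `survey` (a [soil_survey()]) and `truth` (data frame
#'   with `mapunit_id`, `patch`, `true_sand`, `true_depth_cm`, `area_m2`).
#' @export
generate_soil_survey <- function(config) {
  with_seed(config$seed + 1L, generate_soil_survey_impl(config))
}

generate_soil_survey_impl <- function(config) {
  s <- config$extent_m / config$mapunit_m
  n_units <- s * s
  patch <- grow_patches(s, round(config$patch_fraction * n_units),
                        config$n_patch_seeds)
  mu_id <- sprintf("mu%05d", seq_len(n_units))
  # unit (i = row from south, j = column) -> rectangle
  unit_row <- (seq_len(n_units) - 1) %% s
  unit_col <- (seq_len(n_units) - 1) %/% s
  geoms <- lapply(seq_len(n_units), function(k) {
    x0 <- unit_col[k] * config$mapunit_m
    y0 <- unit_row[k] * config$mapunit_m
    rect_ring(x0, y0, x0 + config$mapunit_m, y0 + config$mapunit_m)
  })
  mapunits <- vector_layer(geoms, data.frame(mapunit_id = mu_id,
                                             stringsAsFactors = FALSE))

  comp_choices <- seq(config$components_range[1], config$components_range[2])
  n_comp <- comp_choices[sample.int(length(comp_choices), n_units, replace = TRUE)]
  comp_unit <- rep(seq_len(n_units), n_comp)
  total_comp <- length(comp_unit)
  frac <- stats::rgamma(total_comp, shape = 3)
  frac <- frac / rep(rowsum(frac, comp_unit), n_comp)

  comp_patch <- patch[comp_unit]
  sand_level <- numeric(total_comp)
  sand_level[comp_patch] <- rtruncnorm(sum(comp_patch),
                                       config$sand_patch["mean"],
                                       config$sand_patch["sd"], 0, 100)
  sand_level[!comp_patch] <- rtruncnorm(sum(!comp_patch),
                                        config$sand_background["mean"],
                                        config$sand_background["sd"], 0, 100)
  depth_draw <- numeric(total_comp)
  depth_draw[comp_patch] <- stats::rnorm(sum(comp_patch),
                                         config$depth_patch["mean"],
                                         config$depth_patch["sd"])
  depth_draw[!comp_patch] <- stats::rnorm(sum(!comp_patch),
                                          config$depth_background["mean"],
                                          config$depth_background["sd"])
  depth_draw <- pmax(depth_draw, 20)
  # at/beyond the cap the survey reports no restrictive layer
  restrictive <- ifelse(depth_draw >= config$cap_depth, NA_real_, depth_draw)
  true_depth <- pmin(depth_draw, config$cap_depth)

  cokey <- sprintf("co%06d", seq_len(total_comp))
  components <- data.frame(
    mapunit_id = mu_id[comp_unit],
    soil_type_id = cokey,
    areal_fraction = frac,
    restrictive_depth_cm = restrictive,
    stringsAsFactors = FALSE
  )

  hz_choices <- seq(config$horizons_range[1], config$horizons_range[2])
  n_hz <- hz_choices[sample.int(length(hz_choices), total_comp, replace = TRUE)]
  hz_comp <- rep(seq_len(total_comp), n_hz)
  # horizon boundaries: sorted uniform cuts of the described profile
  profile_bottom <- true_depth
  bounds <- lapply(seq_len(total_comp), function(i) {
    k <- n_hz[i]
    cuts <- sort(stats::runif(k - 1, 0.15, 0.85)) * profile_bottom[i]
    c(0, cuts, profile_bottom[i])
  })
  top <- unlist(lapply(bounds, function(b) b[-length(b)]))
  bottom <- unlist(lapply(bounds, function(b) b[-1]))
  sand_hz <- pmin(100, pmax(0, sand_level[hz_comp] +
                              stats::rnorm(length(hz_comp), 0, config$horizon_sand_sd)))
  if (config$missing_sand_rate > 0) {
    sand_hz[stats::runif(length(sand_hz)) < config$missing_sand_rate] <- NA_real_
  }
  horizons <- data.frame(
    soil_type_id = cokey[hz_comp],
    top_cm = top,
    bottom_cm = bottom,
    percent_sand = sand_hz,
    stringsAsFactors = FALSE
  )

  # ground truth from the same draws: depth-weighted component sand over
  # horizons with data, fraction-weighted unit values with the same
  # missing-data renormalisation the aggregation stage defines
  len <- bottom - top
  ok <- !is.na(sand_hz)
  cnum <- rowsum((len * sand_hz)[ok], hz_comp[ok])
  cden <- rowsum(len[ok], hz_comp[ok])
  comp_sand <- rep(NA_real_, total_comp)
  comp_sand[as.integer(rownames(cnum))] <- cnum / cden
  okc <- !is.na(comp_sand)
  unum <- rowsum((frac * comp_sand)[okc], comp_unit[okc])
  uden <- rowsum(frac[okc], comp_unit[okc])
  unit_sand <- rep(NA_real_, n_units)
  unit_sand[as.integer(rownames(unum))] <- unum / uden
  unit_depth <- as.numeric(rowsum(frac * true_depth, comp_unit) /
                             rowsum(frac, comp_unit))

  truth <- data.frame(
    mapunit_id = mu_id,
    patch = patch,
    true_sand = unit_sand,
    true_depth_cm = unit_depth,
    area_m2 = config$mapunit_m^2,
    stringsAsFactors = FALSE
  )
  list(survey = soil_survey(mapunits, components, horizons), truth = truth)
}

#' True suitable area from a ground-truth table
#'
#' Sums the areas of map units whose true sand and depth pass the rule —
#' the generator-side oracle for [suitable_area()].
#'
#' @param truth Ground-truth table from [generate_soil_survey()].
#' @param rule A [threshold_rule()].
#' @return Area in km^2.
#' @export
true_suitable_area <- function(truth, rule) {
  pass <- !is.na(truth$true_sand) & truth$true_sand >= rule$sand &
    truth$true_depth_cm >= rule$depth
  sum(truth$area_m2[pass]) / 1e6
}

#' Generate synthetic ecosystem locations
#'
#' Places rotated rectangular locations, each wholly inside one map unit:
#' with probability `location_patch_bias` the unit is a sandy-patch unit,
#' otherwise a background unit. Location areas are log-uniform within the
#' configured range. Because a location sits inside a single unit, its true
#' mean sand and depth are that unit's ground-truth values exactly.
#'
#' @param config A [synthetic_config()].
#' @param survey_bundle Result of [generate_soil_survey()].
#' @return List with `locations` (a [vector_layer()] with `location_id`) and
#'   `truth` (per-location `location_id`, `mapunit_id`, `on_patch`,
#'   `true_sand`, `true_depth_cm`, `area_m2`).
#' @export
generate_locations <- function(config, survey_bundle) {
  with_seed(config$seed + 2L, generate_locations_impl(config, survey_bundle))
}

generate_locations_impl <- function(config, survey_bundle) {
  truth <- survey_bundle$truth
  s <- config$extent_m / config$mapunit_m
  patch_units <- which(truth$patch)
  bg_units <- which(!truth$patch)
  if (!length(patch_units)) patch_units <- bg_units
  if (!length(bg_units)) bg_units <- patch_units
  n <- config$n_locations
  on_patch <- stats::runif(n) < config$location_patch_bias
  unit <- integer(n)
  unit[on_patch] <- patch_units[sample.int(length(patch_units), sum(on_patch),
                                           replace = TRUE)]
  unit[!on_patch] <- bg_units[sample.int(length(bg_units), sum(!on_patch),
                                         replace = TRUE)]
  area <- exp(stats::runif(n, log(config$location_area_range[1]),
                           log(config$location_area_range[2])))
  aspect <- stats::runif(n, 1, config$location_aspect_max)
  angle <- stats::runif(n, 0, pi)
  geoms <- vector("list", n)
  for (i in seq_len(n)) {
    w <- sqrt(area[i] * aspect[i]); h <- sqrt(area[i] / aspect[i])
    ca <- cos(angle[i]); sa <- sin(angle[i])
    corners <- cbind(c(-w, w, w, -w) / 2, c(-h, -h, h, h) / 2) %*%
      rbind(c(ca, sa), c(-sa, ca))
    hx <- max(abs(corners[, 1])); hy <- max(abs(corners[, 2]))
    ux <- ((unit[i] - 1) %/% s) * config$mapunit_m
    uy <- ((unit[i] - 1) %% s) * config$mapunit_m
    cx <- stats::runif(1, ux + hx, ux + config$mapunit_m - hx)
    cy <- stats::runif(1, uy + hy, uy + config$mapunit_m - hy)
    geoms[[i]] <- cbind(corners[, 1] + cx, corners[, 2] + cy)
  }
  ids <- sprintf("loc%04d", seq_len(n))
  loc_truth <- data.frame(
    location_id = ids,
    mapunit_id = truth$mapunit_id[unit],
    on_patch = truth$patch[unit],
    true_sand = truth$true_sand[unit],
    true_depth_cm = truth$true_depth_cm[unit],
    area_m2 = area,
    stringsAsFactors = FALSE
  )
  list(locations = vector_layer(geoms, data.frame(location_id = ids,
                                                  stringsAsFactors = FALSE)),
       truth = loc_truth)
}

lc_category_codes <- c(forest = 41, open = 52, agriculture = 82, urban = 22,
                       water = 11, wetland = 90, other = 12)

#' Generate a synthetic land-cover raster
#'
#' Samples each cell's class from the patch- or background-conditional
#' category fractions, written as NLCD-style codes (41 forest, 52 open,
#' 82 agriculture, 22 urban, 11 water, 90 wetland, 12 other) so the default
#' [nlcd_scheme()] applies. The realised per-category cell counts are
#' attached as attribute `category_counts` (ground truth from the draws).
#'
#' @param config A [synthetic_config()].
#' @param survey_bundle Result of [generate_soil_survey()].
#' @return A [grid_raster()] of land-cover codes.
#' @export
generate_landcover <- function(config, survey_bundle) {
  with_seed(config$seed + 3L, generate_landcover_impl(config, survey_bundle))
}

generate_landcover_impl <- function(config, survey_bundle) {
  res <- config$landcover_cell_m
  ncell <- ceiling(config$extent_m / res)
  s <- config$extent_m / config$mapunit_m
  xc <- (seq_len(ncell) - 0.5) * res
  yc <- config$extent_m - (seq_len(ncell) - 0.5) * res  # row 1 = north
  ucol <- pmax(pmin(floor(xc / config$mapunit_m), s - 1), 0)
  urow <- pmax(pmin(floor(yc / config$mapunit_m), s - 1), 0)
  patch_grid <- matrix(survey_bundle$truth$patch[outer(urow, ucol * s, "+") + 1],
                       nrow = ncell)
  cats <- names(lc_category_codes)
  draw <- matrix(0L, nrow = ncell, ncol = ncell)
  for (is_patch in c(TRUE, FALSE)) {
    sel <- patch_grid == is_patch
    p <- if (is_patch) config$landcover_patch else config$landcover_background
    draw[sel] <- sample.int(length(cats), sum(sel), replace = TRUE,
                            prob = p[cats])
  }
  vals <- matrix(lc_category_codes[draw], nrow = ncell)
  r <- grid_raster(vals, xmin = 0, ymin = 0, cellsize = res, nodata = -9999)
  attr(r, "category_counts") <- stats::setNames(tabulate(draw, length(cats)), cats)
  r
}

#' Generate synthetic species occurrences
#'
#' Each group's points land on a uniformly chosen *truly suitable* map unit
#' with the group's affinity probability, and uniformly anywhere in the
#' landscape otherwise (so a group with affinity 0 still overlaps the map at
#' about the suitable-area fraction).
#'
#' @param config A [synthetic_config()].
#' @param survey_bundle Result of [generate_soil_survey()].
#' @param rule [threshold_rule()] defining "truly suitable" in the truth
#'   table; default the classic 76% / 160 cm rule.
#' @return Data frame of points: `label`, `affinity`, `x`, `y`, and the
#'   ground-truth flag `on_suitable`.
#' @export
generate_occurrences <- function(config, survey_bundle,
                                 rule = threshold_rule(76, 160)) {
  with_seed(config$seed + 4L, generate_occurrences_impl(config, survey_bundle, rule))
}

generate_occurrences_impl <- function(config, survey_bundle, rule) {
  truth <- survey_bundle$truth
  s <- config$extent_m / config$mapunit_m
  suit_units <- which(!is.na(truth$true_sand) & truth$true_sand >= rule$sand &
                        truth$true_depth_cm >= rule$depth)
  n_groups <- config$n_species
  n_hi <- round(config$high_affinity_fraction * n_groups)
  affinity <- rep(c("high", "other"), c(n_hi, n_groups - n_hi))
  p_aff <- ifelse(affinity == "high", config$affinity_high, config$affinity_other)
  rows <- lapply(seq_len(n_groups), function(g) {
    m <- config$points_per_species
    targeted <- stats::runif(m) < p_aff[g] & length(suit_units) > 0
    x <- numeric(m); y <- numeric(m)
    k <- sum(targeted)
    if (k) {
      u <- suit_units[sample.int(length(suit_units), k, replace = TRUE)]
      x[targeted] <- ((u - 1) %/% s) * config$mapunit_m +
        stats::runif(k, 0, config$mapunit_m)
      y[targeted] <- ((u - 1) %% s) * config$mapunit_m +
        stats::runif(k, 0, config$mapunit_m)
    }
    x[!targeted] <- stats::runif(m - k, 0, config$extent_m)
    y[!targeted] <- stats::runif(m - k, 0, config$extent_m)
    ucol <- pmin(floor(x / config$mapunit_m), s - 1)
    urow <- pmin(floor(y / config$mapunit_m), s - 1)
    data.frame(label = sprintf("species%02d", g), affinity = affinity[g],
               x = x, y = y,
               on_suitable = (ucol * s + urow + 1) %in% suit_units,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic scenario
#'
#' Runs all four generators under one seed and assembles the ground-truth
#' manifest: the true suitability thresholds implied by the generated
#' locations (area-weighted mean minus SD of their true means), the true
#' suitable area under those thresholds, and the realised land-cover
#' category counts. With `dir` set, everything is written to disk
#' (CSV/GeoJSON/ASCII-grid/YAML) and the files round-trip through the
#' package readers.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @param landcover Generate the land-cover raster (the slowest part);
#'   set `FALSE` for soils-only scenarios.
#' @return List of class `synthetic_scenario`: `survey`, `truth`,
#'   `locations`, `location_truth`, `landcover`, `occurrences`, `manifest`,
#'   `config`, and `paths` when written.
#' @export
generate_scenario <- function(config = synthetic_config(), dir = NULL,
                              landcover = TRUE) {
  sb <- generate_soil_survey(config)
  loc <- generate_locations(config, sb)
  lt <- loc$truth
  sand_stats <- area_weighted_stats(lt$true_sand[!is.na(lt$true_sand)],
                                    lt$area_m2[!is.na(lt$true_sand)])
  depth_stats <- area_weighted_stats(lt$true_depth_cm, lt$area_m2)
  thr <- c(sand = derive_thresholds(sand_stats["mean"], sand_stats["sd"]),
           depth = derive_thresholds(depth_stats["mean"], depth_stats["sd"]))
  names(thr) <- c("sand", "depth")
  rule <- threshold_rule(thr["sand"], thr["depth"])
  lc <- if (landcover) generate_landcover(config, sb)
  occ <- generate_occurrences(config, sb, rule)
  manifest <- list(
    seed = config$seed,
    extent_m = config$extent_m,
    mapunit_m = config$mapunit_m,
    n_mapunits = nrow(sb$truth),
    n_patch_units = sum(sb$truth$patch),
    n_locations = config$n_locations,
    true_sand_mean = unname(sand_stats["mean"]),
    true_sand_sd = unname(sand_stats["sd"]),
    true_depth_mean = unname(depth_stats["mean"]),
    true_depth_sd = unname(depth_stats["sd"]),
    true_sand_threshold = unname(thr["sand"]),
    true_depth_threshold = unname(thr["depth"]),
    true_suitable_area_km2 = true_suitable_area(sb$truth, rule),
    landcover_category_counts = if (landcover) {
      as.list(attr(lc, "category_counts"))
    }
  )
  out <- structure(list(survey = sb$survey, truth = sb$truth,
                        locations = loc$locations, location_truth = lt,
                        landcover = lc, occurrences = occ,
                        manifest = manifest, config = config),
                   class = "synthetic_scenario")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_soil_tables(sb$survey, dir)
    paths <- c(paths,
               truth = write_full_precision_csv(sb$truth, file.path(dir, "truth.csv")),
               locations = write_vector_layer(loc$locations,
                                              file.path(dir, "locations.geojson")),
               location_truth = write_full_precision_csv(
                 lt, file.path(dir, "location_truth.csv")),
               occurrences = write_full_precision_csv(
                 occ, file.path(dir, "occurrences.csv")))
    if (landcover) {
      paths <- c(paths, landcover = write_ascii_grid(lc, file.path(dir, "landcover.asc")))
    }
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    paths <- c(paths, manifest = file.path(dir, "manifest.yaml"))
    out$paths <- paths
  }
  out
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_scenario> seed %d: %d map units (%d patch), %d locations\n",
              m$seed, m$n_mapunits, m$n_patch_units, m$n_locations))
  cat(sprintf("  true thresholds: %g %% sand, %g cm depth; true suitable area %.1f km^2\n",
              m$true_sand_threshold, m$true_depth_threshold,
              m$true_suitable_area_km2))
  invisible(x)
}
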