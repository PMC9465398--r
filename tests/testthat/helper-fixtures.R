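# Small deterministic fixtures, built in code.

# Two 100 m x 100 m map units side by side: A has one component,
# B two components with fractions 0.6 / 0.4.
tiny_survey <- function() {
  geoms <- list(rect_ring(0, 0, 100, 100), rect_ring(100, 0, 200, 100))
  mapunits <- vector_layer(geoms, data.frame(mapunit_id = c("A", "B"),
                                             stringsAsFactors = FALSE))
  components <- data.frame(
    mapunit_id = c("A", "B", "B"),
    soil_type_id = c("a1", "b1", "b2"),
    areal_fraction = c(1, 0.6, 0.4),
    restrictive_depth_cm = c(NA, 150, 250),
    stringsAsFactors = FALSE
  )
  horizons <- data.frame(
    soil_type_id = c("a1", "a1", "b1", "b2"),
    top_cm = c(0, 50, 0, 0),
    bottom_cm = c(50, 100, 100, 80),
    percent_sand = c(90, 70, 80, 40),
    stringsAsFactors = FALSE
  )
  soil_survey(mapunits, components, horizons)
}

# brute-force profile oracle: slice the profile into thin laminae and take
# the unweighted mean sand over laminae that carry data
slice_mean_sand <- function(top, bottom, sand, dz = 0.01) {
  z <- seq(min(top) + dz / 2, max(bottom) - dz / 2, by = dz)
  v <- rep(NA_real_, length(z))
  for (i in seq_along(top)) {
    v[z >= top[i] & z < bottom[i]] <- sand[i]
  }
  mean(v, na.rm = TRUE)
}

# brute-force zonal oracle: average a per-unit value over fine sample points
# inside a polygon (units looked up by point location)
point_sample_mean <- function(polygon, unit_value_at, n = 400) {
  bb <- geom_bbox(polygon)
  xs <- seq(bb["xmin"], bb["xmax"], length.out = n)
  ys <- seq(bb["ymin"], bb["ymax"], length.out = n)
  gx <- rep(xs, each = n); gy <- rep(ys, times = n)
  keep <- points_in_geom(gx, gy, polygon)
  mean(unit_value_at(gx[keep], gy[keep]), na.rm = TRUE)
}

# a fast soils-only scenario for tests that need the generator
small_scenario <- function(seed = 1, ...) {
  generate_scenario(
    synthetic_config(extent_m = 10000, mapunit_m = 1000, n_locations = 40,
                     n_species = 4, points_per_species = 15, seed = seed, ...),
    landcover = FALSE
  )
}
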