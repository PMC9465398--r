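test_that("a fixed seed reproduces the scenario exactly", {
  a <- small_scenario(seed = 17)
  b <- small_scenario(seed = 17)
  expect_identical(a$survey$components, b$survey$components)
  expect_identical(a$survey$horizons, b$survey$horizons)
  expect_identical(a$truth, b$truth)
  expect_identical(a$locations$geometry, b$locations$geometry)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$manifest, b$manifest)
  c <- small_scenario(seed = 18)
  expect_false(identical(a$truth$true_sand, c$truth$true_sand))
})

test_that("ground truth equals the pipeline's own aggregation, exactly", {
  sc <- small_scenario(seed = 2)
  cls <- classify_survey(sc$survey, threshold_rule(76, 160))
  ord <- match(sc$truth$mapunit_id, cls$mapunit_id)
  expect_equal(cls$mean_sand[ord], sc$truth$true_sand, tolerance = 1e-12)
  expect_equal(cls$depth_cm[ord], sc$truth$true_depth_cm, tolerance = 1e-12)
})

test_that("per-location truth matches composition through the overlay", {
  sc <- small_scenario(seed = 4)
  comp <- compose_locations(sc$locations, sc$survey)
  ord <- match(sc$location_truth$location_id, comp$summary$location_id)
  expect_equal(comp$summary$mean_sand[ord], sc$location_truth$true_sand,
               tolerance = 1e-6)
  expect_equal(comp$summary$mean_depth_cm[ord], sc$location_truth$true_depth_cm,
               tolerance = 1e-6)
  expect_equal(comp$summary$total_area_m2[ord], sc$location_truth$area_m2,
               tolerance = 1e-6)
})

test_that("patch fraction zero yields a background-only landscape", {
  sc <- generate_scenario(
    synthetic_config(extent_m = 6000, mapunit_m = 1000, patch_fraction = 0,
                     n_locations = 5, location_patch_bias = 1, seed = 9),
    landcover = FALSE
  )
  expect_false(any(sc$truth$patch))
  # background sand ~ N(45, 15): essentially nothing passes the 76/160 rule
  expect_lt(true_suitable_area(sc$truth, threshold_rule(76, 160)), 2)
})

test_that("location placement bias controls the on-patch fraction", {
  on_patch <- unlist(lapply(1:20, function(seed) {
    cfg <- synthetic_config(extent_m = 10000, mapunit_m = 1000,
                            patch_fraction = 0.3, n_locations = 20,
                            location_patch_bias = 0.5, seed = seed)
    generate_locations(cfg, generate_soil_survey(cfg))$truth$on_patch
  }))
  p_hat <- mean(on_patch)
  # off-patch draws go to background units, so the on-patch rate is the bias
  se <- sqrt(0.5 * 0.5 / length(on_patch))
  expect_lt(abs(p_hat - 0.5), 4 * se)
  # bias 1: every location sits on a patch unit
  cfg1 <- synthetic_config(extent_m = 10000, mapunit_m = 1000,
                           patch_fraction = 0.3, n_locations = 20,
                           location_patch_bias = 1, seed = 1)
  expect_true(all(generate_locations(cfg1, generate_soil_survey(cfg1))$truth$on_patch))
})

test_that("locations lie inside the landscape and carry their stated areas", {
  sc <- small_scenario(seed = 12)
  areas <- layer_areas(sc$locations)
  expect_equal(areas, sc$location_truth$area_m2, tolerance = 1e-9)
  rng <- sc$config$location_area_range
  expect_true(all(areas >= rng[1] & areas <= rng[2]))
  bbs <- vapply(sc$locations$geometry, geom_bbox, numeric(4))
  expect_true(all(bbs[c(1, 2), ] >= 0) && all(bbs[c(3, 4), ] <= 10000))
})

test_that("manifest bookkeeping is consistent with its own tables", {
  sc <- small_scenario(seed = 8)
  m <- sc$manifest
  expect_equal(sum(sc$truth$area_m2) / 1e6, (m$extent_m / 1000)^2)
  expect_equal(m$n_patch_units, sum(sc$truth$patch))
  rule <- threshold_rule(m$true_sand_threshold, m$true_depth_threshold)
  expect_equal(m$true_suitable_area_km2, true_suitable_area(sc$truth, rule))
  lt <- sc$location_truth
  s <- area_weighted_stats(lt$true_sand, lt$area_m2)
  expect_equal(m$true_sand_threshold, derive_thresholds(s[["mean"]], s[["sd"]]))
})

test_that("a scenario written to disk round-trips through the readers", {
  dir <- withr::local_tempdir()
  sc <- generate_scenario(
    synthetic_config(extent_m = 5000, mapunit_m = 1000, n_locations = 8,
                     n_species = 2, points_per_species = 5,
                     landcover_cell_m = 50, seed = 30),
    dir = dir
  )
  back <- read_soil_tables(file.path(dir, "components.csv"),
                           file.path(dir, "horizons.csv"),
                           file.path(dir, "mapunits.geojson"))
  expect_equal(back$components, sc$survey$components, ignore_attr = TRUE)
  expect_equal(back$horizons, sc$survey$horizons, ignore_attr = TRUE)
  locs <- read_vector_layer(file.path(dir, "locations.geojson"), quiet = TRUE)
  expect_equal(length(locs$geometry), 8)
  expect_equal(sum(layer_areas(locs)), sum(layer_areas(sc$locations)),
               tolerance = 1e-9)
  lc <- read_ascii_grid(file.path(dir, "landcover.asc"))
  expect_equal(lc$values, sc$landcover$values)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$true_suitable_area_km2, sc$manifest$true_suitable_area_km2)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(extent_m = 5000, mapunit_m = 1000,
                                patch_fraction = 1e-6),
               "no map unit")
  expect_error(synthetic_config(extent_m = 5500, mapunit_m = 1000), "divide")
  expect_error(synthetic_config(location_patch_bias = 1.5), "\\[0, 1\\]")
})
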