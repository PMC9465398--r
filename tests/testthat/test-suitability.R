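test_that("classification is inclusive at the threshold boundary", {
  rule <- threshold_rule(76, 160)
  expect_identical(classify_soil_type(76, 160, rule), "suitable")
  expect_identical(classify_soil_type(75.9, 200, rule), "unsuitable")
  expect_identical(classify_soil_type(90, 159.9, rule), "unsuitable")
  expect_identical(classify_soil_type(NA, 200, rule), "nodata")
  expect_identical(classify_soil_type(80, NA, rule), "nodata")
  # degenerate rule: everything with data is suitable
  expect_identical(classify_soil_type(c(0, 50, NA), c(1, 1, 1),
                                      threshold_rule(0, 0)),
                   c("suitable", "suitable", "nodata"))
})

test_that("map units are classified from fraction-weighted component values", {
  srv <- tiny_survey()
  cls <- classify_survey(srv, threshold_rule(76, 160))
  cls <- cls[order(cls$mapunit_id), ]
  expect_equal(cls$mean_sand, c(80, 0.6 * 80 + 0.4 * 40))
  expect_equal(cls$depth_cm, c(200, 0.6 * 150 + 0.4 * 200))
  expect_identical(cls$state, c("suitable", "unsuitable"))
})

test_that("suitability map states, areas and the exclusion mask behave", {
  srv <- tiny_survey()
  m <- suitability_map(srv, threshold_rule(76, 160), cellsize = 10)
  expect_equal(suitable_area(m), 0.01)            # unit A = 100 x 100 m
  expect_equal(suitable_area(m, "vector"), 0.01)
  # conservation: all states together tile the mapped extent
  states <- table(m$raster$values)
  expect_equal(sum(states) * 100 / 1e6, 0.02)

  # full-coverage water mask -> everything excluded
  mask <- grid_raster(matrix(1, 10, 20), 0, 0, 10)
  m2 <- suitability_map(srv, threshold_rule(76, 160), exclusion = mask,
                        cellsize = 10)
  expect_equal(suitable_area(m2), 0)
  expect_true(all(m2$raster$values == 2))
  expect_equal(suitable_area(m2, "vector"), 0.01)  # vector path ignores mask

  # degenerate rule without mask: everything suitable
  m3 <- suitability_map(srv, threshold_rule(0, 0), cellsize = 10)
  expect_equal(suitable_area(m3), 0.02)

  bad_mask <- grid_raster(matrix(1, 10, 20), 0, 0, 10, crs = "EPSG:3857")
  expect_error(suitability_map(srv, threshold_rule(0, 0), exclusion = bad_mask),
               "CRS mismatch")
})

test_that("a checkerboard of suitable/unsuitable units yields half the area", {
  n <- 4
  geoms <- list(); ids <- character(0); sand <- numeric(0)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    geoms <- c(geoms, list(rect_ring(i * 100, j * 100, (i + 1) * 100, (j + 1) * 100)))
    ids <- c(ids, sprintf("u%d%d", i, j))
    sand <- c(sand, if ((i + j) %% 2 == 0) 90 else 30)
  }
  srv <- soil_survey(
    vector_layer(geoms, data.frame(mapunit_id = ids)),
    data.frame(mapunit_id = ids, soil_type_id = paste0(ids, "c"),
               areal_fraction = 1, restrictive_depth_cm = NA),
    data.frame(soil_type_id = paste0(ids, "c"), top_cm = 0, bottom_cm = 100,
               percent_sand = sand)
  )
  m <- suitability_map(srv, threshold_rule(76, 160), cellsize = 10)
  expect_equal(suitable_area(m), 0.08)  # half of 0.16 km^2
  expect_equal(suitable_area(m, "vector"), 0.08)
})

test_that("raising either threshold never increases suitable area", {
  sc <- small_scenario(seed = 11)
  srv <- sc$survey
  areas <- vapply(c(0, 40, 76, 90), function(thr_sand) {
    suitable_area(suitability_map(srv, threshold_rule(thr_sand, 160),
                                  cellsize = 100))
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  areas_d <- vapply(c(0, 100, 160, 190), function(thr_depth) {
    suitable_area(suitability_map(srv, threshold_rule(76, thr_depth),
                                  cellsize = 100))
  }, numeric(1))
  expect_true(all(diff(areas_d) <= 1e-9))
})

test_that("vector and raster areas agree on grid-aligned synthetic scenes", {
  sc <- small_scenario(seed = 3)
  m <- suitability_map(sc$survey, threshold_rule(76, 160), cellsize = 10)
  v <- suitable_area(m, "vector")
  r <- suitable_area(m, "raster")
  expect_lt(abs(v - r), 0.01 * max(v, 1e-9) + 1e-9)
  # and both equal the generator's bookkeeping
  expect_equal(v, true_suitable_area(sc$truth, m$rule))
})
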