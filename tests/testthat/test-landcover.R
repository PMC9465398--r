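test_that("reclassification substitutes categories and keeps the grid", {
  r <- grid_raster(matrix(41, 5, 5), 0, 0, 30)
  rc <- reclassify_landcover(r, nlcd_scheme())
  expect_true(all(rc$values == match("forest", attr(rc, "categories"))))
  expect_equal(rc$cellsize, 30)

  # shrub + grass + barren all map to "open"
  r2 <- grid_raster(matrix(c(52, 71, 31), 3, 3), 0, 0, 30)
  rc2 <- reclassify_landcover(r2, nlcd_scheme())
  expect_true(all(rc2$values == match("open", attr(rc2, "categories"))))

  r3 <- grid_raster(matrix(c(41, 999), 2, 2), 0, 0, 30)
  expect_error(reclassify_landcover(r3, nlcd_scheme()), "999")

  expect_error(landcover_scheme(c("1" = "swamp")), "unknown")
})

test_that("a four-code checkerboard reclassifies to quarter shares", {
  codes <- c(41, 52, 82, 22)  # forest, open, agriculture, urban
  m <- matrix(codes, 8, 8)    # each code fills 16 cells
  rc <- reclassify_landcover(grid_raster(m, 0, 0, 10), nlcd_scheme())
  counts <- table(factor(rc$values, levels = 1:6,
                         labels = attr(rc, "categories")))
  expect_equal(unname(counts[c("forest", "open", "agriculture", "urban")]),
               rep(16L, 4), ignore_attr = TRUE)
})

test_that("cover summary proportions and conservation on a controlled scene", {
  srv <- tiny_survey()  # unit A suitable, unit B not (rule 76/160)
  m <- suitability_map(srv, threshold_rule(76, 160), cellsize = 10)
  # forest on the west half (over unit A), agriculture on the east
  cov_codes <- cbind(matrix(41, 10, 10), matrix(82, 10, 10))
  cov <- grid_raster(cov_codes, 0, 0, 10)
  s <- summarize_cover(m, cov)
  expect_equal(s$area_km2[s$category == "forest"], 0.01)
  expect_equal(s$area_km2[s$category == "agriculture"], 0)
  expect_equal(s$prop_of_suitable[s$category == "forest"], 1)
  # conservation: named + other areas total the suitable area
  reported <- s$category != "excluded"
  expect_equal(sum(s$area_km2[reported]), s$suitable_total_km2[1])
  # landscape-wide areas cover the whole extent
  expect_equal(sum(s$landscape_area_km2), 0.02)
})

test_that("no suitable cells yields zero areas without error", {
  srv <- tiny_survey()
  m <- suitability_map(srv, threshold_rule(101, 300), cellsize = 10)
  cov <- grid_raster(matrix(41, 10, 20), 0, 0, 10)
  s <- summarize_cover(m, cov)
  expect_true(all(s$area_km2 == 0))
  expect_true(all(s$suitable_total_km2 == 0))
})

test_that("regions tiling the extent sum to the global summary", {
  sc <- small_scenario(seed = 21)
  cfg <- sc$config
  lc <- generate_landcover(cfg, list(truth = sc$truth))
  m <- suitability_map(sc$survey, threshold_rule(76, 160), cellsize = 100)
  halves <- vector_layer(
    list(rect_ring(0, 0, 5000, 10000), rect_ring(5000, 0, 10000, 10000)),
    data.frame(region_id = c("west", "east"))
  )
  global <- summarize_cover(m, lc)
  per_region <- summarize_cover(m, lc, regions = halves)
  for (cat in unique(global$category)) {
    expect_equal(sum(per_region$area_km2[per_region$category == cat]),
                 global$area_km2[global$category == cat])
  }
  expect_equal(sum(unique(per_region$suitable_total_km2[per_region$region == "west"]),
                   unique(per_region$suitable_total_km2[per_region$region == "east"])),
               global$suitable_total_km2[1])

  far <- vector_layer(list(rect_ring(1e6, 1e6, 2e6, 2e6)),
                      data.frame(region_id = "nowhere"))
  expect_warning(s <- summarize_cover(m, lc, regions = far), "does not intersect")
  expect_true(all(s$area_km2 == 0))
})

test_that("generated land cover recovers the configured class fractions", {
  cfg <- synthetic_config(extent_m = 6000, mapunit_m = 1000,
                          patch_fraction = 0, landcover_cell_m = 30, seed = 13)
  sb <- generate_soil_survey(cfg)
  lc <- generate_landcover(cfg, sb)
  counts <- attr(lc, "category_counts")
  props <- counts / sum(counts)
  expect_equal(unname(props), unname(cfg$landcover_background[names(counts)]),
               tolerance = 0.05)
  # realised counts are the truth for the raster itself
  tab <- table(factor(lc$values, levels = edaphic:::lc_category_codes))
  expect_equal(unname(c(tab)), unname(counts), ignore_attr = TRUE)
})
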