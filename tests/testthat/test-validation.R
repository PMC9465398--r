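# a two-unit map: west 100x100 m suitable, east unsuitable
half_suitable_map <- function(cellsize = 10) {
  suitability_map(tiny_survey(), threshold_rule(76, 160), cellsize = cellsize)
}

test_that("polygon overlap proportions match geometric oracles", {
  m <- half_suitable_map()
  polys <- vector_layer(
    list(rect_ring(10, 10, 90, 90),      # wholly inside the suitable unit
         rect_ring(110, 10, 190, 90),    # wholly in the unsuitable unit
         rect_ring(50, 20, 150, 60)),    # half and half
    data.frame(label = c("in", "out", "half"))
  )
  got <- overlap_proportion_polygons(polys, m)
  expect_equal(got$overlap, c(1, 0, 0.5))
  expect_equal(got$area_m2, c(6400, 6400, 4000))

  zero <- vector_layer(list(cbind(c(0, 1, 2), c(0, 0, 0))),
                       data.frame(label = "degenerate"))
  expect_error(overlap_proportion_polygons(zero, m), "zero area")
})

test_that("point overlap counts per group and handles the extent edge", {
  m <- half_suitable_map()
  pts <- data.frame(
    label = c("sp1", "sp1", "sp1", "sp1", "sp2", "sp2"),
    affinity = c(rep("high", 4), rep("other", 2)),
    x = c(10, 20, 30, 150, 50, 500),   # sp2's second point is off the map
    y = c(10, 20, 30, 50, 50, 50)
  )
  got <- overlap_proportion_points(pts, m)
  got <- got[order(got$label), ]
  expect_equal(got$overlap, c(0.75, 0.5))
  expect_equal(got$n_outside, c(0, 1))

  # boundary points resolve to exactly one cell (half-open intervals)
  cell <- raster_cell_of(m$raster, c(0, 100, 200), c(0, 50, 50))
  expect_equal(cell[1, ], c(row = 10, col = 1))     # lower-left corner
  expect_equal(cell[2, ], c(row = 5, col = 11))     # east side of the edge
  expect_true(all(is.na(cell[3, ])))                # right edge is outside
})

test_that("validation report assembles all three strands with summaries", {
  m <- half_suitable_map()
  heldout <- vector_layer(list(rect_ring(10, 10, 90, 90),
                               rect_ring(120, 10, 180, 90)),
                          data.frame(location_id = c("h1", "h2")))
  nonfocal <- vector_layer(list(rect_ring(0, 0, 50, 50),
                                rect_ring(50, 0, 100, 50)),
                           data.frame(label = c("bog", "bog")))
  species <- data.frame(label = c("sp1", "sp1", "sp2", "sp2"),
                        affinity = c("high", "high", "other", "other"),
                        x = c(10, 20, 150, 160), y = c(10, 20, 50, 60))
  rep <- validation_report(m, heldout = heldout, nonfocal = nonfocal,
                           species = species)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$overlap[rep$class == "heldout-focal"], c(1, 0))
  bin <- rep[grepl("heldout locations", rep$label), ]
  expect_equal(bin$overlap, 0.5)  # one of two exceeds the 0.5 cutoff
  # non-focal "bog" polygons aggregate area-weighted (both fully suitable)
  expect_equal(rep$overlap[rep$class == "nonfocal-ecosystem"], 1)
  expect_equal(rep$n[rep$class == "nonfocal-ecosystem"], 2)
  expect_equal(rep$overlap[rep$label == "mean over species"], 0.5)
  expect_equal(rep$overlap[rep$label == "mean over high-affinity species"], 1)

  # empty species strand: rows omitted, no crash
  expect_warning(rep2 <- validation_report(m, heldout = heldout,
                                           species = species[0, ]),
                 "omitted")
  expect_false(any(rep2$class == "species"))
})

test_that("overlap is invariant under joint translation of map and entities", {
  sc <- small_scenario(seed = 6)
  m <- suitability_map(sc$survey, threshold_rule(76, 160), cellsize = 100)
  pts <- sc$occurrences
  base <- overlap_proportion_points(pts, m)
  shift <- 12345
  m2 <- m
  m2$raster$xmin <- m2$raster$xmin + shift
  m2$raster$ymin <- m2$raster$ymin + shift
  pts2 <- pts; pts2$x <- pts2$x + shift; pts2$y <- pts2$y + shift
  expect_equal(overlap_proportion_points(pts2, m2)$overlap, base$overlap)
})

test_that("raising thresholds never increases any overlap proportion", {
  sc <- small_scenario(seed = 6)
  m_lo <- suitability_map(sc$survey, threshold_rule(60, 120), cellsize = 100)
  m_hi <- suitability_map(sc$survey, threshold_rule(80, 170), cellsize = 100)
  lo <- overlap_proportion_points(sc$occurrences, m_lo)$overlap
  hi <- overlap_proportion_points(sc$occurrences, m_hi)$overlap
  expect_true(all(hi <= lo + 1e-12))
  locs <- sc$locations
  lo_p <- overlap_proportion_polygons(locs, m_lo)$overlap
  hi_p <- overlap_proportion_polygons(locs, m_hi)$overlap
  expect_true(all(hi_p <= lo_p + 1e-12))
})

test_that("species placed on suitable soil with probability p overlap near p", {
  # simulation oracle over seeds: affinity-1 groups overlap fully when the
  # rule matches the generator's truth; affinity-0 groups overlap at about
  # the suitable-area fraction
  overlaps_p1 <- numeric(0); overlaps_p0 <- numeric(0); suit_frac <- numeric(0)
  for (seed in 1:20) {
    sc <- generate_scenario(
      synthetic_config(extent_m = 8000, mapunit_m = 1000, n_locations = 10,
                       n_species = 2, points_per_species = 25,
                       high_affinity_fraction = 0.5,
                       affinity_high = 1, affinity_other = 0, seed = seed),
      landcover = FALSE
    )
    # the generator targets units suitable under the scenario's own true
    # thresholds, so overlap must be judged under that same rule
    rule <- threshold_rule(sc$manifest$true_sand_threshold,
                           sc$manifest$true_depth_threshold)
    m <- suitability_map(sc$survey, rule, cellsize = 100)
    got <- overlap_proportion_points(sc$occurrences, m)
    overlaps_p1 <- c(overlaps_p1, got$overlap[got$affinity == "high"])
    overlaps_p0 <- c(overlaps_p0, got$overlap[got$affinity == "other"])
    suit_frac <- c(suit_frac, true_suitable_area(sc$truth, rule) / 64)
  }
  expect_true(all(overlaps_p1 == 1))
  # binomial error band around the mean suitable fraction
  p <- mean(suit_frac)
  se <- sqrt(p * (1 - p) / (20 * 25))
  expect_lt(abs(mean(overlaps_p0) - p), 4 * se + 0.01)
})
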