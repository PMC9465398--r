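test_that("train/validation split has round-half-up sizes and is deterministic", {
  ids <- sprintf("loc%03d", 1:156)
  sp <- split_train_validation(ids, 0.7, seed = 42)
  expect_length(sp$train, 109)
  expect_length(sp$validation, 47)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sp, split_train_validation(ids, 0.7, seed = 42))
  expect_false(identical(sp$train, split_train_validation(ids, 0.7, seed = 43)$train))

  expect_length(split_train_validation(letters[1:10], 0.7, seed = 1)$train, 7)
  # round-half-up: 0.5 * 5 = 2.5 -> 3
  expect_length(split_train_validation(letters[1:5], 0.5, seed = 1)$train, 3)
  expect_error(split_train_validation("a", 0.7, seed = 1), "at least two")
})

test_that("split does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(split_train_validation(letters[1:10], 0.7, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("area-weighted stats equal replication-oracle population stats", {
  expect_equal(area_weighted_stats(c(80, 90), c(1, 1)),
               c(mean = 85, sd = 5))
  expect_equal(area_weighted_stats(77, 123), c(mean = 77, sd = 0))
  # integer weights == replicating each value weight times
  set.seed(4)
  for (rep in 1:10) {
    x <- stats::runif(5, 0, 100)
    w <- sample(1:9, 5, replace = TRUE)
    rep_x <- rep(x, w)
    expect_equal(
      area_weighted_stats(x, w),
      c(mean = mean(rep_x),
        sd = sqrt(mean((rep_x - mean(rep_x))^2)))
    )
  }
  got <- area_weighted_stats(c(60, 100), c(1, 3))
  expect_equal(got[["mean"]], 90)
  expect_equal(got[["sd"]], sqrt(300), tolerance = 1e-12)
  expect_error(area_weighted_stats(numeric(0), numeric(0)), "no values")
  expect_error(area_weighted_stats(c(1, 2), c(1, -1)), "positive")
})

test_that("thresholds are mean minus one SD with round-half-up", {
  expect_equal(derive_thresholds(87, 11), 76)
  expect_equal(derive_thresholds(193, 33), 160)
  expect_equal(derive_thresholds(50, 0), 50)
  expect_equal(derive_thresholds(80.2, 3.7, rounding = "none"), 76.5)
  expect_equal(derive_thresholds(80.2, 3.7), 77)  # 76.5 rounds half-up
  expect_error(derive_thresholds(10, -1), "non-negative")
})

test_that("fitting two equal-area locations reproduces the textbook thresholds", {
  locs <- data.frame(location_id = c("a", "b"),
                     mean_sand = c(76, 98),
                     mean_depth_cm = c(160, 226),
                     total_area_m2 = c(2e5, 2e5))
  fit <- edaphic_fit(locs, fraction = 1, seed = 1)
  expect_equal(unname(fit$stats),
               c(87, 11, 193, 33))
  expect_equal(coef(fit), c(sand = 76, depth = 160))
  expect_equal(fit$n_train, 2)
  expect_equal(fit$n_validation, 0)
})

test_that("fit is invariant to rescaling all areas and degenerate inputs behave", {
  locs <- data.frame(location_id = letters[1:4],
                     mean_sand = c(70, 85, 92, 99),
                     mean_depth_cm = c(120, 180, 200, 150),
                     total_area_m2 = c(1, 4, 2, 3) * 1e5)
  f1 <- edaphic_fit(locs, seed = 8)
  locs2 <- locs; locs2$total_area_m2 <- locs2$total_area_m2 * 1000
  f2 <- edaphic_fit(locs2, seed = 8)
  expect_equal(f1$stats, f2$stats)
  expect_equal(coef(f1), coef(f2))

  same <- data.frame(location_id = c("a", "b"), mean_sand = 80,
                     mean_depth_cm = 170, total_area_m2 = 1e5)
  f3 <- edaphic_fit(same, fraction = 1, seed = 1)
  expect_equal(coef(f3), c(sand = 80, depth = 170))  # zero SD -> threshold = mean
})

test_that("thresholds are monotone non-increasing in the SD", {
  thr <- vapply(c(0, 5, 11, 20), function(s) derive_thresholds(87, s), numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("all-missing locations are excluded from the fit and reported", {
  locs <- data.frame(location_id = c("a", "b", "c"),
                     mean_sand = c(76, 98, NA),
                     mean_depth_cm = c(160, 226, 100),
                     total_area_m2 = 1e5)
  fit <- edaphic_fit(locs, fraction = 1, seed = 1)
  expect_equal(fit$excluded_ids, "c")
  expect_equal(unname(fit$stats[c("mean_sand", "sd_sand")]), c(87, 11))
  expect_error(edaphic_fit(locs[c(1, 3), ], fraction = 1, seed = 1),
               "at least two usable")
})

test_that("fit methods: predict, residuals, simulate, coef(raw)", {
  locs <- data.frame(location_id = letters[1:6],
                     mean_sand = c(70, 85, 92, 99, 88, 81),
                     mean_depth_cm = c(120, 180, 200, 150, 190, 170),
                     total_area_m2 = 1e5)
  fit <- edaphic_fit(locs, fraction = 1, seed = 2)
  expect_true(all(coef(fit, raw = TRUE) <= fit$stats[c("mean_sand", "mean_depth")]))

  pr <- predict(fit, data.frame(mean_sand = c(100, 0, NA), depth_cm = c(200, 200, 200)))
  expect_identical(pr, c("suitable", "unsuitable", "nodata"))
  # survey predict returns the per-map-unit classification
  cls <- predict(fit, tiny_survey())
  expect_named(cls, c("mapunit_id", "mean_sand", "depth_cm", "state"))

  res <- residuals(fit)
  # area-weighted mean of residuals is zero by construction (equal areas here)
  expect_equal(mean(res[, "sand"]), 0, tolerance = 1e-12)
  expect_equal(mean(res[, "depth"]), 0, tolerance = 1e-12)

  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_identical(simulate(fit, nsim = 3, seed = 5), sims)
  expect_true(all(sims[[1]]$mean_sand <= 100 & sims[[1]]$mean_sand >= 0))

  expect_output(print(summary(fit)), "thresholds")
})

test_that("calibration recovers the configured distribution as locations grow", {
  # locations drawn from a known mean/sd; area weights independent of value
  diffs <- t(vapply(1:20, function(seed) {
    set.seed(seed + 1000)
    n <- 200
    x <- stats::rnorm(n, 85, 9)
    w <- stats::runif(n, 1e4, 1e6)
    s <- area_weighted_stats(x, w)
    c(s[["mean"]] - 85, s[["sd"]] - 9)
  }, numeric(2)))
  se <- apply(diffs, 2, stats::sd) / sqrt(nrow(diffs))
  expect_lt(abs(mean(diffs[, 1])), 2 * se[1] + 1e-9)
  expect_lt(abs(mean(diffs[, 2])), 2 * se[2] + 1e-9)
})
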