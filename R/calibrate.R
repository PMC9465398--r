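#' Split locations into training and validation sets
#'
#' Uniform sampling without replacement; the training size is
#' `round-half-up(fraction * N)`, so 156 locations at fraction 0.7 split
#' into 109 training and 47 validation locations. Deterministic for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param location_ids Vector of location identifiers (N >= 2).
#' @param fraction Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed (required — there is no hidden default).
#' @return List with elements `train` and `validation`.
#' @export
split_train_validation <- function(location_ids, fraction = 0.7, seed) {
  n <- length(location_ids)
  if (n < 2) stop("need at least two locations to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- floor(fraction * n + 0.5)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = location_ids[sort(idx)],
       validation = location_ids[sort(setdiff(seq_len(n), idx))])
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Area-weighted mean and standard deviation
#'
#' The population-form weighted statistics: `mean = sum(w*x)/sum(w)` and
#' `sd = sqrt(sum(w*(x - mean)^2)/sum(w))`. With equal weights these reduce
#' to the ordinary population mean and SD; replicating each value in
#' proportion to its weight and taking unweighted population statistics
#' gives the same numbers.
#'
#' @param values Numeric vector.
#' @param weights Positive numeric vector of the same length (areas, m^2).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
#' @examples
#' area_weighted_stats(c(76, 98), c(1, 1))   # mean 87, sd 11
#' area_weighted_stats(c(160, 226), c(1, 1)) # mean 193, sd 33
area_weighted_stats <- function(values, weights) {
  if (length(values) == 0) stop("no values to average")
  if (length(values) != length(weights)) stop("values and weights differ in length")
  if (any(weights <= 0)) stop("weights must be positive")
  m <- sum(weights * values) / sum(weights)
  s <- sqrt(sum(weights * (values - m)^2) / sum(weights))
  c(mean = m, sd = s)
}

#' Derive a suitability threshold from weighted statistics
#'
#' The threshold is the area-weighted mean minus one area-weighted SD,
#' optionally rounded half-up to the nearest integer (thresholds are applied
#' as integers, e.g. "at least 76% sand and at least 160 cm depth").
#' Rounding happens after the subtraction, on the full-precision values.
#'
#' @param mean,sd Weighted mean and SD (sd >= 0).
#' @param rounding `"integer"` (default) or `"none"`.
#' @return The threshold.
#' @export
derive_thresholds <- function(mean, sd, rounding = c("integer", "none")) {
  rounding <- match.arg(rounding)
  if (any(sd < 0)) stop("sd must be non-negative")
  thr <- mean - sd
  if (rounding == "integer") thr <- floor(thr + 0.5)
  thr
}

#' Fit an edaphic suitability model
#'
#' Calibrates sand and depth suitability thresholds from known ecosystem
#' locations. The locations are split into training and validation sets
#' (default 70/30); over the training set the model computes area-weighted
#' means and SDs of the location mean percent sand and location mean soil
#' depth, weighting each location by its area; the thresholds are one
#' area-weighted SD below each mean. A soil is classified suitable when its
#' profile is at least as sandy *and* at least as deep as the thresholds.
#'
#' Locations whose entire composition lacks sand data are excluded from the
#' fit (their mean is undefined) and listed in the returned object.
#'
#' @param locations Either the result of [compose_locations()], a list of
#'   [location_composition()] objects, or a data frame with columns
#'   `location_id`, `mean_sand`, `mean_depth_cm`, `total_area_m2`.
#' @param fraction Training fraction; default 0.7.
#' @param seed Integer seed for the random split (required).
#' @param rounding Threshold rounding, `"integer"` (default) or `"none"`.
#' @param cap_depth Maximum reported depth (cm), carried for provenance.
#' @return An object of class `edaphic_fit` with components `stats` (the
#'   area-weighted means/SDs), `thresholds` (as applied), `thresholds_raw`
#'   (unrounded), `train_ids`, `validation_ids`, `excluded_ids`, `training`
#'   (the per-location table used) and the call parameters.
#' @seealso [predict.edaphic_fit()], [threshold_rule()], [suitability_map()]
#' @export
#' @examples
#' locs <- data.frame(location_id = c("a", "b"),
#'                    mean_sand = c(76, 98),
#'                    mean_depth_cm = c(160, 226),
#'                    total_area_m2 = c(1e6, 1e6))
#' fit <- edaphic_fit(locs, fraction = 1, seed = 1)  # fraction 1: no held-out set
#' coef(fit)  # sand 76, depth 160
edaphic_fit <- function(locations, fraction = 0.7, seed,
                        rounding = c("integer", "none"), cap_depth = 200) {
  rounding <- match.arg(rounding)
  tab <- as_location_table(locations)
  excluded <- tab$location_id[is.na(tab$mean_sand)]
  usable <- tab[!is.na(tab$mean_sand), , drop = FALSE]
  if (nrow(usable) < 2) stop("need at least two usable locations to calibrate")
  split <- if (fraction >= 1 - 1e-9) {
    list(train = usable$location_id, validation = character(0))
  } else {
    split_train_validation(usable$location_id, fraction, seed)
  }
  training <- usable[usable$location_id %in% split$train, , drop = FALSE]
  sand <- area_weighted_stats(training$mean_sand, training$total_area_m2)
  depth <- area_weighted_stats(training$mean_depth_cm, training$total_area_m2)
  thr_raw <- c(sand = unname(sand["mean"] - sand["sd"]),
               depth = unname(depth["mean"] - depth["sd"]))
  thr <- c(sand = derive_thresholds(sand["mean"], sand["sd"], rounding),
           depth = derive_thresholds(depth["mean"], depth["sd"], rounding))
  structure(list(
    call = match.call(),
    stats = c(mean_sand = unname(sand["mean"]), sd_sand = unname(sand["sd"]),
              mean_depth = unname(depth["mean"]), sd_depth = unname(depth["sd"])),
    thresholds = unname_inner(thr),
    thresholds_raw = thr_raw,
    n_train = nrow(training),
    n_validation = length(split$validation),
    train_ids = split$train,
    validation_ids = split$validation,
    excluded_ids = excluded,
    training = training,
    locations = tab,
    fraction = fraction,
    seed = if (missing(seed)) NA_integer_ else seed,
    rounding = rounding,
    cap_depth = cap_depth
  ), class = "edaphic_fit")
}

unname_inner <- function(x) stats::setNames(as.numeric(x), c("sand", "depth"))

as_location_table <- function(locations) {
  if (is.data.frame(locations)) {
    need <- c("location_id", "mean_sand", "mean_depth_cm", "total_area_m2")
    miss <- setdiff(need, names(locations))
    if (length(miss)) stop("location table lacks column(s): ", paste(miss, collapse = ", "))
    return(locations[, need])
  }
  if (is.list(locations) && !is.null(locations$summary)) {
    return(locations$summary)
  }
  if (is.list(locations) && all(vapply(locations, inherits, logical(1),
                                       "location_composition"))) {
    return(data.frame(
      location_id = vapply(locations, function(cc) as.character(cc$location_id),
                           character(1)),
      mean_sand = vapply(locations, function(cc) as.numeric(location_mean_sand(cc)),
                         numeric(1)),
      mean_depth_cm = vapply(locations, location_mean_depth, numeric(1)),
      total_area_m2 = vapply(locations, function(cc) cc$total_area_m2, numeric(1)),
      stringsAsFactors = FALSE
    ))
  }
  stop("cannot interpret `locations`; see ?edaphic_fit")
}

#' @export
print.edaphic_fit <- function(x, ...) {
  cat("Edaphic suitability model\n")
  cat(sprintf("  training locations: %d (validation held out: %d%s)\n",
              x$n_train, x$n_validation,
              if (length(x$excluded_ids)) {
                sprintf("; excluded for missing sand data: %d", length(x$excluded_ids))
              } else ""))
  cat(sprintf("  area-weighted sand:  %.1f %% (SD %.1f)\n",
              x$stats["mean_sand"], x$stats["sd_sand"]))
  cat(sprintf("  area-weighted depth: %.1f cm (SD %.1f)\n",
              x$stats["mean_depth"], x$stats["sd_depth"]))
  cat(sprintf("  thresholds (mean - 1 SD): >= %g %% sand and >= %g cm depth\n",
              x$thresholds["sand"], x$thresholds["depth"]))
  invisible(x)
}

#' @export
coef.edaphic_fit <- function(object, raw = FALSE, ...) {
  if (raw) object$thresholds_raw else object$thresholds
}

#' @export
summary.edaphic_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.edaphic_fit")
}

#' @export
print.summary.edaphic_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  split: fraction %.2f, seed %s\n", f$fraction, format(f$seed)))
  cat(sprintf("  threshold rounding: %s (raw: %.4f %%, %.4f cm)\n",
              f$rounding, f$thresholds_raw["sand"], f$thresholds_raw["depth"]))
  tr <- f$training
  cat(sprintf("  training location sand range:  %.1f - %.1f %%\n",
              min(tr$mean_sand), max(tr$mean_sand)))
  cat(sprintf("  training location depth range: %.1f - %.1f cm\n",
              min(tr$mean_depth_cm), max(tr$mean_depth_cm)))
  invisible(x)
}

#' Predict suitability from a fitted edaphic model
#'
#' With a data frame of soil properties (columns `mean_sand` and `depth_cm`)
#' returns a character vector of states; with a [soil_survey()] returns the
#' per-map-unit classification table of [classify_survey()]; with no
#' `newdata` returns the states of the training locations themselves.
#'
#' @param object An [edaphic_fit()].
#' @param newdata Data frame or [soil_survey()]; see Details.
#' @param ... Unused.
#' @return Character vector (or classification data frame) with values
#'   `"suitable"`, `"unsuitable"` or `"nodata"`.
#' @export
predict.edaphic_fit <- function(object, newdata = NULL, ...) {
  rule <- threshold_rule(object$thresholds["sand"], object$thresholds["depth"])
  if (is.null(newdata)) {
    tab <- object$training
    return(classify_soil_type(tab$mean_sand, tab$mean_depth_cm, rule))
  }
  if (inherits(newdata, "soil_survey")) {
    return(classify_survey(newdata, rule, cap_depth = object$cap_depth))
  }
  depth <- if (!is.null(newdata$depth_cm)) newdata$depth_cm else newdata$mean_depth_cm
  classify_soil_type(newdata$mean_sand, depth, rule)
}

#' Residuals of an edaphic fit
#'
#' Deviations of each training location's mean sand and depth from the
#' fitted area-weighted means — the spread the `- 1 SD` threshold rule is
#' built from.
#'
#' @param object An [edaphic_fit()].
#' @param ... Unused.
#' @return Matrix with columns `sand` and `depth`, one row per training
#'   location.
#' @export
residuals.edaphic_fit <- function(object, ...) {
  tr <- object$training
  out <- cbind(sand = tr$mean_sand - object$stats["mean_sand"],
               depth = tr$mean_depth_cm - object$stats["mean_depth"])
  rownames(out) <- tr$location_id
  out
}

#' Simulate location means from a fitted edaphic model
#'
#' Draws replicate sets of location mean sand/depth from independent normal
#' distributions with the fitted area-weighted means and SDs (sand truncated
#' to \[0, 100\], depth to (0, cap_depth\]) — a parametric bootstrap of the
#' calibration table.
#'
#' @param object An [edaphic_fit()].
#' @param nsim Number of replicate tables.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like `object$training`.
#' @export
simulate.edaphic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n_train
  draw <- function() {
    data.frame(
      location_id = object$training$location_id,
      mean_sand = pmin(100, pmax(0, stats::rnorm(n, object$stats["mean_sand"],
                                                 object$stats["sd_sand"]))),
      mean_depth_cm = pmin(object$cap_depth,
                           pmax(1, stats::rnorm(n, object$stats["mean_depth"],
                                                object$stats["sd_depth"]))),
      total_area_m2 = object$training$total_area_m2,
      stringsAsFactors = FALSE
    )
  }
  runner <- function() replicate(nsim, draw(), simplify = FALSE)
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Plot a fitted edaphic model
#'
#' Scatter of location mean soil depth against mean percent sand, symbols
#' scaled by location area, with dotted lines at the fitted thresholds —
#' the standard way to display a threshold calibration.
#'
#' @param x An [edaphic_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.edaphic_fit <- function(x, ...) {
  tab <- x$locations[!is.na(x$locations$mean_sand), ]
  cex <- 0.5 + 2 * sqrt(tab$total_area_m2 / max(tab$total_area_m2))
  in_train <- tab$location_id %in% x$train_ids
  graphics::plot(tab$mean_sand, tab$mean_depth_cm, cex = cex,
                 pch = ifelse(in_train, 16, 1),
                 col = grDevices::adjustcolor("steelblue4", 0.5),
                 xlab = "Location mean percent sand (%)",
                 ylab = "Location mean soil depth (cm)", ...)
  graphics::abline(v = x$thresholds["sand"], lty = 3)
  graphics::abline(h = x$thresholds["depth"], lty = 3)
  graphics::legend("bottomleft", pch = c(16, 1), bty = "n",
                   legend = c("training", "validation"))
  invisible(x)
}
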