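#' Soil profiles
#'
#' A `soil_profile` is one soil type (a SSURGO component): its depth-ordered
#' horizons with percent sand, plus the reported depth to the nearest
#' restrictive layer (e.g. bedrock). Depth to a restrictive layer is capped
#' at `cap_depth` (default 200 cm, the maximum depth soil surveys report);
#' a profile with no reported restrictive layer is treated as `cap_depth`
#' deep. The cap applies only to the restrictive-layer depth — horizon
#' weighting always covers the entire described profile.
#'
#' @param soil_type_id Identifier of the soil type.
#' @param top_cm,bottom_cm Numeric vectors of horizon top/bottom depths (cm
#'   below the surface); intervals must be positive and non-overlapping.
#' @param percent_sand Numeric vector of horizon sand contents in
#'   \[0, 100\]; `NA` where the survey reports none.
#' @param restrictive_depth_cm Depth (cm) to the nearest restrictive layer,
#'   or `NA` when none is reported.
#' @param cap_depth Maximum reported depth (cm); default 200.
#' @return An object of class `soil_profile`.
#' @export
#' @examples
#' p <- soil_profile("A", top_cm = c(0, 25), bottom_cm = c(25, 100),
#'                   percent_sand = c(100, 60))
#' profile_mean_sand(p)  # 70
#' profile_depth(p)      # 200 (no restrictive layer reported)
soil_profile <- function(soil_type_id, top_cm, bottom_cm, percent_sand,
                         restrictive_depth_cm = NA_real_, cap_depth = 200) {
  ord <- order(top_cm)
  top_cm <- as.numeric(top_cm)[ord]
  bottom_cm <- as.numeric(bottom_cm)[ord]
  percent_sand <- as.numeric(percent_sand)[ord]
  if (any(bottom_cm <= top_cm)) {
    stop("soil type ", soil_type_id, ": horizon bottom depth must exceed top depth")
  }
  if (length(top_cm) > 1 && any(top_cm[-1] < bottom_cm[-length(bottom_cm)] - 1e-9)) {
    stop("soil type ", soil_type_id, ": overlapping horizons")
  }
  if (any(!is.na(percent_sand) & (percent_sand < 0 | percent_sand > 100))) {
    stop("soil type ", soil_type_id, ": percent sand outside [0, 100]")
  }
  if (!is.na(restrictive_depth_cm) && restrictive_depth_cm <= 0) {
    stop("soil type ", soil_type_id, ": restrictive depth must be positive")
  }
  structure(list(soil_type_id = soil_type_id, top_cm = top_cm,
                 bottom_cm = bottom_cm, percent_sand = percent_sand,
                 restrictive_depth_cm = as.numeric(restrictive_depth_cm),
                 cap_depth = cap_depth),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> %s: %d horizon(s), 0-%g cm, restrictive depth %s cm\n",
              x$soil_type_id, length(x$top_cm), max(x$bottom_cm),
              if (is.na(x$restrictive_depth_cm)) "not reported" else
                format(x$restrictive_depth_cm)))
  invisible(x)
}

#' Depth-weighted mean percent sand of a soil profile
#'
#' The mean percent sand over the entire profile, weighting each horizon's
#' sand content by the horizon's length (cm). Horizons with missing sand are
#' excluded from both the numerator and the denominator (the weights are
#' renormalised over the horizons that carry data, not imputed). When no
#' horizon carries data the result is `NA` with attribute `no_data = TRUE`,
#' so callers can decide how to treat wholly undescribed profiles.
#'
#' @param profile A [soil_profile()].
#' @return Percent sand in \[0, 100\], or flagged `NA`.
#' @export
profile_mean_sand <- function(profile) {
  len <- profile$bottom_cm - profile$top_cm
  sand <- profile$percent_sand
  ok <- !is.na(sand)
  if (!any(ok)) {
    return(structure(NA_real_, no_data = TRUE))
  }
  sum(len[ok] * sand[ok]) / sum(len[ok])
}

#' Capped depth to the nearest restrictive layer
#'
#' Returns `min(restrictive_depth_cm, cap_depth)`; when no restrictive layer
#' is reported the profile is taken to be `cap_depth` deep.
#'
#' @param profile A [soil_profile()].
#' @return Depth in cm, in `(0, cap_depth]`.
#' @export
profile_depth <- function(profile) {
  if (is.na(profile$restrictive_depth_cm)) return(profile$cap_depth)
  min(profile$restrictive_depth_cm, profile$cap_depth)
}

#' Per-soil-type aggregates for a whole survey
#'
#' Vectorised application of [profile_mean_sand()] and [profile_depth()] to
#' every component of a survey.
#'
#' @param survey A [soil_survey()].
#' @param cap_depth Maximum reported depth (cm).
#' @return Data frame with one row per soil type: `soil_type_id`,
#'   `mean_sand` (NA when the component has no sand data) and `depth_cm`.
#' @export
aggregate_profiles <- function(survey, cap_depth = 200) {
  hz <- survey$horizons
  len <- hz$bottom_cm - hz$top_cm
  ok <- !is.na(hz$percent_sand)
  num <- rowsum((len * hz$percent_sand)[ok], hz$soil_type_id[ok])
  den <- rowsum(len[ok], hz$soil_type_id[ok])
  sand <- stats::setNames(as.numeric(num / den), rownames(num))

  comp <- unique(survey$components[, c("soil_type_id", "restrictive_depth_cm")])
  depth <- pmin(comp$restrictive_depth_cm, cap_depth)
  depth[is.na(depth)] <- cap_depth
  data.frame(
    soil_type_id = comp$soil_type_id,
    mean_sand = unname(sand[as.character(comp$soil_type_id)]),
    depth_cm = depth,
    stringsAsFactors = FALSE
  )
}
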