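#' Land-cover reclassification schemes
#'
#' A `landcover_scheme` maps every raw raster code to one of the summary
#' categories: `forest`, `open` (shrubland, grassland, barren), `agriculture`
#' (pasture/hay and cultivated crops), `urban`, `excluded` (open water and
#' wetlands, which the suitability map omits) or `other`.
#'
#' @param mapping Named character vector: names are raw codes (as character),
#'   values are categories.
#' @return An object of class `landcover_scheme`.
#' @export
landcover_scheme <- function(mapping) {
  allowed <- c("forest", "open", "agriculture", "urban", "excluded", "other")
  bad <- setdiff(unique(mapping), allowed)
  if (length(bad)) stop("unknown land-cover categories: ", paste(bad, collapse = ", "))
  structure(list(mapping = mapping, categories = allowed),
            class = "landcover_scheme")
}

#' NLCD-style default scheme
#'
#' The default mapping for National Land Cover Database codes: deciduous,
#' evergreen and mixed forest to `forest`; shrub/scrub, grassland/herbaceous
#' and barren land to `open`; pasture/hay and cultivated crops to
#' `agriculture`; the four developed classes to `urban`; open water and both
#' wetland classes to `excluded`; perennial ice/snow to `other`.
#'
#' @return A [landcover_scheme()].
#' @export
nlcd_scheme <- function() {
  landcover_scheme(c(
    "11" = "excluded", "12" = "other",
    "21" = "urban", "22" = "urban", "23" = "urban", "24" = "urban",
    "31" = "open",
    "41" = "forest", "42" = "forest", "43" = "forest",
    "52" = "open", "71" = "open",
    "81" = "agriculture", "82" = "agriculture",
    "90" = "excluded", "95" = "excluded"
  ))
}

#' Reclassify a categorical land-cover raster
#'
#' Substitutes each cell's raw code by its category (coded 1..6 in the order
#' forest, open, agriculture, urban, excluded, other; the order is attached
#' as attribute `categories`). The grid is unchanged. Codes present in the
#' raster but absent from the scheme raise an error listing them.
#'
#' @param cover A [grid_raster()] of raw codes.
#' @param scheme A [landcover_scheme()].
#' @return A [grid_raster()] of category codes with attribute `categories`.
#' @export
reclassify_landcover <- function(cover, scheme) {
  vals <- cover$values
  codes <- unique(as.vector(vals))
  codes <- codes[!is.na(codes) & codes != cover$nodata]
  unmapped <- setdiff(as.character(codes), names(scheme$mapping))
  if (length(unmapped)) {
    stop("land-cover codes with no category in the scheme: ",
         paste(sort(unmapped), collapse = ", "))
  }
  cat_idx <- match(scheme$mapping, scheme$categories)
  lut <- stats::setNames(cat_idx, names(scheme$mapping))
  out <- matrix(lut[as.character(vals)], nrow = nrow(vals))
  out[vals == cover$nodata] <- cover$nodata
  r <- grid_raster(out, cover$xmin, cover$ymin, cover$cellsize,
                   nodata = cover$nodata, crs = cover$crs)
  attr(r, "categories") <- scheme$categories
  r
}

#' Summarise land cover on suitable soils
#'
#' Intersects the suitability map with a reclassified land-cover raster and
#' reports, per region (default: the whole extent), the area of suitable
#' soil under each category and its proportion of the suitable total, plus
#' the landscape-wide area of each category for comparison. Proportions are
#' reported over the four named categories plus `other`; `excluded` cells
#' are never suitable by construction.
#'
#' @param map A [suitability_map()].
#' @param cover A reclassified land-cover raster ([reclassify_landcover()]),
#'   or a raw raster plus `scheme`.
#' @param regions Optional [vector_layer()] of region polygons with a
#'   `region_id` attribute.
#' @param scheme Scheme used when `cover` is a raw raster.
#' @return Data frame with columns `region`, `category`, `area_km2`
#'   (suitable soil under the category), `prop_of_suitable`,
#'   `landscape_area_km2`, `suitable_total_km2`.
#' @export
summarize_cover <- function(map, cover, regions = NULL, scheme = nlcd_scheme()) {
  if (is.null(attr(cover, "categories"))) {
    cover <- reclassify_landcover(cover, scheme)
  }
  categories <- attr(cover, "categories")
  cov <- resample_nearest(cover, map$raster)
  suit <- map$raster$values == state_codes["suitable"]
  cell_km2 <- map$cellsize^2 / 1e6

  region_cells <- function(geom) {
    xc <- raster_col_centres(map$raster)
    yc <- raster_row_centres(map$raster)
    gx <- rep(xc, each = length(yc))
    gy <- rep(yc, times = length(xc))
    matrix(points_in_geom(gx, gy, geom), nrow = length(yc))
  }

  one_region <- function(label, sel) {
    if (!any(sel)) {
      warning("region ", label, " does not intersect the mapped extent")
    }
    cv <- cov$values[sel]
    st_suit <- suit[sel]
    counts <- vapply(seq_along(categories), function(k) {
      sum(cv == k & st_suit, na.rm = TRUE)
    }, numeric(1))
    land_counts <- vapply(seq_along(categories), function(k) {
      sum(cv == k, na.rm = TRUE)
    }, numeric(1))
    total_suit <- sum(st_suit, na.rm = TRUE)
    reported <- categories != "excluded"
    prop <- rep(NA_real_, length(categories))
    denom <- sum(counts[reported])
    if (denom > 0) prop[reported] <- counts[reported] / denom
    data.frame(
      region = label,
      category = categories,
      area_km2 = counts * cell_km2,
      prop_of_suitable = prop,
      landscape_area_km2 = land_counts * cell_km2,
      suitable_total_km2 = total_suit * cell_km2,
      stringsAsFactors = FALSE
    )
  }

  if (is.null(regions)) {
    sel <- matrix(TRUE, nrow = nrow(map$raster$values), ncol = ncol(map$raster$values))
    return(one_region("all", sel))
  }
  labels <- if ("region_id" %in% names(regions$data)) {
    as.character(regions$data$region_id)
  } else {
    as.character(seq_along(regions$geometry))
  }
  out <- lapply(seq_along(regions$geometry), function(i) {
    one_region(labels[i], region_cells(regions$geometry[[i]]))
  })
  do.call(rbind, out)
}
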