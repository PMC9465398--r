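#' Overlap proportion of polygons with suitable soil
#'
#' For each polygon, the fraction of its area lying on suitable soil.
#' Computed on the map's raster: cells whose centre falls in the polygon are
#' tallied, and excluded or nodata cells count as non-suitable. Polygons
#' smaller than one cell fall back to the state of the cell containing their
#' centroid. Polygon area outside the mapped extent counts as non-suitable.
#'
#' @param entities A [vector_layer()] of polygons (labels in a `label`
#'   attribute; row numbers when absent).
#' @param map A [suitability_map()].
#' @return Data frame with `label`, `area_m2`, `overlap` in \[0, 1\].
#' @export
overlap_proportion_polygons <- function(entities, map) {
  r <- map$raster
  xc <- raster_col_centres(r)
  yc <- raster_row_centres(r)
  labels <- if ("label" %in% names(entities$data)) {
    as.character(entities$data$label)
  } else if ("location_id" %in% names(entities$data)) {
    as.character(entities$data$location_id)
  } else {
    as.character(seq_along(entities$geometry))
  }
  out <- lapply(seq_along(entities$geometry), function(i) {
    geom <- entities$geometry[[i]]
    a <- geom_area(geom)
    if (a <= 0) stop("entity ", labels[i], " has zero area")
    bb <- geom_bbox(geom)
    cols <- which(xc >= bb["xmin"] & xc <= bb["xmax"])
    rows <- which(yc >= bb["ymin"] & yc <= bb["ymax"])
    n_in <- 0; n_suit <- 0
    if (length(cols) && length(rows)) {
      gx <- rep(xc[cols], each = length(rows))
      gy <- rep(yc[rows], times = length(cols))
      inside <- points_in_geom(gx, gy, geom)
      if (any(inside)) {
        vals <- r$values[cbind(rep(rows, times = length(cols))[inside],
                               rep(cols, each = length(rows))[inside])]
        n_in <- sum(inside)
        n_suit <- sum(vals == state_codes["suitable"], na.rm = TRUE)
      }
    }
    if (n_in == 0) {
      # sub-cell polygon: use the cell under its centroid
      ctr <- geom_centroid(geom)
      cell <- raster_cell_of(r, ctr[1], ctr[2])
      st <- if (is.na(cell[1, 1])) NA else r$values[cell]
      n_in <- 1
      n_suit <- as.numeric(!is.na(st) && st == state_codes["suitable"])
    }
    data.frame(label = labels[i], area_m2 = a, overlap = n_suit / n_in,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overlap proportion of occurrence points with suitable soil
#'
#' Per group (species), the fraction of points whose containing cell is
#' suitable. Cell membership follows the raster's half-open cell intervals,
#' so no point belongs to two cells; points outside the mapped extent count
#' as non-overlapping and are tallied in the `n_outside` column.
#'
#' @param points Data frame with columns `label`, `x`, `y` and optionally
#'   `affinity` (`"high"` or `"other"`).
#' @param map A [suitability_map()].
#' @return Data frame with `label`, `affinity`, `n`, `n_outside`, `overlap`.
#' @export
overlap_proportion_points <- function(points, map) {
  if (!all(c("label", "x", "y") %in% names(points))) {
    stop("points need columns label, x, y")
  }
  cells <- raster_cell_of(map$raster, points$x, points$y)
  outside <- is.na(cells[, 1])
  state <- rep(NA_real_, nrow(points))
  state[!outside] <- map$raster$values[cells[!outside, , drop = FALSE]]
  suitable <- !is.na(state) & state == state_codes["suitable"]
  affinity <- if ("affinity" %in% names(points)) points$affinity else "n/a"
  groups <- split(seq_len(nrow(points)), points$label)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    data.frame(label = g,
               affinity = affinity[idx][1],
               n = length(idx),
               n_outside = sum(outside[idx]),
               overlap = mean(suitable[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Validate a suitability map by occurrence overlap
#'
#' Assembles the three validation strands into one report: per held-out
#' focal location (polygon overlap, plus a summary row giving the fraction
#' of held-out locations whose overlap exceeds `coverage_cutoff`), per
#' non-focal ecosystem type (area-weighted overlap aggregated over that
#' type's polygons), and per species (point overlap, with summary rows for
#' the mean over all species and over the high-affinity subset). Empty input
#' strands are omitted with a warning.
#'
#' @param map A [suitability_map()].
#' @param heldout Optional [vector_layer()] of held-out focal-location
#'   polygons.
#' @param nonfocal Optional [vector_layer()] of non-focal ecosystem polygons
#'   with a `label` attribute giving the ecosystem type.
#' @param species Optional data frame of occurrence points (`label`, `x`,
#'   `y`, optional `affinity`).
#' @param coverage_cutoff Overlap above which a held-out location counts as
#'   "fell within the map" in the binarised summary; default 0.5.
#' @return Data frame of class `validation_report` with columns `label`,
#'   `class` (`heldout-focal`, `nonfocal-ecosystem`, `species` or
#'   `summary`), `affinity`, `n`, `overlap`.
#' @export
validation_report <- function(map, heldout = NULL, nonfocal = NULL,
                              species = NULL, coverage_cutoff = 0.5) {
  rows <- list()
  row <- function(label, class, affinity, n, overlap) {
    data.frame(label = label, class = class, affinity = affinity,
               n = n, overlap = overlap, stringsAsFactors = FALSE)
  }
  if (!is.null(heldout) && length(heldout$geometry)) {
    hp <- overlap_proportion_polygons(heldout, map)
    rows <- c(rows, list(
      row(hp$label, "heldout-focal", "n/a", 1, hp$overlap),
      row(sprintf("heldout locations with overlap > %.2f", coverage_cutoff),
          "summary", "n/a", nrow(hp), mean(hp$overlap > coverage_cutoff))
    ))
  } else if (is.null(heldout)) {
  } else {
    warning("no held-out locations supplied; strand omitted")
  }
  if (!is.null(nonfocal) && length(nonfocal$geometry)) {
    np <- overlap_proportion_polygons(nonfocal, map)
    agg <- lapply(split(np, np$label), function(d) {
      row(d$label[1], "nonfocal-ecosystem", "n/a", nrow(d),
          sum(d$overlap * d$area_m2) / sum(d$area_m2))
    })
    rows <- c(rows, unname(agg))
  } else if (!is.null(nonfocal)) {
    warning("no non-focal ecosystems supplied; strand omitted")
  }
  if (!is.null(species) && nrow(species)) {
    sp <- overlap_proportion_points(species, map)
    rows <- c(rows, list(
      row(sp$label, "species", sp$affinity, sp$n, sp$overlap),
      row("mean over species", "summary", "n/a", nrow(sp), mean(sp$overlap))
    ))
    if (any(sp$affinity == "high")) {
      hi <- sp[sp$affinity == "high", ]
      rows <- c(rows, list(
        row("mean over high-affinity species", "summary", "high",
            nrow(hi), mean(hi$overlap))
      ))
    }
  } else if (!is.null(species)) {
    warning("no species occurrences supplied; strand omitted")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- row(character(0), character(0), character(0),
                               integer(0), numeric(0))
  class(out) <- c("validation_report", "data.frame")
  out
}
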