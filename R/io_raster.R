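#' Gridded rasters
#'
#' A `grid_raster` holds a single-band regular grid: a numeric matrix whose
#' first row is the northernmost row of cells, the coordinates of the lower
#' left corner, a square cell size in metres, a nodata value and a CRS tag.
#' On disk rasters are ESRI ASCII grids (`.asc`), a plain-text format every
#' GIS reads.
#'
#' @param values Numeric matrix; row 1 is the top (north) row.
#' @param xmin,ymin Coordinates of the lower-left corner (m).
#' @param cellsize Cell edge length (m).
#' @param nodata Value standing for missing cells.
#' @param crs CRS tag (planar metres assumed).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        nodata = -9999, crs = "local-metre") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells of %g m, origin (%g, %g), CRS: %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin, x$crs))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(xmin = r$xmin, ymin = r$ymin,
    xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymax = r$ymin + nrow(r$values) * r$cellsize)
}

# x coordinates of cell centres for columns, y for rows (row 1 = north)
raster_col_centres <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize
raster_row_centres <- function(r) {
  ymax <- r$ymin + nrow(r$values) * r$cellsize
  ymax - (seq_len(nrow(r$values)) - 0.5) * r$cellsize
}

#' Locate points on a raster grid
#'
#' Cell membership uses half-open intervals (a point on the shared edge of
#' two cells belongs to the cell to its east/north-of-bottom), so no point
#' belongs to two cells. Points outside the extent get NA.
#'
#' @param r A [grid_raster()].
#' @param x,y Point coordinates (m).
#' @return Integer matrix with columns `row`, `col` (NA outside the extent).
#' @export
raster_cell_of <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cellsize) + 1
  row_from_bottom <- floor((y - r$ymin) / r$cellsize) + 1
  row <- nrow(r$values) - row_from_bottom + 1
  bad <- col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param crs CRS tag to attach (the format itself carries none).
#' @return A [grid_raster()].
#' @export
read_ascii_grid <- function(path, crs = "local-metre") {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (suppressWarnings(is.na(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows
  if (is.null(ncols) || is.null(nrows)) stop("malformed ASCII grid header in ", path)
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != ncols * nrows) stop("ASCII grid has wrong cell count in ", path)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  grid_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = nodata, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param r A [grid_raster()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(formatC(vals[i, ], format = "g", digits = 15), collapse = " "), con)
  }
  invisible(path)
}

#' Nearest-neighbour resampling onto a template grid
#'
#' Used to co-register a 30 m land-cover raster with a 10 m soil grid. Each
#' template cell takes the value of the source cell containing its centre;
#' template cells outside the source extent get the nodata value.
#'
#' @param src Source [grid_raster()].
#' @param template [grid_raster()] defining the output grid (values ignored).
#' @return A [grid_raster()] on the template grid with `src`'s values.
#' @export
resample_nearest <- function(src, template) {
  if (!identical(src$crs, template$crs)) {
    stop("CRS mismatch: ", src$crs, " vs ", template$crs)
  }
  xc <- raster_col_centres(template)
  yc <- raster_row_centres(template)
  scol <- floor((xc - src$xmin) / src$cellsize) + 1
  srow_fb <- floor((yc - src$ymin) / src$cellsize) + 1
  srow <- nrow(src$values) - srow_fb + 1
  scol[scol < 1 | scol > ncol(src$values)] <- NA
  srow[srow < 1 | srow > nrow(src$values)] <- NA
  out <- matrix(src$nodata, nrow = nrow(template$values), ncol = ncol(template$values))
  ok_r <- which(!is.na(srow)); ok_c <- which(!is.na(scol))
  if (length(ok_r) && length(ok_c)) {
    out[ok_r, ok_c] <- src$values[srow[ok_r], scol[ok_c], drop = FALSE]
  }
  grid_raster(out, template$xmin, template$ymin, template$cellsize,
              nodata = src$nodata, crs = template$crs)
}

# Burn polygon features into a template grid: cells whose centre falls in a
# feature take that feature's value (later features win ties). Convex parts
# are located by bounding box then point-in-polygon on cell centres.
rasterize_features <- function(geometry, values, template, background = NA_real_) {
  out <- matrix(background, nrow = nrow(template$values), ncol = ncol(template$values))
  xc <- raster_col_centres(template)
  yc <- raster_row_centres(template)
  for (i in seq_along(geometry)) {
    bb <- geom_bbox(geometry[[i]])
    cols <- which(xc >= bb["xmin"] & xc <= bb["xmax"])
    rows <- which(yc >= bb["ymin"] & yc <= bb["ymax"])
    if (!length(cols) || !length(rows)) next
    gx <- rep(xc[cols], each = length(rows))
    gy <- rep(yc[rows], times = length(cols))
    inside <- points_in_geom(gx, gy, geometry[[i]])
    if (any(inside)) {
      idx <- cbind(rep(rows, times = length(cols))[inside],
                   rep(cols, each = length(rows))[inside])
      out[idx] <- values[i]
    }
  }
  grid_raster(out, template$xmin, template$ymin, template$cellsize,
              nodata = template$nodata, crs = template$crs)
}
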