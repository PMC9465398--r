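#' Vector layers
#'
#' A `vector_layer` is the package's lightweight feature collection: a list of
#' geometries (point vectors `c(x, y)`, ring matrices, or lists of ring
#' matrices for multi-part polygons), a data frame of attributes with one row
#' per feature, and a CRS tag. Coordinates are planar metres.
#'
#' @param geometry List of geometries.
#' @param data Data frame of feature attributes (one row per geometry).
#' @param crs Character CRS tag. `"local-metre"` marks a planar local frame.
#' @return An object of class `vector_layer`.
#' @export
vector_layer <- function(geometry, data = NULL, crs = "local-metre") {
  if (is.null(data)) data <- data.frame(row.names = seq_along(geometry))
  if (nrow(data) != length(geometry)) {
    stop("attribute table must have one row per geometry")
  }
  structure(list(geometry = geometry, data = data, crs = crs),
            class = "vector_layer")
}

#' @export
length.vector_layer <- function(x) length(x$geometry)

#' @export
print.vector_layer <- function(x, ...) {
  cat(sprintf("<vector_layer> %d feature(s), CRS: %s\n", length(x$geometry), x$crs))
  if (ncol(x$data)) {
    cat("attributes:", paste(names(x$data), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Feature areas of a vector layer
#'
#' @param layer A `vector_layer` of polygons.
#' @return Numeric vector of areas (m^2), one per feature; points get 0.
#' @export
layer_areas <- function(layer) {
  vapply(layer$geometry, function(g) {
    if (is.numeric(g) && is.null(dim(g))) 0 else geom_area(g)
  }, numeric(1))
}

geojson_geometry <- function(g) {
  close_ring <- function(r) {
    r <- as_ring(r)
    rbind(r, r[1, , drop = FALSE])
  }
  if (is.numeric(g) && is.null(dim(g))) {
    list(type = "Point", coordinates = as.list(unname(g[1:2])))
  } else if (is.matrix(g) || is.data.frame(g)) {
    r <- close_ring(g)
    list(type = "Polygon",
         coordinates = list(lapply(seq_len(nrow(r)), function(i) as.list(unname(r[i, ])))))
  } else {
    parts <- lapply(g, function(r) {
      r <- close_ring(r)
      list(lapply(seq_len(nrow(r)), function(i) as.list(unname(r[i, ]))))
    })
    list(type = "MultiPolygon", coordinates = parts)
  }
}

parse_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  as_ring(m)
}

parse_geometry <- function(g) {
  type <- g$type
  if (identical(type, "Point")) {
    return(c(x = g$coordinates[[1]], y = g$coordinates[[2]]))
  }
  if (identical(type, "Polygon")) {
    if (length(g$coordinates) > 1) {
      stop("interior rings (holes) are not supported")
    }
    return(parse_ring(g$coordinates[[1]]))
  }
  if (identical(type, "MultiPolygon")) {
    parts <- lapply(g$coordinates, function(poly) {
      if (length(poly) > 1) stop("interior rings (holes) are not supported")
      parse_ring(poly[[1]])
    })
    if (length(parts) == 1) return(parts[[1]])
    return(parts)
  }
  stop("unsupported geometry type: ", type)
}

#' Read a GeoJSON vector layer
#'
#' Supports Point, Polygon and MultiPolygon features without interior rings.
#' GeoJSON carries no projected CRS, so when the file lacks a (legacy) `crs`
#' member the coordinates are assumed to be planar metres, with a warning.
#'
#' @param path Path to a GeoJSON FeatureCollection file.
#' @param quiet Suppress the missing-CRS warning.
#' @return A [vector_layer()].
#' @export
read_vector_layer <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read vector layer: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  crs <- js$crs$properties$name
  if (is.null(crs)) {
    crs <- "local-metre"
    if (!quiet) {
      warning("no CRS declared in ", basename(path),
              "; assuming planar metre coordinates", call. = FALSE)
    }
  }
  feats <- js$features
  geometry <- lapply(feats, function(f) parse_geometry(f$geometry))
  props <- lapply(feats, function(f) {
    p <- f$properties
    if (is.null(p)) list() else lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(props, names)))
  data <- as.data.frame(
    lapply(stats::setNames(keys, keys), function(k) {
      vals <- lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
      unlist(vals)
    }),
    optional = TRUE, stringsAsFactors = FALSE
  )
  if (length(feats) == 0) data <- data.frame()
  vector_layer(geometry, data, crs = crs)
}

#' Write a vector layer to GeoJSON
#'
#' The CRS tag is stored in a legacy `crs` member so that round-tripping
#' through [read_vector_layer()] preserves it.
#'
#' @param layer A [vector_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vector_layer <- function(layer, path) {
  feats <- lapply(seq_along(layer$geometry), function(i) {
    props <- if (ncol(layer$data)) as.list(layer$data[i, , drop = FALSE]) else NULL
    if (!is.null(props)) props <- lapply(props, function(v) if (is.na(v)) NULL else v)
    list(type = "Feature",
         properties = props,
         geometry = geojson_geometry(layer$geometry[[i]]))
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = layer$crs)),
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
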