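#' Planar geometry primitives
#'
#' The package works in a projected coordinate reference system with metre
#' units (soil surveys and land-cover rasters are delivered that way).
#' Polygons are single closed rings stored as two-column matrices of vertex
#' coordinates (columns `x`, `y`); the first vertex is not repeated at the
#' end. Multi-part polygons are lists of such rings whose areas add.
#' Interior rings (holes) are not supported.
#'
#' @name edaphic-geometry
#' @keywords internal
NULL

#' Area of a polygon ring (shoelace formula)
#'
#' @param ring Two-column numeric matrix of vertices (unclosed).
#' @return Area in squared coordinate units (m^2 for metre CRS).
#' @export
#' @examples
#' ring_area(cbind(c(0, 10, 10, 0), c(0, 0, 5, 5)))  # 50
ring_area <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Signed area: positive for counter-clockwise rings.
ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  if (ncol(ring) != 2) stop("a ring must have two coordinate columns")
  # drop an explicitly closed last vertex
  n <- nrow(ring)
  if (n > 1 && isTRUE(all(ring[1, ] == ring[n, ]))) ring <- ring[-n, , drop = FALSE]
  ring
}

#' Area of a (possibly multi-part) polygon geometry
#'
#' @param geom A ring matrix or a list of ring matrices.
#' @return Total area (m^2).
#' @export
geom_area <- function(geom) {
  if (is.matrix(geom) || is.data.frame(geom)) return(ring_area(geom))
  sum(vapply(geom, ring_area, numeric(1)))
}

geom_rings <- function(geom) {
  if (is.matrix(geom) || is.data.frame(geom)) list(as_ring(geom)) else lapply(geom, as_ring)
}

geom_bbox <- function(geom) {
  rings <- geom_rings(geom)
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

geom_centroid <- function(geom) {
  # area-weighted centroid over parts
  rings <- geom_rings(geom)
  cs <- t(vapply(rings, ring_centroid, numeric(3)))
  w <- cs[, 3]
  if (sum(w) <= 0) {
    pts <- do.call(rbind, rings)
    return(colMeans(pts))
  }
  c(sum(cs[, 1] * w), sum(cs[, 2] * w)) / sum(w)
}

ring_centroid <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y), 0))
  }
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  c(cx, cy, abs(a))
}

#' Test whether a ring is convex
#'
#' Collinear vertices are tolerated. Used to guard the clipping routine,
#' which requires a convex clip window.
#'
#' @param ring Two-column vertex matrix.
#' @return Logical scalar.
#' @export
is_convex_ring <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  i0 <- seq_len(n)
  i1 <- c(2:n, 1)
  i2 <- c(3:n, 1, 2)
  cross <- (ring[i1, 1] - ring[i0, 1]) * (ring[i2, 2] - ring[i1, 2]) -
    (ring[i1, 2] - ring[i0, 2]) * (ring[i2, 1] - ring[i1, 1])
  all(cross >= -1e-9 * max(abs(cross), 1)) || all(cross <= 1e-9 * max(abs(cross), 1))
}

# Sutherland-Hodgman: clip `subject` (any simple ring) against one directed
# edge (a -> b) of a counter-clockwise convex window, keeping the left side.
clip_edge <- function(subject, ax, ay, bx, by) {
  n <- nrow(subject)
  if (n == 0) return(subject)
  out_x <- numeric(2 * n + 4)
  out_y <- numeric(2 * n + 4)
  k <- 0
  ex <- bx - ax; ey <- by - ay
  side <- function(px, py) ex * (py - ay) - ey * (px - ax)
  sx <- subject[n, 1]; sy <- subject[n, 2]
  s_in <- side(sx, sy) >= 0
  for (i in seq_len(n)) {
    px <- subject[i, 1]; py <- subject[i, 2]
    p_in <- side(px, py) >= 0
    if (p_in) {
      if (!s_in) {
        t <- side(sx, sy) / (side(sx, sy) - side(px, py))
        k <- k + 1
        out_x[k] <- sx + t * (px - sx); out_y[k] <- sy + t * (py - sy)
      }
      k <- k + 1
      out_x[k] <- px; out_y[k] <- py
    } else if (s_in) {
      t <- side(sx, sy) / (side(sx, sy) - side(px, py))
      k <- k + 1
      out_x[k] <- sx + t * (px - sx); out_y[k] <- sy + t * (py - sy)
    }
    sx <- px; sy <- py; s_in <- p_in
  }
  cbind(out_x[seq_len(k)], out_y[seq_len(k)])
}

#' Clip a polygon against a convex window
#'
#' Sutherland–Hodgman clipping of an arbitrary simple ring against a convex
#' ring. Returns the intersection ring (possibly with zero vertices when the
#' polygons are disjoint).
#'
#' @param subject Ring matrix (any simple polygon).
#' @param window Ring matrix; must be convex.
#' @return Ring matrix of the intersection (0 rows if empty).
#' @export
clip_convex <- function(subject, window) {
  subject <- as_ring(subject)
  window <- as_ring(window)
  if (!is_convex_ring(window)) {
    stop("clip window must be a convex ring")
  }
  if (ring_signed_area(window) < 0) window <- window[rev(seq_len(nrow(window))), , drop = FALSE]
  n <- nrow(window)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    out <- clip_edge(out, window[i, 1], window[i, 2], window[j, 1], window[j, 2])
    if (nrow(out) == 0) break
  }
  out
}

#' Intersection area between a polygon geometry and a convex ring
#'
#' @param geom Ring matrix or list of ring matrices.
#' @param window Convex ring matrix.
#' @return Area of the intersection (m^2).
#' @export
intersection_area <- function(geom, window) {
  sum(vapply(geom_rings(geom), function(r) ring_area(clip_convex(r, window)),
             numeric(1)))
}

#' Points-in-ring test (even-odd rule)
#'
#' Vectorised ray casting. Points exactly on an edge may resolve to either
#' side; the overlay code never depends on boundary points.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param ring Ring matrix.
#' @return Logical vector.
#' @export
points_in_ring <- function(x, y, ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_geom <- function(x, y, geom) {
  rings <- geom_rings(geom)
  inside <- logical(length(x))
  for (r in rings) inside <- inside | points_in_ring(x, y, r)
  inside
}

# axis-aligned rectangle ring
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
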