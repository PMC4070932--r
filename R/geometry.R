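# Planar polygon utilities on lon/lat coordinates. Within the synthetic
# domain cell areas are treated as planar (degree^2); the per-cell wetland
# fraction is a ratio, so the areal unit cancels.

#' Polygon area by the shoelace formula
#'
#' @param ring Two-column matrix of vertices (x = lon, y = lat), open ring
#'   (first vertex not repeated).
#' @return Absolute area in squared coordinate units.
#' @export
poly_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Axis-aligned rectangle as a polygon ring
#'
#' @param x0,x1,y0,y1 Rectangle bounds (`x0 < x1`, `y0 < y1`).
#' @return Open 4-vertex ring matrix, counter-clockwise.
#' @export
rect_ring <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Sutherland-Hodgman clip of a ring against the rectangle [x0,x1]x[y0,y1].
# Returns a ring matrix or NULL when the intersection is empty/degenerate.
clip_ring_rect <- function(ring, x0, x1, y0, y1) {
  clip_edge <- function(pts, inside, intersect) {
    if (is.null(pts) || nrow(pts) == 0) return(NULL)
    n <- nrow(pts)
    out_x <- numeric(0); out_y <- numeric(0)
    for (i in seq_len(n)) {
      p <- pts[i, ]; q <- pts[if (i == n) 1L else i + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) { out_x <- c(out_x, p[1]); out_y <- c(out_y, p[2]) }
      if (xor(pin, qin)) {
        s <- intersect(p, q)
        out_x <- c(out_x, s[1]); out_y <- c(out_y, s[2])
      }
    }
    if (length(out_x) < 3) return(NULL)
    cbind(out_x, out_y)
  }
  ix <- function(p, q, val, ax) {  # intersection with axis-parallel line
    t <- (val - p[ax]) / (q[ax] - p[ax])
    p + t * (q - p)
  }
  pts <- ring
  pts <- clip_edge(pts, function(p) p[1] >= x0, function(p, q) ix(p, q, x0, 1))
  pts <- clip_edge(pts, function(p) p[1] <= x1, function(p, q) ix(p, q, x1, 1))
  pts <- clip_edge(pts, function(p) p[2] >= y0, function(p, q) ix(p, q, y0, 2))
  pts <- clip_edge(pts, function(p) p[2] <= y1, function(p, q) ix(p, q, y1, 2))
  pts
}

# Ray-casting point-in-polygon (boundary counts as inside).
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# Minimum distance from points to a polygon boundary segment set; 0 inside.
dist_to_ring <- function(px, py, ring) {
  n <- nrow(ring)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[if (k == n) 1L else k + 1L, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
    dx <- px - (a[1] + t * abx); dy <- py - (a[2] + t * aby)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  d <- sqrt(d2)
  d[point_in_ring(px, py, ring)] <- 0
  d
}

#' Buffer a polyline into rectangle polygons
#'
#' Represents a stream centerline as a set of per-segment rectangles of the
#' given width. Joints are not mitred, so areas at bends are approximate;
#' intended for building synthetic stream polygons, not precise hydrography.
#'
#' @param coords Two-column matrix of line vertices.
#' @param width Total buffer width in coordinate units.
#' @return List of ring matrices, one per segment.
#' @export
buffer_line <- function(coords, width) {
  stopifnot(nrow(coords) >= 2, width > 0)
  h <- width / 2
  out <- vector("list", nrow(coords) - 1L)
  for (i in seq_len(nrow(coords) - 1L)) {
    a <- coords[i, ]; b <- coords[i + 1L, ]
    v <- b - a; len <- sqrt(sum(v^2))
    if (len == 0) next
    nvec <- c(-v[2], v[1]) / len * h
    out[[i]] <- rbind(a + nvec, b + nvec, b - nvec, a - nvec)
  }
  out[!vapply(out, is.null, logical(1))]
}
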