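# Fractional wetland-cover raster from classified water-body polygons.

#' Water-body class vocabulary
#'
#' `water_classes()` lists all recognised classes; `kept_water_classes()`
#' lists the habitat classes that count as wetland for watersnakes
#' (perennial natural and artificial streams, lakes/ponds, reservoirs,
#' swamps/marshes). Desert playas, saline lakes, estuaries, peat bogs, and
#' intermittent streams are recognised but excluded by default.
#'
#' @return Character vector of class labels.
#' @export
water_classes <- function() {
  c("perennial_stream", "artificial_stream", "lake_pond", "reservoir",
    "swamp_marsh", "playa", "saline_lake", "estuary", "peat_bog",
    "intermittent")
}

#' @rdname water_classes
#' @export
kept_water_classes <- function() {
  c("perennial_stream", "artificial_stream", "lake_pond", "reservoir",
    "swamp_marsh")
}

#' Construct a classified water-body polygon
#'
#' @param class_label One of [water_classes()].
#' @param ring Two-column vertex matrix (lon, lat), open ring, non-degenerate.
#' @return A `water_body` object.
#' @export
water_body <- function(class_label, ring) {
  if (!class_label %in% water_classes())
    stop("unknown water-body class: ", class_label)
  ring <- as.matrix(ring)
  if (nrow(ring) < 3 || ncol(ring) != 2 || anyNA(ring))
    stop("invalid geometry: need a >=3-vertex finite ring")
  if (poly_area(ring) <= 0) stop("invalid geometry: zero-area ring")
  structure(list(class_label = class_label, ring = ring), class = "water_body")
}

#' Build the fractional wetland-cover raster
#'
#' For every grid cell, the value is the total area of kept-class polygons
#' intersecting the cell divided by the cell area, clipped to `[0, 1]`
#' (overlapping polygons can push the raw sum above 1). Dropped classes
#' contribute nothing. Areas are planar in degree^2; since the result is a
#' per-cell ratio the areal unit cancels.
#'
#' @param polygons List of [water_body()] objects (e.g. a
#'   [generate_water_bodies()] output).
#' @param grid A [grid_spec()].
#' @param keep_classes Classes counted as wetland; default
#'   [kept_water_classes()].
#' @return A [raster_layer()] of fractions in `[0, 1]`.
#' @export
build_wetland_raster <- function(polygons, grid,
                                 keep_classes = kept_water_classes()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(keep_classes %in% water_classes()))
    stop("keep_classes outside the class vocabulary")
  cs <- grid$cell_size
  cell_area <- cs^2
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (wb in polygons) {
    stopifnot(inherits(wb, "water_body"))
    if (!wb$class_label %in% keep_classes) next
    ring <- wb$ring
    # cell index window covered by the polygon bbox
    c0 <- max(1L, floor((min(ring[, 1]) - grid$origin_lon) / cs) + 1L)
    c1 <- min(grid$n_cols, floor((max(ring[, 1]) - grid$origin_lon) / cs - 1e-12) + 1L)
    r0 <- max(1L, floor((grid$origin_lat - max(ring[, 2])) / cs) + 1L)
    r1 <- min(grid$n_rows, floor((grid$origin_lat - min(ring[, 2])) / cs - 1e-12) + 1L)
    if (c0 > c1 || r0 > r1) next
    for (r in r0:r1) {
      y1 <- grid$origin_lat - (r - 1) * cs
      y0 <- y1 - cs
      for (cc in c0:c1) {
        x0 <- grid$origin_lon + (cc - 1) * cs
        clipped <- clip_ring_rect(ring, x0, x0 + cs, y0, y1)
        if (!is.null(clipped)) acc[r, cc] <- acc[r, cc] + poly_area(clipped)
      }
    }
  }
  raster_layer(grid, pmin(acc / cell_area, 1))
}
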