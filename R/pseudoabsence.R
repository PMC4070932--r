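# Accessible-area delimitation and pseudo-absence sampling. Distances are
# Euclidean in decimal degrees, matching the way the exclusion constraint is
# stated ("at least 2 degrees from known presence points").

#' Delimit the accessible area around presences
#'
#' Cells whose centers lie within `buffer_deg` (degree metric) of the convex
#' hull of the presences are marked accessible. With fewer than 3
#' non-collinear presences the hull degenerates and the union of point
#' buffers of radius `buffer_deg` is used instead.
#'
#' @param presences An [occurrence_set()].
#' @param buffer_deg Non-negative buffer in decimal degrees.
#' @param grid A [grid_spec()].
#' @return A [raster_layer()] with values 1 (accessible) / 0.
#' @export
accessible_area <- function(presences, buffer_deg, grid) {
  stopifnot(inherits(presences, "occurrence_set"), inherits(grid, "grid_spec"))
  if (buffer_deg < 0) stop("buffer_deg must be >= 0")
  if (nrow(presences) == 0) stop("no presences")
  ctr <- grid_centers(grid)
  px <- presences$lon; py <- presences$lat
  hull <- unique(cbind(px, py))
  degenerate <- nrow(hull) < 3
  if (!degenerate) {
    h <- grDevices::chull(hull[, 1], hull[, 2])
    degenerate <- length(h) < 3
    if (!degenerate) hull <- hull[h, , drop = FALSE]
  }
  if (degenerate) {
    d2 <- matrix(Inf, grid$n_rows, grid$n_cols)
    for (i in seq_len(nrow(hull)))
      d2 <- pmin(d2, (ctr$lon - hull[i, 1])^2 + (ctr$lat - hull[i, 2])^2)
    acc <- sqrt(d2) <= buffer_deg
  } else {
    d <- dist_to_ring(as.vector(ctr$lon), as.vector(ctr$lat), hull)
    acc <- matrix(d <= buffer_deg, grid$n_rows, grid$n_cols)
  }
  raster_layer(grid, acc + 0)
}

#' Sample pseudo-absences
#'
#' Draws `n` background points, one per grid cell (cell centers), uniformly
#' over the admissible cells: accessible, carrying valid data on every layer
#' of `env` (when given), and at least `min_dist_deg` (Euclidean degrees)
#' from every presence. Deterministic given `seed`. The reference workflow
#' uses `n = nrow(presences)` and `min_dist_deg = 2`.
#'
#' @param presences An [occurrence_set()].
#' @param accessible A binary [raster_layer()] from [accessible_area()].
#' @param min_dist_deg Minimum distance to any presence, in degrees.
#' @param n Number of points; default equals the number of presences.
#' @param seed Integer seed.
#' @param env Optional [env_stack()] used to exclude nodata cells.
#' @return A `pseudo_absence_set`: data.frame of `lon`, `lat` with attributes
#'   recording the constraints and seed.
#' @export
sample_pseudo_absences <- function(presences, accessible, min_dist_deg = 2,
                                   n = nrow(presences), seed = 1, env = NULL) {
  stopifnot(inherits(presences, "occurrence_set"),
            inherits(accessible, "raster_layer"))
  grid <- accessible$grid
  ok <- admissible_cells(presences, accessible, min_dist_deg, env)
  idx <- which(ok)
  if (length(idx) < n)
    stop(sprintf(
      "admissible region has %d cells but %d pseudo-absences requested (deficit %d)",
      length(idx), n, n - length(idx)))
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n)]
  ctr <- grid_centers(grid)
  structure(
    data.frame(lon = ctr$lon[pick], lat = ctr$lat[pick]),
    min_dist_deg = min_dist_deg, seed = seed, n = n,
    class = c("pseudo_absence_set", "data.frame"))
}

# Logical matrix of cells satisfying all pseudo-absence constraints.
admissible_cells <- function(presences, accessible, min_dist_deg, env = NULL) {
  grid <- accessible$grid
  ctr <- grid_centers(grid)
  ok <- accessible$values > 0
  if (!is.null(env)) {
    for (l in env$layers) ok <- ok & !is.na(l$values)
  }
  if (min_dist_deg > 0) {
    d2min <- matrix(Inf, grid$n_rows, grid$n_cols)
    for (i in seq_len(nrow(presences))) {
      d2 <- (ctr$lon - presences$lon[i])^2 + (ctr$lat - presences$lat[i])^2
      d2min <- pmin(d2min, d2)
    }
    ok <- ok & d2min >= min_dist_deg^2
  } else {
    # still never drop a point onto a presence cell
    idx <- cell_of(grid, presences$lon, presences$lat)
    hit <- !is.na(idx$row)
    ok[cbind(idx$row[hit], idx$col[hit])] <- FALSE
  }
  ok
}
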