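# Risk assessment: binarization, per-native-species range overlap, source-
# connected suitable extent (flood fill through suitable cells), and the
# overlap decline under the connectivity constraint.

#' Binarize a suitability surface
#'
#' A cell is suitable iff its value is `>= threshold` (the single
#' suitability convention used across thresholding, omission, and
#' binarization). Nodata propagates.
#'
#' @param surface A [suitability_surface()].
#' @param threshold Finite threshold.
#' @return A [raster_layer()] of 1 (suitable) / 0 / NA.
#' @export
binarize <- function(surface, threshold) {
  stopifnot(is.finite(threshold))
  raster_layer(surface$raster$grid, (surface$raster$values >= threshold) + 0)
}

#' Suitability of a native species' range
#'
#' Collects the suitability values of all valid cells inside the rasterized
#' range and reports a five-number boxplot summary (whiskers extend to the
#' most extreme data point within 1.5 x IQR of the box) plus the proportion
#' of range cells at or above the threshold — the range-overlap risk metric.
#' Cells with nodata suitability are excluded from both numerator and
#' denominator; their count is recorded.
#'
#' @param surface A [suitability_surface()].
#' @param threshold Binarization threshold.
#' @param range_map A [range_map()].
#' @return An `overlap_report`: list with `species_id`,
#'   `suitability_quartiles` (`min_whisker`, `q1`, `median`, `q3`,
#'   `max_whisker`), `proportion_suitable`, `n_cells`, `n_excluded`.
#' @export
range_overlap <- function(surface, threshold, range_map) {
  mask <- rasterize_range(range_map, surface$raster$grid)
  vals <- surface$raster$values[mask]
  n_excluded <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("range does not intersect valid cells")
  q <- unname(quantile(vals, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo <- min(vals[vals >= q[1] - 1.5 * iqr])
  hi <- max(vals[vals <= q[3] + 1.5 * iqr])
  structure(list(
    species_id = range_map$species_id,
    suitability_quartiles = c(min_whisker = lo, q1 = q[1], median = q[2],
                              q3 = q[3], max_whisker = hi),
    proportion_suitable = mean(vals >= threshold),
    n_cells = length(vals), n_excluded = n_excluded),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%s: %.1f%% of %d range cells suitable (median suitability %.3f)\n",
              x$species_id, 100 * x$proportion_suitable, x$n_cells,
              x$suitability_quartiles["median"]))
  invisible(x)
}

# One flood-fill dilation step under the 4- or 8-neighbor rule.
dilate_once <- function(m, neighbors) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  if (neighbors == 8) {
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  }
  out
}

#' Suitable area connected to source populations
#'
#' Zero-cost flood fill from the source cells: movement is allowed only
#' through suitable cells, with unsuitable cells acting as barriers. Sources
#' falling on unsuitable or nodata cells contribute nothing (with a
#' warning when none remain).
#'
#' @param suitable Binary [raster_layer()] (e.g. from [binarize()]).
#' @param sources Data.frame or matrix of source coordinates (`lon`, `lat`).
#' @param neighbors 4 (rook) or 8 (queen, default — matches cost-distance
#'   tools' adjacency).
#' @return A `connectivity_mask`: list with `reachable` ([raster_layer()] of
#'   1/0), `sources`, `connectivity_rule`.
#' @export
connected_suitable <- function(suitable, sources, neighbors = 8) {
  if (!neighbors %in% c(4, 8)) stop("neighbors must be 4 or 8")
  sources <- as.data.frame(sources)
  if (nrow(sources) == 0) stop("need at least one source")
  grid <- suitable$grid
  suit <- !is.na(suitable$values) & suitable$values > 0
  idx <- cell_of(grid, sources[[1]], sources[[2]])
  reach <- matrix(FALSE, grid$n_rows, grid$n_cols)
  ok <- !is.na(idx$row)
  seeded <- FALSE
  for (i in which(ok)) {
    if (suit[idx$row[i], idx$col[i]]) {
      reach[idx$row[i], idx$col[i]] <- TRUE
      seeded <- TRUE
    }
  }
  if (!seeded) {
    warning("no source falls on a suitable cell; reachable mask is empty")
  } else {
    repeat {
      grown <- dilate_once(reach, neighbors) & suit
      if (identical(grown, reach)) break
      reach <- grown
    }
  }
  structure(list(reachable = raster_layer(grid, reach + 0),
                 sources = sources, connectivity_rule = neighbors),
            class = "connectivity_mask")
}

#' Range overlap restricted to source-connected habitat
#'
#' Recomputes the overlap proportion counting only range cells that are both
#' suitable and reachable from the sources, and reports the decline relative
#' to the unrestricted proportion (non-negative by construction).
#'
#' @param surface A [suitability_surface()].
#' @param threshold Binarization threshold.
#' @param range_map A [range_map()].
#' @param mask A [connected_suitable()] result.
#' @return List with `unrestricted`, `connected`, `decline`.
#' @export
overlap_decline <- function(surface, threshold, range_map, mask) {
  rmask <- rasterize_range(range_map, surface$raster$grid)
  vals <- surface$raster$values[rmask]
  reach <- mask$reachable$values[rmask]
  keep <- !is.na(vals)
  if (!any(keep)) stop("range does not intersect valid cells")
  vals <- vals[keep]; reach <- reach[keep]
  unrestricted <- mean(vals >= threshold)
  connected <- mean(vals >= threshold & reach > 0)
  list(unrestricted = unrestricted, connected = connected,
       decline = unrestricted - connected)
}
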