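# Plain-text interchange: occurrence CSV, polygon/range/source GeoJSON.

#' Occurrence CSV input/output
#'
#' Columns: `species`, `lon`, `lat`, `precision_km` (and optionally
#' `source`).
#'
#' @param path File path.
#' @param x An [occurrence_set()].
#' @return `read_occurrences_csv()` returns an [occurrence_set()].
#' @export
read_occurrences_csv <- function(path) {
  occurrence_set(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrences_csv
#' @export
write_occurrences_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

ring_to_geojson_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

geojson_coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Water-body polygons as GeoJSON
#'
#' Each polygon is a Feature with a `"class"` property from
#' [water_classes()].
#'
#' @param polygons List of [water_body()] objects.
#' @param path File path.
#' @return `read_water_bodies_geojson()` returns a list of [water_body()].
#' @export
write_water_bodies_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(wb) {
    list(type = "Feature",
         properties = list(class = wb$class_label),
         geometry = list(type = "Polygon",
                         coordinates = list(ring_to_geojson_coords(wb$ring))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_water_bodies_geojson
#' @export
read_water_bodies_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    water_body(f$properties$class,
               geojson_coords_to_ring(f$geometry$coordinates[[1]]))
  })
}

#' Range maps as GeoJSON
#'
#' Ranges are written as MultiPolygon Features with a `"species"` property;
#' reading returns [range_map()] objects backed by polygon rings (rasterized
#' by cell-center containment).
#'
#' @param ranges List of [range_map()] objects.
#' @param path File path.
#' @param grid Required when writing mask-backed ranges.
#' @return `read_ranges_geojson()` returns a list of [range_map()].
#' @export
write_ranges_geojson <- function(ranges, path, grid = NULL) {
  feats <- lapply(ranges, function(rm) {
    rings <- range_rings(rm, grid)
    list(type = "Feature",
         properties = list(species = rm$species_id),
         geometry = list(
           type = "MultiPolygon",
           coordinates = lapply(rings, function(r)
             list(ring_to_geojson_coords(r)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_ranges_geojson
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(poly)
      geojson_coords_to_ring(poly[[1]]))
    range_map(f$properties$species, rings = rings)
  })
}

# Polygon rings of a range map (rect ranges become 4-vertex rings; mask
# ranges need the grid to trace cell outlines, emitted per-cell).
range_rings <- function(rm, grid = NULL) {
  if (!is.null(rm$rings)) return(rm$rings)
  if (!is.null(rm$rects))
    return(lapply(rm$rects, function(r) rect_ring(r["x0"], r["x1"], r["y0"], r["y1"])))
  if (is.null(grid)) stop("mask-backed ranges need a grid to export")
  cells <- which(rm$mask, arr.ind = TRUE)
  cs <- grid$cell_size
  lapply(seq_len(nrow(cells)), function(i) {
    x0 <- grid$origin_lon + (cells[i, 2] - 1) * cs
    y1 <- grid$origin_lat - (cells[i, 1] - 1) * cs
    rect_ring(x0, x0 + cs, y1 - cs, y1)
  })
}

#' Source-population points as CSV
#'
#' @param sources Data.frame with `lon`, `lat`.
#' @param path File path.
#' @return `read_sources_csv()` returns a data.frame.
#' @export
write_sources_csv <- function(sources, path) {
  write.csv(as.data.frame(sources), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sources_csv
#' @export
read_sources_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
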