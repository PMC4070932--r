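#' @useDynLib invrisk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd cor sd predict coef
#' @importFrom utils head read.csv write.csv
NULL

#' Define a geographic analysis grid
#'
#' A regular lat/lon grid of square cells. Cell (1,1) is the north-west
#' corner; a cell covers the half-open interval \code{[edge, edge + cell_size)}
#' in longitude (west edge inclusive) and, measured southward from the
#' northern origin, the analogous half-open band in latitude (north edge
#' inclusive).
#'
#' @param origin_lon Longitude of the western edge (decimal degrees).
#' @param origin_lat Latitude of the northern edge (decimal degrees).
#' @param cell_size Cell edge length in decimal degrees; must be positive.
#'   The analysis resolution used throughout is 2.5 arc-minutes
#'   (\code{2.5/60} degrees) for real-data work; synthetic benchmarks may use
#'   coarser cells.
#' @param n_rows,n_cols Grid dimensions (rows run north to south).
#' @return A \code{grid_spec} object.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat), is.numeric(cell_size))
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  structure(
    list(origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.6g deg, NW corner (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%.6g", x$n_rows, x$n_cols, x$cell_size)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `grid_lon_centers()` / `grid_lat_centers()` return numeric vectors
#'   (latitudes descend from the northern origin). `grid_centers()` returns a
#'   list with matrices `lon` and `lat` of dimension `n_rows x n_cols`.
#' @export
grid_lon_centers <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname grid_lon_centers
#' @export
grid_lat_centers <- function(grid) {
  grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' @rdname grid_lon_centers
#' @export
grid_centers <- function(grid) {
  list(lon = matrix(grid_lon_centers(grid), grid$n_rows, grid$n_cols, byrow = TRUE),
       lat = matrix(grid_lat_centers(grid), grid$n_rows, grid$n_cols))
}

#' Locate points on a grid
#'
#' Maps lon/lat coordinates to 1-based row/column indices. Points outside the
#' grid extent get NA indices.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @return A data.frame with columns `row`, `col`, and `cell`
#'   (`(row-1)*n_cols + col`, NA when outside).
#' @export
cell_of <- function(grid, lon, lat) {
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1L) * grid$n_cols + col))
}

grid_extent <- function(grid) {
  c(lon_min = grid$origin_lon,
    lon_max = grid$origin_lon + grid$n_cols * grid$cell_size,
    lat_min = grid$origin_lat - grid$n_rows * grid$cell_size,
    lat_max = grid$origin_lat)
}

#' Construct a raster layer
#'
#' A raster is a matrix of values on a [grid_spec()]; `NA` entries are nodata
#' and are excluded from every statistic the package computes.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`.
#' @return A `raster_layer` object (list with `grid` and `values`).
#' @export
raster_layer <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values dimensions do not match the grid")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_layer %s: %d valid cells, range [%.4g, %.4g]\n",
              format(x$grid), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Nodata mask of a raster
#'
#' @param x A [raster_layer()].
#' @return Logical matrix, TRUE where the cell carries no data.
#' @export
nodata_mask <- function(x) is.na(x$values)

#' Bundle co-registered predictor layers
#'
#' The standard stack holds the four predictors used throughout: temperature
#' seasonality (`bio4`, units: SD of monthly temperature x 100), mean
#' temperature of the warmest (`bio10`) and coldest (`bio11`) quarters
#' (degrees C), and fractional wetland cover (`wetland`, in `[0, 1]`).
#' Arbitrary extra named layers are allowed.
#'
#' @param ... Named [raster_layer()] objects sharing one grid.
#' @return An `env_stack` object.
#' @export
env_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !inherits(layers[[1]], "raster_layer"))
    layers <- layers[[1]]
  if (length(layers) == 0) stop("env_stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  for (l in layers) stopifnot(inherits(l, "raster_layer"))
  g <- layers[[1]]$grid
  for (l in layers[-1])
    if (!grid_equal(g, l$grid)) stop("all layers must share one grid_spec")
  if ("wetland" %in% names(layers)) {
    w <- layers$wetland$values
    if (any(w < -1e-9 | w > 1 + 1e-9, na.rm = TRUE))
      stop("wetland values must lie in [0, 1]")
  }
  if (all(c("bio10", "bio11") %in% names(layers))) {
    d <- layers$bio10$values - layers$bio11$values
    if (any(d < -1e-9, na.rm = TRUE))
      stop("bio10 must be >= bio11 wherever both are valid")
  }
  structure(list(layers = layers, grid = g), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack %s with layers: %s\n", format(x$grid),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract predictor values at point locations
#'
#' @param env An [env_stack()].
#' @param lon,lat Coordinates.
#' @param layers Layer names to extract (default all).
#' @return Numeric matrix, one row per point, one column per layer; NA where a
#'   point falls outside the grid or on nodata.
#' @export
env_values_at <- function(env, lon, lat, layers = names(env$layers)) {
  idx <- cell_of(env$grid, lon, lat)
  out <- matrix(NA_real_, length(lon), length(layers),
                dimnames = list(NULL, layers))
  ok <- !is.na(idx$row)
  for (nm in layers) {
    v <- env$layers[[nm]]$values
    out[ok, nm] <- v[cbind(idx$row[ok], idx$col[ok])]
  }
  out
}

#' Per-cell suitability surface
#'
#' Wraps a raster of model output on the probability-like `[0, 1]` scale,
#' recording which backend (or the ensemble) produced it.
#'
#' @param raster A [raster_layer()] with valid values in `[0, 1]`.
#' @param provenance Label: a backend id or `"ensemble"` or `"truth"`.
#' @return A `suitability_surface`.
#' @export
suitability_surface <- function(raster, provenance = "unknown") {
  stopifnot(inherits(raster, "raster_layer"))
  v <- raster$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  structure(list(raster = raster, scale = "probability-like [0,1]",
                 provenance = provenance),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("suitability_surface [%s] ", x$provenance))
  print(x$raster)
  invisible(x)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange (the GeoTIFF fallback format). Rows are
#' written north to south, matching the in-memory layout.
#'
#' @param x A [raster_layer()].
#' @param path File path.
#' @param nodata Value standing in for NA on disk.
#' @return `read_ascii_grid()` returns a [raster_layer()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  g <- x$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_lon),
           sprintf("yllcorner %.10g", g$origin_lat - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- x$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(val(1)); nrows <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  if (!all(dim(m) == c(nrows, ncols))) stop("malformed ASCII grid body")
  m[m == nodata] <- NA_real_
  raster_layer(grid_spec(xll, yll + nrows * cs, cs, nrows, ncols), m)
}
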