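# Occurrence cleaning: precision filtering, one-record-per-cell spatial
# thinning, and latitudinal band assignment for spatially stratified
# cross-validation. Every transformation is appended to a provenance log.

#' Construct an occurrence set
#'
#' A data.frame of presence records (`species`, `lon`, `lat`, `precision_km`,
#' `source`) carrying a provenance log of applied filters. Record order is
#' stable under filtering.
#'
#' @param records data.frame with at least `lon` and `lat` (decimal degrees);
#'   missing `species`/`precision_km`/`source` columns are filled with
#'   defaults.
#' @param log List of prior provenance entries.
#' @return An `occurrence_set` (a data.frame subclass).
#' @export
occurrence_set <- function(records, log = list()) {
  records <- as.data.frame(records)
  if (!all(c("lon", "lat") %in% names(records)))
    stop("records need lon and lat columns")
  if (is.null(records$species)) records$species <- "unknown"
  if (is.null(records$precision_km)) records$precision_km <- 0
  if (is.null(records$source)) records$source <- "unknown"
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE) ||
      any(records$lat < -90 | records$lat > 90, na.rm = TRUE))
    stop("coordinates outside [-180,180] x [-90,90]")
  records <- records[, c("species", "lon", "lat", "precision_km", "source")]
  rownames(records) <- NULL
  structure(records, provenance = log,
            class = c("occurrence_set", "data.frame"))
}

#' Provenance log of an occurrence set
#'
#' @param x An [occurrence_set()].
#' @return List of log entries (step, parameters, record counts).
#' @export
provenance <- function(x) attr(x, "provenance")

log_step <- function(x, step, params, n_before, n_after) {
  log <- c(attr(x, "provenance"),
           list(list(step = step, params = params,
                     n_before = n_before, n_after = n_after)))
  attr(x, "provenance") <- log
  x
}

#' Filter records by coordinate precision
#'
#' Retains exactly the records with reported precision strictly below
#' `max_km` (a record at exactly the cutoff is dropped).
#'
#' @param records An [occurrence_set()].
#' @param max_km Positive cutoff in km; default 5.
#' @return Filtered [occurrence_set()] with updated provenance.
#' @export
filter_precision <- function(records, max_km = 5) {
  stopifnot(inherits(records, "occurrence_set"))
  if (max_km <= 0) stop("max_km must be > 0")
  if (any(records$precision_km < 0, na.rm = TRUE))
    stop("negative precision values")
  n0 <- nrow(records)
  keep <- records$precision_km < max_km
  out <- occurrence_set(records[keep, , drop = FALSE], provenance(records))
  log_step(out, "filter_precision", list(max_km = max_km), n0, nrow(out))
}

#' Thin occurrences to one record per grid cell
#'
#' On the thinning grid (10 arc-minutes in the reference workflow) each cell
#' retains at most one record, chosen uniformly at random with the given
#' seed. Re-thinning an already-thinned set is a no-op. Retained records are
#' returned in their original order with all fields untouched.
#'
#' @param records An [occurrence_set()].
#' @param thinning_grid A [grid_spec()] covering all records.
#' @param seed Integer seed for the within-cell choice.
#' @return Thinned [occurrence_set()].
#' @export
thin_to_grid <- function(records, thinning_grid, seed = 1) {
  stopifnot(inherits(records, "occurrence_set"),
            inherits(thinning_grid, "grid_spec"))
  n0 <- nrow(records)
  if (n0 == 0) {
    return(log_step(records, "thin_to_grid",
                    list(cell_size = thinning_grid$cell_size, seed = seed), 0, 0))
  }
  idx <- cell_of(thinning_grid, records$lon, records$lat)
  if (any(is.na(idx$cell)))
    stop(sum(is.na(idx$cell)), " record(s) outside the thinning grid extent")
  set.seed(seed)
  keep <- vapply(split(seq_len(n0), idx$cell), function(rows) {
    if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
  }, integer(1))
  keep <- sort(unname(keep))
  out <- occurrence_set(records[keep, , drop = FALSE], provenance(records))
  log_step(out, "thin_to_grid",
           list(cell_size = thinning_grid$cell_size, seed = seed), n0, nrow(out))
}

#' Assign records to latitudinal bands
#'
#' Partitions records into `k` contiguous latitude intervals, labeled 1..k
#' from south to north, for spatially stratified cross-validation. The
#' default `"quantile"` rule gives near-equal record counts per band
#' (guaranteeing non-degenerate folds); `"width"` slices the latitude extent
#' into equal-width intervals.
#'
#' @param records An [occurrence_set()].
#' @param k Number of bands (>= 2); default 5.
#' @param method `"quantile"` (equal counts) or `"width"` (equal intervals).
#' @return Integer vector of band labels with attributes `breaks` (the k-1
#'   interior latitude boundaries, for assigning other point sets to the same
#'   bands) and `method`.
#' @export
assign_latitudinal_bands <- function(records, k = 5,
                                     method = c("quantile", "width")) {
  method <- match.arg(method)
  stopifnot(inherits(records, "occurrence_set"))
  if (k < 2) stop("k must be >= 2")
  n <- nrow(records)
  if (n < k) stop("fewer records than bands")
  lat <- records$lat
  if (length(unique(lat)) < k) stop("need at least k distinct latitudes")
  if (method == "quantile") {
    ord <- order(lat)
    band <- integer(n)
    band[ord] <- floor((seq_len(n) - 1) * k / n) + 1L
    sorted <- lat[ord]
    cuts <- which(diff(floor((seq_len(n) - 1) * k / n)) > 0)
    breaks <- (sorted[cuts] + sorted[cuts + 1L]) / 2
  } else {
    breaks <- seq(min(lat), max(lat), length.out = k + 1L)[2:k]
    band <- findInterval(lat, breaks) + 1L
  }
  structure(as.integer(band), breaks = breaks, method = method)
}

# Assign arbitrary latitudes to previously computed band boundaries.
bands_from_breaks <- function(lat, breaks) {
  findInterval(lat, breaks) + 1L
}
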