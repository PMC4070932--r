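# Synthetic-landscape generators. These state the "world" the test suite runs
# against: WorldClim-style smooth temperature gradients, a patchy fractional
# wetland layer, museum-style occurrence records with georeferencing noise,
# classified water-body polygons, and blob-shaped native ranges.

# Gaussian smoothing of a matrix by separable row/column kernel matrices.
gauss_smooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  smat <- function(n) {
    k <- exp(-0.5 * (outer(seq_len(n), seq_len(n), "-") / sigma)^2)
    k / rowSums(k)
  }
  smat(nrow(z)) %*% z %*% t(smat(ncol(z)))
}

# Smoothed standard-normalized noise field.
noise_field <- function(n_rows, n_cols, sigma) {
  z <- gauss_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), sigma)
  (z - mean(z)) / sd(z)
}

#' Generate a synthetic environmental stack
#'
#' Temperature layers are linear latitudinal gradients plus spatially
#' correlated (Gaussian-smoothed) noise scaled by `roughness`; with
#' `roughness = 0` they are exact linear gradients. The wetland layer is
#' sparse and patchy: a thresholded smooth noise field, independent of
#' `roughness`, with most cells at 0 (wetland cover genuinely varies at a
#' finer spatial scale than interpolated climate, so it gets its own recipe).
#' `bio10 >= bio11` holds everywhere by construction.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed; the output is a pure function of
#'   `(grid, seed, roughness, lon_gradient)`.
#' @param roughness Non-negative noise scale (degrees C for the temperature
#'   layers, x100 units for bio4). Default 0.8.
#' @param lon_gradient East-west warming rate of bio10/bio11 in degrees C per
#'   degree longitude (default 0.4, cooler toward the west — the
#'   continentality/elevation structure of a west-coast domain). Set to 0 for
#'   a purely latitudinal temperature field.
#' @return An [env_stack()] with layers `bio4`, `bio10`, `bio11`, `wetland`.
#' @export
generate_environment <- function(grid, seed, roughness = 0.8,
                                 lon_gradient = 0.4) {
  stopifnot(inherits(grid, "grid_spec"))
  if (roughness < 0) stop("roughness must be >= 0")
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  lat <- matrix(grid_lat_centers(grid), nr, nc)       # varies by row only
  south <- grid$origin_lat - lat                      # 0 at north edge
  east <- matrix(grid_lon_centers(grid) - grid$origin_lon, nr, nc, byrow = TRUE)
  f10 <- noise_field(nr, nc, sigma = 3)
  f11 <- noise_field(nr, nc, sigma = 3)
  f4  <- noise_field(nr, nc, sigma = 3)
  fw1 <- noise_field(nr, nc, sigma = 2)
  fw2 <- noise_field(nr, nc, sigma = 0.7)

  bio10 <- 12.25 + 0.7 * south + lon_gradient * east + roughness * f10
  offset <- pmax(12 + 2.5 * roughness * f11, 0.5)     # keeps bio10 >= bio11
  bio11 <- bio10 - offset
  bio4 <- 9000 - 160 * south + 250 * roughness * f4

  zw <- 0.6 * fw1 + 0.4 * fw2
  q <- quantile(zw, 0.85)
  top <- quantile(zw, 0.995)
  wet <- pmin(pmax((zw - q) / (top - q), 0), 1)  # arg order keeps matrix dims

  env_stack(bio4 = raster_layer(grid, bio4),
            bio10 = raster_layer(grid, bio10),
            bio11 = raster_layer(grid, bio11),
            wetland = raster_layer(grid, wet))
}

#' Response-term descriptors for the synthetic truth
#'
#' Terms are combined additively on the logit scale, so after the inverse
#' logit: a `resp_unimodal` term gives a bell-shaped suitability response
#' peaking at `optimum` (term `-((x - optimum)/width)^2`); a `resp_sigmoid`
#' term, linear on the logit scale (`slope * (x - midpoint)`), gives a
#' sigmoid response; a `resp_saturating` term (`slope * min(x, plateau_onset)`)
#' rises and then plateaus beyond `plateau_onset`.
#'
#' @param optimum,width Peak location and spread of the unimodal term.
#' @param midpoint,slope Sigmoid inflection and logit-scale slope.
#' @param plateau_onset Predictor value where the saturating term flattens.
#' @return A `resp_term` object.
#' @export
resp_unimodal <- function(optimum, width) {
  stopifnot(width > 0)
  structure(list(shape = "unimodal", optimum = optimum, width = width),
            class = "resp_term")
}

#' @rdname resp_unimodal
#' @export
resp_sigmoid <- function(midpoint, slope) {
  structure(list(shape = "sigmoid", midpoint = midpoint, slope = slope),
            class = "resp_term")
}

#' @rdname resp_unimodal
#' @export
resp_saturating <- function(slope, plateau_onset) {
  structure(list(shape = "saturating", slope = slope,
                 plateau_onset = plateau_onset), class = "resp_term")
}

#' Evaluate one response term
#'
#' @param term A `resp_term`.
#' @param x Numeric predictor values.
#' @return Logit-scale contribution, same shape as `x`.
#' @export
resp_eval <- function(term, x) {
  switch(term$shape,
    unimodal = -((x - term$optimum) / term$width)^2,
    sigmoid = term$slope * (x - term$midpoint),
    saturating = term$slope * pmin(x, term$plateau_onset),
    stop("unknown response shape: ", term$shape))
}

#' Parameters of the synthetic true suitability
#'
#' @param intercept Logit-scale intercept.
#' @param terms Named list of [resp_unimodal()]-family terms; names must match
#'   layers of the stack the truth is evaluated on.
#' @return A `suitability_params` object.
#' @export
suitability_params <- function(intercept = 0, terms = list()) {
  for (t in terms) stopifnot(inherits(t, "resp_term"))
  structure(list(intercept = intercept, terms = terms),
            class = "suitability_params")
}

#' Default synthetic truth: warm-quarter optimum at 26 C, saturating wetland
#'
#' The stated benchmark world: a unimodal bio10 response with optimum 26
#' (degrees C) and width 3, and a saturating wetland response rising with
#' slope 14 (logit units per unit cover) to a plateau at 0.3 cover. The
#' intercept of -4 makes wetland-free cells essentially unsuitable even at
#' the thermal optimum (suitability ~0.02) — the species is a wetland
#' obligate, and the resulting suitability field is fragmented the way a
#' fine-scale wetland predictor fragments real surfaces. bio4 and bio11
#' carry no causal effect and act as correlated nuisance predictors.
#'
#' @return A [suitability_params()] object.
#' @export
default_truth_params <- function() {
  suitability_params(
    intercept = -4,
    terms = list(bio10 = resp_unimodal(optimum = 26, width = 3),
                 wetland = resp_saturating(slope = 14, plateau_onset = 0.3)))
}

#' Evaluate the synthetic true suitability over a stack
#'
#' Cellwise inverse logit of the summed response terms plus intercept;
#' guaranteed in `[0, 1]`.
#'
#' @param env An [env_stack()].
#' @param params A [suitability_params()].
#' @return A [suitability_surface()] with provenance `"truth"`.
#' @export
true_suitability <- function(env, params) {
  stopifnot(inherits(env, "env_stack"), inherits(params, "suitability_params"))
  missing <- setdiff(names(params$terms), names(env$layers))
  if (length(missing))
    stop("layer(s) missing from stack: ", paste(missing, collapse = ", "))
  eta <- matrix(params$intercept, env$grid$n_rows, env$grid$n_cols)
  for (nm in names(params$terms))
    eta <- eta + resp_eval(params$terms[[nm]], env$layers[[nm]]$values)
  suitability_surface(raster_layer(env$grid, stats::plogis(eta)), "truth")
}

#' Sample museum-style occurrence records from a truth surface
#'
#' Cells inside `native_window` are sampled with probability proportional to
#' true suitability (uniform collecting effort is assumed; opportunistic
#' museum sampling has no stated model). Each record is placed uniformly
#' within its cell, then displaced by a half-normal distance (scale
#' `precision_sd_km`, random bearing) converted to degrees at the record's
#' latitude, emulating georeferencing error. Each record carries a reported
#' `precision_km` drawn lognormally (median 4 km) so the 5-km precision
#' filter is exercised from both sides; the reported precision and the actual
#' displacement are independent draws, as museum metadata only approximates
#' true error.
#'
#' @param truth A [suitability_surface()].
#' @param native_window `c(lon_min, lon_max, lat_min, lat_max)` rectangle.
#' @param n Number of records.
#' @param precision_sd_km Half-normal scale of the coordinate displacement.
#' @param seed Integer seed.
#' @param species_id Species label for the records.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(truth, native_window, n, precision_sd_km = 2,
                               seed = 1, species_id = "synthetic_sp") {
  stopifnot(inherits(truth, "suitability_surface"), n >= 1)
  grid <- truth$raster$grid
  ctr <- grid_centers(grid)
  inside <- ctr$lon >= native_window[1] & ctr$lon <= native_window[2] &
    ctr$lat >= native_window[3] & ctr$lat <= native_window[4] &
    !is.na(truth$raster$values)
  if (!any(inside)) stop("native_window does not intersect the grid")
  w <- truth$raster$values[inside]
  if (sum(w) <= 0) stop("zero total suitability inside native_window")
  idx <- which(inside)
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n, replace = TRUE, prob = w)]
  half <- grid$cell_size / 2
  lon <- ctr$lon[pick] + runif(n, -half, half)
  lat <- ctr$lat[pick] + runif(n, -half, half)
  if (precision_sd_km > 0) {
    d_km <- abs(rnorm(n, 0, precision_sd_km))
    theta <- runif(n, 0, 2 * pi)
    lat_j <- lat + d_km * sin(theta) / 111.32
    lon_j <- lon + d_km * cos(theta) / (111.32 * cos(lat * pi / 180))
  } else {
    lat_j <- lat; lon_j <- lon
  }
  ext <- grid_extent(grid)
  eps <- grid$cell_size * 1e-6
  lon_j <- pmin(pmax(lon_j, ext["lon_min"] + eps), ext["lon_max"] - eps)
  lat_j <- pmin(pmax(lat_j, ext["lat_min"] + eps), ext["lat_max"] - eps)
  precision_km <- exp(rnorm(n, log(4), 0.55))
  occurrence_set(data.frame(
    species = species_id, lon = as.numeric(lon_j), lat = as.numeric(lat_j),
    precision_km = precision_km, source = "synthetic",
    stringsAsFactors = FALSE))
}

#' Generate classified water-body polygons
#'
#' Emulates a hydrography dataset: rectangles and thin stream rectangles with
#' class labels covering both the kept classes (perennial/artificial streams,
#' lakes/ponds, reservoirs, swamps/marshes) and the dropped ones (playas,
#' saline lakes, estuaries, peat bogs, intermittent streams). At least one
#' polygon of every class is produced, and one lake/pond is sized to exactly
#' one grid cell. The attribute `"area_budget"` records the total intended
#' polygon area (degree^2) for auditing.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @return A `water_body_set`: list of [water_body()] objects with attributes
#'   `area_budget` and `unit_cell` (row/col of the one-cell lake).
#' @export
generate_water_bodies <- function(grid, seed) {
  set.seed(seed)
  ext <- grid_extent(grid)
  cs <- grid$cell_size
  span_lon <- ext["lon_max"] - ext["lon_min"]
  span_lat <- ext["lat_max"] - ext["lat_min"]
  rand_rect <- function(w, h) {
    x0 <- runif(1, ext["lon_min"], ext["lon_max"] - w)
    y0 <- runif(1, ext["lat_min"], ext["lat_max"] - h)
    rect_ring(x0, x0 + w, y0, y0 + h)
  }
  polys <- list()
  budget <- 0
  add <- function(class_label, ring) {
    polys[[length(polys) + 1L]] <<- water_body(class_label, ring)
    budget <<- budget + poly_area(ring)
  }
  # one lake exactly covering one cell (fraction-1.0 guarantee)
  ur <- sample.int(grid$n_rows, 1); uc <- sample.int(grid$n_cols, 1)
  x0 <- grid$origin_lon + (uc - 1) * cs
  y1 <- grid$origin_lat - (ur - 1) * cs
  add("lake_pond", rect_ring(x0, x0 + cs, y1 - cs, y1))
  blocky <- c("lake_pond", "reservoir", "swamp_marsh",
              "playa", "saline_lake", "estuary", "peat_bog")
  for (cl in blocky) {
    for (i in seq_len(1 + stats::rbinom(1, 2, 0.5))) {
      w <- runif(1, 1.5, 6) * cs; h <- runif(1, 1.5, 6) * cs
      add(cl, rand_rect(w, h))
    }
  }
  streams <- c("perennial_stream", "artificial_stream", "intermittent")
  for (cl in streams) {
    for (i in seq_len(1 + stats::rbinom(1, 1, 0.5))) {
      horiz <- runif(1) < 0.5
      len <- runif(1, 0.2, 0.6) * (if (horiz) span_lon else span_lat)
      wid <- 0.15 * cs
      ring <- if (horiz) rand_rect(len, wid) else rand_rect(wid, len)
      add(cl, ring)
    }
  }
  structure(polys, class = "water_body_set",
            area_budget = budget, unit_cell = c(row = ur, col = uc))
}

#' Generate synthetic native-species range maps
#'
#' Each range is a connected union of 2-4 overlapping axis-aligned rectangles
#' (each rectangle is anchored inside its predecessor, so the union is
#' connected) varying in size and placement, hence in overlap with high-truth
#' areas.
#'
#' @param grid A [grid_spec()].
#' @param n_species Number of ranges.
#' @param seed Integer seed.
#' @return List of [range_map()] objects.
#' @export
generate_range_maps <- function(grid, n_species, seed) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  ext <- grid_extent(grid)
  cs <- grid$cell_size
  span_lon <- ext["lon_max"] - ext["lon_min"]
  span_lat <- ext["lat_max"] - ext["lat_min"]
  out <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    n_rect <- sample(2:4, 1)
    rects <- vector("list", n_rect)
    w <- runif(1, 0.1, 0.35) * span_lon
    h <- runif(1, 0.1, 0.35) * span_lat
    w <- max(w, 2 * cs); h <- max(h, 2 * cs)
    x0 <- runif(1, ext["lon_min"], ext["lon_max"] - w)
    y0 <- runif(1, ext["lat_min"], ext["lat_max"] - h)
    rects[[1]] <- c(x0 = x0, x1 = x0 + w, y0 = y0, y1 = y0 + h)
    for (j in seq_len(n_rect - 1L)) {
      prev <- rects[[j]]
      w2 <- max(runif(1, 0.05, 0.25) * span_lon, 2 * cs)
      h2 <- max(runif(1, 0.05, 0.25) * span_lat, 2 * cs)
      ax <- runif(1, prev["x0"], prev["x1"])   # anchor inside predecessor
      ay <- runif(1, prev["y0"], prev["y1"])
      x0 <- min(max(ax - w2 / 2, ext["lon_min"]), ext["lon_max"] - w2)
      y0 <- min(max(ay - h2 / 2, ext["lat_min"]), ext["lat_max"] - h2)
      rects[[j + 1L]] <- c(x0 = x0, x1 = x0 + w2, y0 = y0, y1 = y0 + h2)
    }
    out[[s]] <- range_map(sprintf("native_%02d", s), rects = rects)
  }
  out
}

#' Native-species range map
#'
#' A union of axis-aligned rectangles (lon/lat degrees), a set of general
#' polygon rings, or a pre-rasterized binary mask on the analysis grid.
#'
#' @param species_id Species label.
#' @param rects List of named vectors `c(x0, x1, y0, y1)`.
#' @param mask Logical matrix on the analysis grid.
#' @param rings List of two-column vertex matrices (general polygons, e.g.
#'   read from GeoJSON).
#' @return A `range_map` object.
#' @export
range_map <- function(species_id, rects = NULL, mask = NULL, rings = NULL) {
  if (is.null(rects) && is.null(mask) && is.null(rings))
    stop("range_map needs rects, rings, or a mask")
  structure(list(species_id = species_id, rects = rects, mask = mask,
                 rings = rings),
            class = "range_map")
}

#' Rasterize a range map by cell-center containment
#'
#' A cell belongs to the range when its center lies inside any rectangle
#' (closed bounds). Pre-rasterized ranges are returned as-is (dimensions
#' checked).
#'
#' @param range A [range_map()].
#' @param grid A [grid_spec()].
#' @return Logical matrix `n_rows x n_cols`.
#' @export
rasterize_range <- function(range, grid) {
  if (!is.null(range$mask)) {
    if (!all(dim(range$mask) == c(grid$n_rows, grid$n_cols)))
      stop("range mask does not match the grid")
    return(range$mask)
  }
  ctr <- grid_centers(grid)
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!is.null(range$rects)) {
    for (r in range$rects) {
      m <- m | (ctr$lon >= r["x0"] & ctr$lon <= r["x1"] &
                ctr$lat >= r["y0"] & ctr$lat <= r["y1"])
    }
  }
  if (!is.null(range$rings)) {
    for (ring in range$rings) {
      m <- m | matrix(point_in_ring(as.vector(ctr$lon), as.vector(ctr$lat), ring),
                      grid$n_rows, grid$n_cols)
    }
  }
  if (!any(m)) stop("range rasterizes to an empty mask")
  m
}
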