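# Independent oracles and tiny fixture builders. Oracles deliberately share
# no code with the implementation paths they check.

# All-pairs AUC: count presence > absence pairs, ties worth 1/2.
auc_pairs_oracle <- function(pres, abs) {
  wins <- 0
  for (p in pres) for (a in abs)
    wins <- wins + (p > a) + 0.5 * (p == a)
  wins / (length(pres) * length(abs))
}

# Exhaustive Max-SSS scan over unique-score candidates, smallest-t tie-break.
sss_scan_oracle <- function(pres, abs) {
  best <- NULL
  for (t in sort(unique(c(pres, abs)))) {
    se <- sum(pres >= t) / length(pres)
    sp <- sum(abs < t) / length(abs)
    if (is.null(best) || se + sp > best$sss + 1e-12)
      best <- list(threshold = t, se = se, sp = sp, sss = se + sp)
  }
  best
}

# Queue-based breadth-first search flood fill on a logical matrix.
bfs_oracle <- function(suit, seed_cells, neighbors) {
  nr <- nrow(suit); nc <- ncol(suit)
  reach <- matrix(FALSE, nr, nc)
  queue <- seed_cells[suit[seed_cells]]
  reach[queue] <- TRUE
  offs <- if (neighbors == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  }
  queue <- c(queue, integer(sum(suit)))   # preallocate; head/tail pointers
  head <- 1L; tail <- sum(reach)
  while (head <= tail) {
    cell <- queue[head]; head <- head + 1L
    r <- (cell - 1L) %% nr + 1L
    cc <- (cell - 1L) %/% nr + 1L
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          suit[r2, c2] && !reach[r2, c2]) {
        reach[r2, c2] <- TRUE
        tail <- tail + 1L
        queue[tail] <- (c2 - 1L) * nr + r2
      }
    }
  }
  reach
}

# Convex-hull distance oracle: inside test by cross-product signs, boundary
# distance by point-segment minimisation, written independently of
# dist_to_ring().
hull_dist_oracle <- function(px, py, hull) {
  n <- nrow(hull)
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[k %% n + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (cr >= -1e-12)
  }
  dmin <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[k %% n + 1, ]
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    tt <- ((px - a[1]) * vx + (py - a[2]) * vy) / (vx^2 + vy^2)
    tt <- pmin(1, pmax(0, tt))
    dmin <- pmin(dmin, sqrt((px - a[1] - tt * vx)^2 + (py - a[2] - tt * vy)^2))
  }
  ifelse(inside, 0, dmin)
}

# Fixture builders -----------------------------------------------------------

mini_grid <- function(n = 10, cell = 1, lon0 = 0, lat0 = n * cell) {
  grid_spec(lon0, lat0, cell, n, n)
}

const_raster <- function(grid, value) {
  raster_layer(grid, matrix(value, grid$n_rows, grid$n_cols))
}

# Small 4-layer stack with hand-set fields (bio10 varies by row, bio4 by
# column, wetland in a block).
mini_env <- function(n = 10) {
  g <- mini_grid(n)
  bio10 <- matrix(rep(seq(20, 30, length.out = n), n), n, n)   # varies by row
  bio4 <- matrix(rep(seq(4000, 8000, length.out = n), each = n), n, n)
  wet <- matrix(0, n, n); wet[3:5, 3:5] <- 0.6
  env_stack(bio4 = raster_layer(g, bio4),
            bio10 = raster_layer(g, bio10),
            bio11 = raster_layer(g, bio10 - 12),
            wetland = raster_layer(g, wet))
}

make_occ <- function(lon, lat, precision_km = 0, species = "sp") {
  n <- length(lon)
  occurrence_set(data.frame(species = rep_len(species, n), lon = lon,
                            lat = lat,
                            precision_km = rep_len(precision_km, n),
                            source = rep_len("test", n)))
}

# plain data.frame comparison view (drops the provenance log)
occ_df <- function(x) {
  d <- as.data.frame(x)
  attr(d, "provenance") <- NULL
  class(d) <- "data.frame"
  d
}

# The committed benchmark world (seed 11): 100x100 grid of 0.25-degree
# cells, default truth, 300 thinned presences, 300 pseudo-absences at
# >= 2 degrees. Built once per test run and cached.
benchmark_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- grid_spec(-105, 45, 0.25, 100, 100)
    env <- generate_environment(g, seed = 11)
    truth <- true_suitability(env, default_truth_params())
    occ <- sample_occurrences(truth, c(-100, -85, 25, 40), 2000,
                              precision_sd_km = 2, seed = 12)
    occ <- filter_precision(occ, 5)
    occ <- thin_to_grid(occ, grid_spec(-105, 45, 0.5, 50, 50), seed = 13)
    set.seed(14)
    occ <- occurrence_set(occ[sort(sample(nrow(occ), 300)), ])
    acc <- accessible_area(occ, 4, g)
    pa <- sample_pseudo_absences(occ, acc, 2, n = 300, seed = 15, env = env)
    cache <<- list(grid = g, env = env, truth = truth, presences = occ,
                   accessible = acc, absences = pa)
    cache
  }
})
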