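test_that("generate_environment is deterministic and honors the noise-free limit", {
  g <- grid_spec(-105, 45, 0.25, 30, 30)
  a <- generate_environment(g, seed = 7)
  b <- generate_environment(g, seed = 7)
  expect_identical(a, b)                    # bitwise determinism
  c <- generate_environment(g, seed = 8)
  expect_false(identical(a$layers$bio10$values, c$layers$bio10$values))

  # roughness 0 + no east-west term: exact linear latitudinal gradients
  e0 <- generate_environment(g, seed = 1, roughness = 0, lon_gradient = 0)
  for (nm in c("bio4", "bio10", "bio11")) {
    v <- e0$layers[[nm]]$values
    expect_true(all(v == v[, 1]))                      # no lon dependence
    expect_equal(max(abs(diff(diff(v[, 1])))), 0)      # linear in lat
  }
  expect_true(all(a$layers$bio10$values >= a$layers$bio11$values))
  w <- a$layers$wetland$values
  expect_true(all(w >= 0 & w <= 1))
  expect_gt(mean(w == 0), 0.5)              # sparse and patchy
})

test_that("the analysis resolution of 2.5 arc-minutes is supported", {
  g <- grid_spec(-100, 40, 2.5 / 60, 24, 24)
  env <- generate_environment(g, seed = 3)
  expect_equal(env$grid$cell_size, 2.5 / 60)
  expect_equal(dim(env$layers$bio10$values), c(24, 24))
})

test_that("true_suitability matches a cellwise scalar oracle and is bounded", {
  env <- mini_env(8)
  # trivial: no terms, intercept 0 -> uniform 0.5
  flat <- true_suitability(env, suitability_params(intercept = 0))
  expect_true(all(flat$raster$values == 0.5))

  params <- suitability_params(
    intercept = -1.5,
    terms = list(bio10 = resp_unimodal(26, 3),
                 wetland = resp_saturating(8, 0.3),
                 bio4 = resp_sigmoid(6000, -0.001)))
  s <- true_suitability(env, params)
  # independent scalar evaluator, cell by cell
  for (r in seq_len(8)) for (cc in seq_len(8)) {
    b10 <- env$layers$bio10$values[r, cc]
    w <- env$layers$wetland$values[r, cc]
    b4 <- env$layers$bio4$values[r, cc]
    eta <- -1.5 - ((b10 - 26) / 3)^2 + 8 * min(w, 0.3) - 0.001 * (b4 - 6000)
    expect_equal(s$raster$values[r, cc], 1 / (1 + exp(-eta)), tolerance = 1e-12)
  }
  # unimodal term maximized exactly at the optimum
  x <- seq(20, 32, by = 0.5)
  term <- resp_eval(resp_unimodal(26, 3), x)
  expect_equal(x[which.max(term)], 26)

  # bounds hold for random parameter draws
  for (i in 1:20) {
    set.seed(i)
    p <- suitability_params(rnorm(1, 0, 3),
      list(bio10 = resp_unimodal(runif(1, 20, 30), runif(1, 1, 6)),
           wetland = resp_saturating(runif(1, 0, 20), runif(1, 0.05, 0.8))))
    v <- true_suitability(env, p)$raster$values
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(
    true_suitability(env, suitability_params(0, list(nope = resp_sigmoid(0, 1)))),
    "missing")
})

test_that("occurrence sampling follows the truth distribution", {
  g <- mini_grid(10)
  # degenerate truth: single suitable cell catches every record
  m <- matrix(0, 10, 10); m[4, 7] <- 1
  tr <- suitability_surface(raster_layer(g, m), "truth")
  occ <- sample_occurrences(tr, c(0, 10, 0, 10), 50, precision_sd_km = 0, seed = 2)
  idx <- cell_of(g, occ$lon, occ$lat)
  expect_true(all(idx$row == 4 & idx$col == 7))

  # uniform truth: chi-square goodness of fit against uniform cell counts
  tru <- suitability_surface(const_raster(g, 0.5), "truth")
  occ2 <- sample_occurrences(tru, c(0, 10, 0, 10), 2000, precision_sd_km = 0, seed = 3)
  cells <- cell_of(g, occ2$lon, occ2$lat)$cell
  counts <- tabulate(cells, nbins = 100)
  p <- stats::chisq.test(counts, p = rep(1 / 100, 100))$p.value
  expect_gt(p, 1e-3)

  # determinism + precision straddles the 5-km filter
  occ3 <- sample_occurrences(tru, c(0, 10, 0, 10), 400, seed = 4)
  occ4 <- sample_occurrences(tru, c(0, 10, 0, 10), 400, seed = 4)
  expect_identical(occ_df(occ3), occ_df(occ4))
  expect_gt(mean(occ3$precision_km < 5), 0.2)
  expect_gt(mean(occ3$precision_km >= 5), 0.1)

  expect_error(sample_occurrences(tr, c(50, 60, 50, 60), 10), "intersect")
  zero <- suitability_surface(const_raster(g, 0), "truth")
  expect_error(sample_occurrences(zero, c(0, 10, 0, 10), 10), "zero total")
})

test_that("water-body generator covers the class vocabulary with audited areas", {
  g <- mini_grid(20, cell = 0.5)
  wbs <- generate_water_bodies(g, seed = 5)
  expect_setequal(unique(vapply(wbs, function(w) w$class_label, character(1))),
                  water_classes())
  # shoelace oracle: polygon areas sum to the generator's area budget
  total <- sum(vapply(wbs, function(w) {
    ring <- w$ring; n <- nrow(ring); j <- c(n, 1:(n - 1))
    abs(sum(ring[j, 1] * ring[, 2] - ring[, 1] * ring[j, 2])) / 2
  }, numeric(1)))
  expect_equal(total, attr(wbs, "area_budget"), tolerance = 0.01)
  # the unit-cell lake rasterizes to fraction exactly 1
  uc <- attr(wbs, "unit_cell")
  wet <- build_wetland_raster(wbs, g, keep_classes = "lake_pond")
  expect_equal(wet$values[uc["row"], uc["col"]], 1)
  expect_identical(wbs, generate_water_bodies(g, seed = 5))
})

test_that("range maps are connected, non-empty, and rasterize consistently", {
  g <- mini_grid(20, cell = 0.5)
  ranges <- generate_range_maps(g, 5, seed = 9)
  expect_length(ranges, 5)
  for (rm in ranges) {
    mask <- rasterize_range(rm, g)
    expect_gt(sum(mask), 0)
    # connectedness: one 8-connected component
    seeds <- which(mask)[1]
    reach <- bfs_oracle(mask, seeds, 8)
    expect_identical(reach, mask)
  }
  # geometric oracle: single-rectangle range area within one cell per boundary cell
  for (i in 1:10) {
    set.seed(i)
    w <- runif(1, 1, 6); h <- runif(1, 1, 6)
    x0 <- runif(1, 0, 10 - w); y0 <- runif(1, 0, 10 - h)
    rm <- range_map("r", rects = list(c(x0 = x0, x1 = x0 + w, y0 = y0, y1 = y0 + h)))
    mask <- rasterize_range(rm, g)
    cell_area <- g$cell_size^2
    n_boundary <- 2 * (ceiling(w / g$cell_size) + ceiling(h / g$cell_size)) + 4
    expect_lt(abs(sum(mask) * cell_area - w * h), n_boundary * cell_area)
  }
  # whole-grid range: overlap proportion equals the global suitable fraction
  whole <- range_map("all", rects = list(c(x0 = 0, x1 = 10, y0 = 0, y1 = 10)))
  vals <- matrix(runif(400), 20, 20)
  s <- suitability_surface(raster_layer(g, vals), "x")
  rep <- range_overlap(s, 0.5, whole)
  expect_equal(rep$proportion_suitable, mean(vals >= 0.5))
})
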