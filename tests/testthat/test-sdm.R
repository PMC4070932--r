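test_that("accessible area follows hull, buffer, and point fallback", {
  g <- mini_grid(20, cell = 0.5)
  # square of presences, buffer 0 -> hull interior cells only
  occ <- make_occ(c(2, 2, 8, 8, 5), c(2, 8, 2, 8, 5))
  acc0 <- accessible_area(occ, 0, g)
  ctr <- grid_centers(g)
  inside <- ctr$lon >= 2 & ctr$lon <= 8 & ctr$lat >= 2 & ctr$lat <= 8
  expect_identical(acc0$values > 0, inside)
  # single presence -> degree-metric disc
  one <- make_occ(5, 5)
  acc1 <- accessible_area(one, 2, g)
  expect_identical(acc1$values > 0,
                   sqrt((ctr$lon - 5)^2 + (ctr$lat - 5)^2) <= 2)
  # exhaustive distance-to-hull oracle on a random presence cloud
  set.seed(11)
  occ2 <- make_occ(runif(15, 2, 8), runif(15, 2, 8))
  acc2 <- accessible_area(occ2, 1.2, g)
  hull_pts <- cbind(occ2$lon, occ2$lat)
  hull <- hull_pts[rev(grDevices::chull(hull_pts)), ]  # counter-clockwise
  d <- hull_dist_oracle(as.vector(ctr$lon), as.vector(ctr$lat), hull)
  expect_identical(as.vector(acc2$values > 0), d <= 1.2)
})

test_that("pseudo-absences respect distance, area, and count constraints", {
  w <- benchmark_world()
  for (seed in 1:20) {
    pa <- sample_pseudo_absences(w$presences, w$accessible, 2,
                                 n = 150, seed = seed, env = w$env)
    expect_equal(nrow(pa), 150)
    dmin <- min(sqrt(outer(pa$lon, w$presences$lon, "-")^2 +
                     outer(pa$lat, w$presences$lat, "-")^2))
    expect_gte(dmin, 2)
    idx <- cell_of(w$grid, pa$lon, pa$lat)
    expect_true(all(w$accessible$values[cbind(idx$row, idx$col)] > 0))
    expect_false(any(duplicated(idx$cell)))        # one point per cell
  }
  # brute-force all-pairs admissible mask on a small case
  g <- mini_grid(15)
  occ <- make_occ(c(4, 8), c(6, 9))
  acc <- accessible_area(occ, 6, g)
  got <- invrisk:::admissible_cells(occ, acc, 3)
  ctr <- grid_centers(g)
  oracle <- acc$values > 0
  for (i in seq_len(nrow(occ)))
    oracle <- oracle &
      sqrt((ctr$lon - occ$lon[i])^2 + (ctr$lat - occ$lat[i])^2) >= 3
  expect_identical(got, oracle)
  expect_error(
    sample_pseudo_absences(occ, acc, 3, n = 10000, seed = 1),
    "deficit")
})

test_that("all backends separate a threshold problem perfectly", {
  env <- mini_env(10)
  ctr <- grid_centers(env$grid)
  b10 <- env$layers$bio10$values
  pres_cells <- which(b10 > 26)
  abs_cells <- which(b10 <= 26)
  occ <- make_occ(ctr$lon[pres_cells], ctr$lat[pres_cells])
  ab <- data.frame(lon = ctr$lon[abs_cells], lat = ctr$lat[abs_cells])
  for (b in c("maxent_like", "boosted_trees", "random_forest")) {
    m <- fit_model(b, occ, ab, env, seed = 1)
    sp <- predict_points(m, occ$lon, occ$lat, env)
    sa <- predict_points(m, ab$lon, ab$lat, env)
    expect_equal(auc(sp, sa), 1.0, tolerance = 1e-9)
    expect_true(all(c(sp, sa) >= 0 & c(sp, sa) <= 1))
  }
})

test_that("maxent_like is invariant to row permutation; trees are seed-deterministic", {
  w <- benchmark_world()
  occ <- occurrence_set(w$presences[1:80, ])
  ab <- w$absences[1:80, ]
  m1 <- fit_model("maxent_like", occ, ab, w$env, seed = 1)
  set.seed(99)
  perm_p <- sample(nrow(occ)); perm_a <- sample(nrow(ab))
  m2 <- fit_model("maxent_like", occurrence_set(occ[perm_p, ]),
                  ab[perm_a, ], w$env, seed = 1)
  pts <- data.frame(lon = runif(50, -104, -81), lat = runif(50, 21, 44))
  expect_equal(predict_points(m1, pts$lon, pts$lat, w$env),
               predict_points(m2, pts$lon, pts$lat, w$env), tolerance = 1e-10)
  for (b in c("boosted_trees", "random_forest")) {
    f1 <- fit_model(b, occ, ab, w$env, seed = 7)
    f2 <- fit_model(b, occ, ab, w$env, seed = 7)
    expect_identical(predict_points(f1, pts$lon, pts$lat, w$env),
                     predict_points(f2, pts$lon, pts$lat, w$env))
  }
})

test_that("clamping freezes predictions outside the training range", {
  w <- benchmark_world()
  occ <- occurrence_set(w$presences[1:100, ])
  ab <- w$absences[1:100, ]
  for (b in c("maxent_like", "boosted_trees", "random_forest")) {
    m <- fit_model(b, occ, ab, w$env, seed = 2)
    # in-range: clamped and unclamped agree
    X <- invrisk:::env_values_at(w$env, occ$lon[1:20], occ$lat[1:20])
    expect_equal(invrisk:::predict_matrix(m, X, clamp = TRUE),
                 invrisk:::predict_matrix(m, X, clamp = FALSE))
    # beyond the training max of bio10: equal to the at-max prediction
    Xhi <- X; Xhi[, "bio10"] <- m$ranges["max", "bio10"] + 5
    Xmax <- X; Xmax[, "bio10"] <- m$ranges["max", "bio10"]
    expect_equal(invrisk:::predict_matrix(m, Xhi, clamp = TRUE),
                 invrisk:::predict_matrix(m, Xmax, clamp = TRUE))
    # constant along a ray leaving the training hypercube in one coordinate
    ray <- lapply(c(0, 3, 9), function(d) {
      Xr <- X[1, , drop = FALSE]; Xr[, "bio4"] <- m$ranges["max", "bio4"] + d
      invrisk:::predict_matrix(m, Xr, clamp = TRUE)
    })
    expect_equal(ray[[1]], ray[[2]])
    expect_equal(ray[[1]], ray[[3]])
  }
})

test_that("response curves are flat for pure-noise predictors", {
  g <- mini_grid(30, cell = 1 / 3)
  set.seed(21)
  sig <- matrix(rep(seq(18, 32, length.out = 30), 30), 30, 30)
  noise <- matrix(rnorm(900, 6000, 600), 30, 30)
  env <- env_stack(bio10 = raster_layer(g, sig),
                   bio4 = raster_layer(g, noise))
  truth <- true_suitability(env, suitability_params(
    intercept = 1, terms = list(bio10 = resp_unimodal(26, 2.5))))
  occ <- sample_occurrences(truth, c(0, 10, 0, 10), 250,
                            precision_sd_km = 0, seed = 22)
  set.seed(23)
  ab <- data.frame(lon = runif(250, 0, 10), lat = runif(250, 0, 10))
  # lambda.1se: the sparser fit appropriate for a pure noise screen
  m <- fit_model("maxent_like", occ, ab, env,
                 hyperparams = list(s = "lambda.1se"), seed = 3)
  flat <- response_curve(m, env, "bio4", 50)
  bumpy <- response_curve(m, env, "bio10", 50)
  expect_lt(diff(range(flat$prediction)), 0.1)
  expect_gt(diff(range(bumpy$prediction)), 0.3)
  expect_error(response_curve(m, env, "wetland", 50), "not a model predictor")
  expect_error(response_curve(m, env, "bio10", 1), "n_points")
})

test_that("degenerate predictors are dropped with a warning", {
  env <- mini_env(10)
  env$layers$bio4 <- const_raster(env$grid, 5000)
  ctr <- grid_centers(env$grid)
  occ <- make_occ(ctr$lon[1:30], ctr$lat[1:30])
  ab <- data.frame(lon = as.vector(ctr$lon)[60:90], lat = as.vector(ctr$lat)[60:90])
  expect_warning(m <- fit_model("random_forest", occ, ab, env, seed = 1),
                 "degenerate")
  expect_false("bio4" %in% m$predictors)
})
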