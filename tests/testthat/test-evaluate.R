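test_that("auc matches hand-computed and oracle values", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)   # identical multisets
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)  # 3 of 4 pairs
  expect_equal(auc(0.5, 0.5), 0.5)                   # tie counts half
  for (i in 1:200) {
    set.seed(i)
    pres <- sample(seq(0, 1, 0.1), sample(1:8, 1), replace = TRUE)
    abs <- sample(seq(0, 1, 0.1), sample(1:8, 1), replace = TRUE)
    expect_equal(auc(pres, abs), auc_pairs_oracle(pres, abs), tolerance = 1e-12)
  }
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("max SSS threshold equals the exhaustive scan", {
  got <- max_sss_threshold(c(0.8, 0.6, 0.4), c(0.5, 0.3, 0.1))
  expect_equal(got$threshold, 0.4)
  expect_equal(got$sensitivity_at, 1)
  expect_equal(got$specificity_at, 2 / 3)
  expect_equal(got$sss, 5 / 3)
  # separable classes: Se = Sp = 1, t at the smallest presence score
  sep <- max_sss_threshold(c(0.7, 0.9), c(0.1, 0.3))
  expect_equal(sep$sss, 2)
  expect_equal(sep$threshold, 0.7)
  # identical distributions: SSS 1 everywhere, smallest candidate returned
  same <- max_sss_threshold(c(0.2, 0.5), c(0.2, 0.5))
  expect_equal(same$sss, 1)
  expect_equal(same$threshold, 0.2)
  for (i in 1:200) {
    set.seed(1000 + i)
    pres <- round(runif(sample(2:30, 1)), 2)
    abs <- round(runif(sample(2:30, 1)), 2)
    got <- max_sss_threshold(pres, abs)
    want <- sss_scan_oracle(pres, abs)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sss, want$sss, tolerance = 1e-12)
  }
})

test_that("spatial CV with a pass-through scorer reproduces per-band AUC", {
  w <- benchmark_world()
  truth_scorer <- function(presences, absences, env, hyperparams, seed) {
    function(lon, lat) invrisk:::score_at(w$truth, lon, lat)
  }
  cv <- spatial_cv(w$presences, w$absences, w$env, truth_scorer, k = 2)
  bands_p <- assign_latitudinal_bands(w$presences, 2)
  bands_a <- findInterval(w$absences$lat, attr(bands_p, "breaks")) + 1L
  for (b in 1:2) {
    sp <- invrisk:::score_at(w$truth, w$presences$lon[bands_p == b],
                             w$presences$lat[bands_p == b])
    sa <- invrisk:::score_at(w$truth, w$absences$lon[bands_a == b],
                             w$absences$lat[bands_a == b])
    expect_equal(cv$per_fold_auc[b], auc(sp, sa))
  }
  expect_equal(cv$mean_auc, mean(cv$per_fold_auc))
})

test_that("label shuffling collapses CV AUC to chance", {
  w <- benchmark_world()
  truth_scorer <- function(presences, absences, env, hyperparams, seed) {
    function(lon, lat) invrisk:::score_at(w$truth, lon, lat)
  }
  aucs <- sapply(1:5, function(s) {
    set.seed(s)
    all_lon <- c(w$presences$lon, w$absences$lon)
    all_lat <- c(w$presences$lat, w$absences$lat)
    pick <- sample(length(all_lon), nrow(w$presences))
    occ <- make_occ(all_lon[pick], all_lat[pick])
    ab <- data.frame(lon = all_lon[-pick], lat = all_lat[-pick])
    spatial_cv(occ, ab, w$env, truth_scorer, k = 4)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("folds with an empty class are skipped with a warning", {
  w <- benchmark_world()
  truth_scorer <- function(presences, absences, env, hyperparams, seed) {
    function(lon, lat) invrisk:::score_at(w$truth, lon, lat)
  }
  # absences confined to the far south: northern folds lose their absences
  ab_south <- w$absences[w$absences$lat < stats::median(w$absences$lat), ]
  expect_warning(
    cv <- spatial_cv(w$presences, ab_south, w$env, truth_scorer, k = 5),
    "skipped")
  expect_true(anyNA(cv$per_fold_auc))
  expect_equal(cv$mean_auc, mean(cv$per_fold_auc, na.rm = TRUE))
})

test_that("ensemble averaging obeys its algebra", {
  g <- mini_grid(6)
  s <- lapply(c(0.2, 0.4, 0.6), function(v) {
    suitability_surface(const_raster(g, v), "m")
  })
  expect_equal(ensemble_mean(s)$raster$values[1, 1], 0.4)
  one <- suitability_surface(raster_layer(g, matrix(runif(36), 6, 6)), "m")
  expect_equal(ensemble_mean(list(one))$raster$values, one$raster$values)
  # weighting by near-equal AUCs barely moves an agreeing ensemble
  set.seed(2)
  base <- matrix(runif(36, 0.3, 0.7), 6, 6)
  close <- lapply(1:3, function(i) {
    suitability_surface(raster_layer(g, pmin(pmax(base +
      runif(36, -0.025, 0.025), 0), 1)), "m")
  })
  eq <- ensemble_mean(close)
  wt <- ensemble_mean(close, weights = c(0.98, 0.97, 0.97))
  expect_lt(max(abs(eq$raster$values - wt$raster$values)), 0.01)
  # bounded by cellwise min/max; nodata propagates
  vals <- lapply(1:3, function(i) matrix(runif(36), 6, 6))
  vals[[2]][3, 3] <- NA
  ss <- lapply(vals, function(v) suitability_surface(raster_layer(g, v), "m"))
  em <- ensemble_mean(ss)$raster$values
  lo <- pmin(vals[[1]], vals[[2]], vals[[3]])
  hi <- pmax(vals[[1]], vals[[2]], vals[[3]])
  ok <- !is.na(em)
  expect_true(all(em[ok] >= lo[ok] - 1e-12 & em[ok] <= hi[ok] + 1e-12))
  expect_true(is.na(em[3, 3]))
  g2 <- mini_grid(7)
  bad <- suitability_surface(const_raster(g2, 0.5), "m")
  expect_error(ensemble_mean(list(one, bad)), "mismatch")
})

test_that("omission rate counts sub-threshold presences", {
  g <- mini_grid(10)
  vals <- matrix(seq(0, 0.99, length.out = 100), 10, 10)
  s <- suitability_surface(raster_layer(g, vals), "m")
  ctr <- grid_centers(g)
  pick <- order(as.vector(vals))[c(1:2, 91:98)]  # 2 low, 8 high cells
  occ <- make_occ(ctr$lon[pick], ctr$lat[pick])
  expect_equal(omission_rate(s, 0, occ), 0)
  expect_equal(omission_rate(s, 1.01, occ), 1)
  expect_equal(omission_rate(s, 0.5, occ), 0.2)
  # presence on nodata excluded with warning
  vals2 <- vals; vals2[1, 1] <- NA
  s2 <- suitability_surface(raster_layer(g, vals2), "m")
  occ2 <- make_occ(c(0.5, ctr$lon[pick[3]]), c(9.5, ctr$lat[pick[3]]))
  expect_warning(om <- omission_rate(s2, 0.5, occ2), "nodata")
  expect_equal(om, 0)
  # monotone in the threshold
  thr <- max_sss_threshold(invrisk:::score_at(s, occ$lon, occ$lat),
                           runif(10, 0, 0.4))
  om1 <- omission_rate(s, thr$threshold, occ)
  expect_lte(om1, omission_rate(s, thr$threshold + 0.2, occ))
})
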