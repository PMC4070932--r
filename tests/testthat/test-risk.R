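test_that("binarization respects bounds and the counting oracle", {
  g <- mini_grid(8)
  vals <- matrix(runif(64), 8, 8); vals[2, 5] <- NA
  s <- suitability_surface(raster_layer(g, vals), "m")
  lo <- binarize(s, min(vals, na.rm = TRUE))
  expect_true(all(lo$values[!is.na(lo$values)] == 1))
  hi <- binarize(s, max(vals, na.rm = TRUE) + 1e-9)
  expect_true(all(hi$values[!is.na(hi$values)] == 0))
  mid <- binarize(s, 0.5)
  expect_equal(sum(mid$values, na.rm = TRUE), sum(vals >= 0.5, na.rm = TRUE))
  expect_true(is.na(mid$values[2, 5]))
})

test_that("range overlap summarises suitability like boxplot.stats", {
  g <- mini_grid(10)
  vals <- matrix(runif(100), 10, 10)
  s <- suitability_surface(raster_layer(g, vals), "m")
  rm_all <- range_map("sat", rects = list(c(x0 = 0, x1 = 10, y0 = 0, y1 = 10)))
  expect_equal(range_overlap(s, 0, rm_all)$proportion_suitable, 1)
  # singleton range
  rm_1 <- range_map("one", rects = list(c(x0 = 2, x1 = 2.9, y0 = 3, y1 = 3.9)))
  rep1 <- range_overlap(s, 0.5, rm_1)
  expect_equal(rep1$n_cells, 1)
  cellval <- vals[7, 3]   # lat 3.5 -> row 7, lon 2.5 -> col 3
  expect_equal(unname(rep1$suitability_quartiles["median"]), cellval)
  expect_true(rep1$proportion_suitable %in% c(0, 1))
  # checkerboard: proportion exactly 0.5
  cb <- matrix(rep(c(0.9, 0.1), 50), 10, 10)
  scb <- suitability_surface(raster_layer(g, cb), "m")
  expect_equal(range_overlap(scb, 0.5, rm_all)$proportion_suitable, 0.5)
  # whisker convention matches grDevices::boxplot.stats
  set.seed(4)
  vals2 <- matrix(c(runif(98, 0.3, 0.5), 0.99, 0.01), 10, 10)
  s2 <- suitability_surface(raster_layer(g, vals2), "m")
  q <- range_overlap(s2, 0.5, rm_all)$suitability_quartiles
  bs <- grDevices::boxplot.stats(as.vector(vals2),
                                 do.conf = FALSE, do.out = FALSE)$stats
  expect_equal(unname(q[c("min_whisker", "max_whisker")]), bs[c(1, 5)])
  expect_true(q["q1"] <= q["median"] && q["median"] <= q["q3"])
})

test_that("connectivity flood fill matches the BFS oracle", {
  g <- mini_grid(20, cell = 0.5)
  # fully suitable grid: everything reachable from one source
  all1 <- raster_layer(g, matrix(1, 20, 20))
  cm <- connected_suitable(all1, data.frame(lon = 5, lat = 5))
  expect_true(all(cm$reachable$values == 1))
  # two patches split by an unsuitable column
  m <- matrix(1, 20, 20); m[, 10] <- 0
  split2 <- raster_layer(g, m)
  cm4 <- connected_suitable(split2, data.frame(lon = 1, lat = 5), neighbors = 4)
  expect_true(all(cm4$reachable$values[, 1:9] == 1))
  expect_true(all(cm4$reachable$values[, 10:20] == 0))
  # random masks, both neighbor rules, 20 trials
  for (i in 1:20) {
    set.seed(i)
    mm <- matrix(runif(400) < 0.55, 20, 20)
    src_cell <- sample(which(mm), 1)
    src_r <- (src_cell - 1) %% 20 + 1; src_c <- (src_cell - 1) %/% 20 + 1
    src <- data.frame(lon = (src_c - 0.5) * 0.5, lat = 10 - (src_r - 0.5) * 0.5)
    for (nb in c(4, 8)) {
      got <- connected_suitable(raster_layer(g, mm + 0), src, neighbors = nb)
      want <- bfs_oracle(mm, src_cell, nb)
      expect_identical(got$reachable$values > 0, want)
      expect_true(all(got$reachable$values <= mm))   # reachable subset suitable
    }
  }
  # source on unsuitable cell: empty mask with warning
  expect_warning(
    empty <- connected_suitable(split2, data.frame(lon = 4.75, lat = 5)),
    "no source")
  expect_equal(sum(empty$reachable$values), 0)
  expect_error(connected_suitable(all1, data.frame(lon = numeric(0),
                                                   lat = numeric(0))),
               "source")
})

test_that("adding suitable cells never shrinks the reachable set", {
  g <- mini_grid(15)
  for (i in 1:10) {
    set.seed(100 + i)
    m1 <- matrix(runif(225) < 0.45, 15, 15)
    m2 <- m1 | (matrix(runif(225) < 0.15, 15, 15))
    src_cell <- sample(which(m1), 1)
    r <- (src_cell - 1) %% 15 + 1; cc <- (src_cell - 1) %/% 15 + 1
    src <- data.frame(lon = cc - 0.5, lat = 15 - r + 0.5)
    r1 <- connected_suitable(raster_layer(g, m1 + 0), src)$reachable$values
    r2 <- connected_suitable(raster_layer(g, m2 + 0), src)$reachable$values
    expect_true(all(r2[r1 > 0] > 0))
  }
})

test_that("overlap decline accounts for isolated suitable patches", {
  g <- mini_grid(10)
  vals <- matrix(0.1, 10, 10)
  vals[, 1:3] <- 0.9       # west suitable patch
  vals[, 8:10] <- 0.9      # east suitable patch, isolated
  s <- suitability_surface(raster_layer(g, vals), "m")
  suit <- binarize(s, 0.5)
  src <- data.frame(lon = 0.5, lat = 5.5)  # in the west patch
  mask <- connected_suitable(suit, src, neighbors = 4)
  rm_all <- range_map("r", rects = list(c(x0 = 0, x1 = 10, y0 = 0, y1 = 10)))
  d <- overlap_decline(s, 0.5, rm_all, mask)
  expect_equal(d$unrestricted, 0.6)
  expect_equal(d$connected, 0.3)           # east patch unreachable
  expect_equal(d$decline, 0.3)
  # full connectivity -> no decline
  mask_all <- connected_suitable(binarize(s, 0), src)
  d2 <- overlap_decline(s, 0.5, rm_all, mask_all)
  expect_equal(d2$decline, 0)
  # empty mask -> connected 0, decline equals unrestricted
  suppressWarnings(
    mask_none <- connected_suitable(suit, data.frame(lon = 5, lat = 5),
                                    neighbors = 4))
  d3 <- overlap_decline(s, 0.5, rm_all, mask_none)
  expect_equal(d3$connected, 0)
  expect_equal(d3$decline, d3$unrestricted)
  # connected proportion never exceeds unrestricted (random trials)
  for (i in 1:10) {
    set.seed(200 + i)
    v <- matrix(runif(100), 10, 10)
    sr <- suitability_surface(raster_layer(g, v), "m")
    msk <- suppressWarnings(
      connected_suitable(binarize(sr, 0.5),
                         data.frame(lon = runif(1, 0, 10),
                                    lat = runif(1, 0, 10))))
    dd <- overlap_decline(sr, 0.5, rm_all, msk)
    expect_gte(dd$decline, -1e-12)
  }
})
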