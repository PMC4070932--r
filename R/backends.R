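# The three suitability backends. All are presence / pseudo-absence
# classifiers emitting scores on a probability-like [0,1] scale:
#   maxent_like   - L1-penalized logistic model over MaxEnt-style feature
#                   expansions (linear, quadratic, pairwise product, hinge),
#                   fitted with glmnet; logistic-scale output.
#   boosted_trees - stagewise logistic gradient boosting of shallow
#                   regression trees with shrinkage, bag fraction, and early
#                   stopping on held-out deviance.
#   random_forest - bagged probability trees with per-split random predictor
#                   subsetting.
# Training feature ranges are recorded per predictor so projections can be
# clamped to the training range.

sdm_backends <- c("maxent_like", "boosted_trees", "random_forest")

#' Default hyperparameters per backend
#'
#' @param backend_id One of `"maxent_like"`, `"boosted_trees"`,
#'   `"random_forest"`.
#' @return Named list of defaults (overridable via the `hyperparams` argument
#'   of [fit_model()]).
#' @export
default_hyperparams <- function(backend_id) {
  switch(backend_id,
    maxent_like = list(n_knots = 6, nfolds = 5, alpha = 1, s = "lambda.min"),
    boosted_trees = list(depth = 3, shrinkage = 0.01, bag_fraction = 0.5,
                         n_trees_max = 3000, patience = 100,
                         val_fraction = 0.2, min_node = 10),
    random_forest = list(n_trees = 500, mtry = NULL, min_node = 5,
                         max_depth = 25, sample_frac = 1, replace = TRUE),
    stop("unknown backend: ", backend_id))
}

#' Fit a suitability model
#'
#' @param backend_id One of `"maxent_like"`, `"boosted_trees"`,
#'   `"random_forest"`.
#' @param presences An [occurrence_set()].
#' @param absences A [sample_pseudo_absences()] result (any data.frame with
#'   `lon`/`lat` works).
#' @param env An [env_stack()] covering all points with valid data.
#' @param hyperparams Named list overriding [default_hyperparams()].
#' @param seed Integer seed; fits are deterministic given
#'   `(data, hyperparams, seed)`.
#' @return An `sdm_fit` carrying the fitted state, the training feature
#'   ranges (for clamping), and training metadata.
#' @export
fit_model <- function(backend_id, presences, absences, env,
                      hyperparams = list(), seed = 1) {
  if (!backend_id %in% sdm_backends) stop("unknown backend: ", backend_id)
  stopifnot(inherits(env, "env_stack"))
  hp <- utils::modifyList(default_hyperparams(backend_id), hyperparams)
  Xp <- env_values_at(env, presences$lon, presences$lat)
  Xa <- env_values_at(env, absences$lon, absences$lat)
  if (anyNA(Xp) || anyNA(Xa))
    stop("training points fall outside the grid or on nodata cells")
  X <- rbind(Xp, Xa)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xa)))
  if (nrow(Xp) == 0 || nrow(Xa) == 0) stop("both classes must be non-empty")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping degenerate single-valued predictor(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-degenerate predictors left")
  ranges <- apply(X, 2, range)
  rownames(ranges) <- c("min", "max")
  state <- switch(backend_id,
    maxent_like = fit_maxent_like(X, y, hp, seed),
    boosted_trees = fit_brt(X, y, hp, seed),
    random_forest = fit_rf(X, y, hp, seed))
  structure(list(backend_id = backend_id, state = state,
                 predictors = colnames(X), ranges = ranges,
                 train_means = colMeans(X), hyperparams = hp,
                 meta = list(n_presences = nrow(Xp), n_absences = nrow(Xa),
                             seed = seed)),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit [%s]: %d presences vs %d pseudo-absences on {%s}\n",
              x$backend_id, x$meta$n_presences, x$meta$n_absences,
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

## ---- maxent_like -----------------------------------------------------------

mx_knots <- function(X, n_knots) {
  lapply(seq_len(ncol(X)), function(j) {
    k <- unique(quantile(X[, j], probs = seq(0.1, 0.9, length.out = n_knots),
                         names = FALSE))
    k[k > min(X[, j]) & k < max(X[, j])]
  })
}

mx_features <- function(X, knots) {
  p <- ncol(X)
  cols <- list()
  nms <- colnames(X)
  for (j in seq_len(p)) {
    cols[[paste0(nms[j], ".lin")]] <- X[, j]
    cols[[paste0(nms[j], ".sq")]] <- X[, j]^2
  }
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      cols[[paste0(nms[i], ".x.", nms[j])]] <- X[, i] * X[, j]
  }
  for (j in seq_len(p)) {
    for (k in knots[[j]]) {
      cols[[sprintf("%s.hf.%.6g", nms[j], k)]] <- pmax(0, X[, j] - k)
      cols[[sprintf("%s.hr.%.6g", nms[j], k)]] <- pmax(0, k - X[, j])
    }
  }
  do.call(cbind, cols)
}

fit_maxent_like <- function(X, y, hp, seed) {
  # scale predictors to [0,1] over the training range before any feature
  # expansion; raw bioclim scales (bio4 ~ 8000) make quadratic/product
  # features ill-conditioned
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  Xs <- sweep(sweep(X, 2, lo), 2, pmax(hi - lo, .Machine$double.eps), "/")
  knots <- mx_knots(Xs, hp$n_knots)
  fm <- mx_features(Xs, knots)
  # fold assignment by sorted data order -> invariant to row permutation
  ord <- do.call(order, as.data.frame(cbind(y, X)))
  foldid <- integer(length(y))
  foldid[ord] <- rep_len(seq_len(hp$nfolds), length(y))
  # lambda.min.ratio stops the path before its ill-conditioned tail (the
  # near-separable fits there trigger spurious convergence warnings)
  cv <- glmnet::cv.glmnet(fm, y, family = "binomial", alpha = hp$alpha,
                          foldid = foldid, standardize = TRUE,
                          lambda.min.ratio = 1e-3)
  list(cv = cv, knots = knots, s = hp$s, lo = lo, hi = hi)
}

predict_maxent_like <- function(state, X) {
  Xs <- sweep(sweep(X, 2, state$lo), 2,
              pmax(state$hi - state$lo, .Machine$double.eps), "/")
  fm <- mx_features(Xs, state$knots)
  as.numeric(predict(state$cv, newx = fm, s = state$s, type = "response"))
}

## ---- boosted_trees ---------------------------------------------------------

fit_brt <- function(X, y, hp, seed) {
  set.seed(seed)
  n <- length(y)
  # stratified internal validation split for early stopping
  val <- logical(n)
  for (cls in c(0, 1)) {
    rows <- which(y == cls)
    nv <- max(1L, round(hp$val_fraction * length(rows)))
    val[sample(rows, nv)] <- TRUE
  }
  train <- which(!val); hold <- which(val)
  p0 <- mean(y[train])
  F0 <- log(p0 / (1 - p0))
  Fv <- rep(F0, n)
  trees <- list(); gammas <- list()
  best_dev <- Inf; best_iter <- 0L
  mtry <- ncol(X)
  bag_n <- max(2L, round(hp$bag_fraction * length(train)))
  for (m in seq_len(hp$n_trees_max)) {
    pr <- stats::plogis(Fv)
    r <- y - pr
    bag <- sample(train, bag_n)
    tree <- cpp_tree_fit(X, r, bag - 1L, hp$depth, hp$min_node, mtry)
    leaf <- cpp_tree_leaf(tree, X) + 1L
    w <- pr * (1 - pr)
    num <- tapply(r[bag], leaf[bag], sum)
    den <- tapply(w[bag], leaf[bag], sum)
    gamma <- rep(0, length(tree$var))
    gamma[as.integer(names(num))] <- num / pmax(den, 1e-10)
    gamma <- pmin(pmax(gamma, -4), 4)
    Fv <- Fv + hp$shrinkage * gamma[leaf]
    trees[[m]] <- tree; gammas[[m]] <- gamma
    ph <- stats::plogis(Fv[hold])
    dev <- -2 * sum(y[hold] * log(pmax(ph, 1e-12)) +
                    (1 - y[hold]) * log(pmax(1 - ph, 1e-12)))
    if (dev < best_dev - 1e-9) { best_dev <- dev; best_iter <- m }
    if (m - best_iter >= hp$patience) break
  }
  n_used <- max(best_iter, 1L)
  list(F0 = F0, shrinkage = hp$shrinkage,
       trees = trees[seq_len(n_used)], gammas = gammas[seq_len(n_used)],
       n_trees = n_used)
}

predict_brt <- function(state, X) {
  Fv <- rep(state$F0, nrow(X))
  for (m in seq_along(state$trees)) {
    leaf <- cpp_tree_leaf(state$trees[[m]], X) + 1L
    Fv <- Fv + state$shrinkage * state$gammas[[m]][leaf]
  }
  stats::plogis(Fv)
}

## ---- random_forest ---------------------------------------------------------

fit_rf <- function(X, y, hp, seed) {
  set.seed(seed)
  mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else hp$mtry
  forest <- cpp_forest_fit(X, y, hp$n_trees, hp$max_depth, hp$min_node,
                           mtry, hp$sample_frac, hp$replace)
  list(forest = forest)
}

predict_rf <- function(state, X) {
  pmin(1, pmax(0, cpp_forest_predict(state$forest, X)))
}

## ---- shared prediction path ------------------------------------------------

clamp_to_ranges <- function(X, ranges) {
  for (j in colnames(X))
    X[, j] <- pmin(pmax(X[, j], ranges["min", j]), ranges["max", j])
  X
}

predict_matrix <- function(model, X, clamp = TRUE) {
  X <- X[, model$predictors, drop = FALSE]
  if (clamp) X <- clamp_to_ranges(X, model$ranges)
  switch(model$backend_id,
    maxent_like = predict_maxent_like(model$state, X),
    boosted_trees = predict_brt(model$state, X),
    random_forest = predict_rf(model$state, X))
}

#' Score point locations with a fitted model
#'
#' @param model An [fit_model()] result.
#' @param lon,lat Coordinates.
#' @param env An [env_stack()] providing the predictors.
#' @param clamp Truncate predictors to the training range first (default
#'   TRUE).
#' @return Numeric scores in `[0, 1]`; NA for points on nodata.
#' @export
predict_points <- function(model, lon, lat, env, clamp = TRUE) {
  X <- env_values_at(env, lon, lat, layers = model$predictors)
  out <- rep(NA_real_, length(lon))
  ok <- rowSums(is.na(X)) == 0
  if (any(ok)) out[ok] <- predict_matrix(model, X[ok, , drop = FALSE], clamp)
  out
}

#' Project a fitted model over a stack
#'
#' With `clamp = TRUE` (default, matching the reference workflow) every
#' predictor is truncated to its training `[min, max]` before evaluation, so
#' predictions are constant along any ray leaving the training range in one
#' coordinate. Nodata propagates.
#'
#' @param model An [fit_model()] result.
#' @param env An [env_stack()] whose layer names cover the model predictors.
#' @param clamp Clamp to training ranges (default TRUE).
#' @return A [suitability_surface()].
#' @export
predict_surface <- function(model, env, clamp = TRUE) {
  missing <- setdiff(model$predictors, names(env$layers))
  if (length(missing))
    stop("missing layer(s): ", paste(missing, collapse = ", "))
  vals <- sapply(model$predictors, function(nm) as.vector(env$layers[[nm]]$values))
  vals <- matrix(vals, ncol = length(model$predictors),
                 dimnames = list(NULL, model$predictors))
  ok <- rowSums(is.na(vals)) == 0
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) out[ok] <- predict_matrix(model, vals[ok, , drop = FALSE], clamp)
  out <- pmin(1, pmax(0, out))
  suitability_surface(
    raster_layer(env$grid, matrix(out, env$grid$n_rows, env$grid$n_cols)),
    provenance = model$backend_id)
}

#' Marginal response curve of a fitted model
#'
#' Evaluation-strip method: the target variable is varied over its training
#' range at `n_points` while all other predictors are held at their training
#' means.
#'
#' @param model An [fit_model()] result.
#' @param env An [env_stack()] (used only for layer-name validation).
#' @param variable Predictor name.
#' @param n_points Number of evaluation points (>= 2).
#' @return data.frame with columns `value` and `prediction`.
#' @export
response_curve <- function(model, env, variable, n_points = 100) {
  if (!variable %in% model$predictors)
    stop(variable, " is not a model predictor")
  if (n_points < 2) stop("n_points must be >= 2")
  vals <- seq(model$ranges["min", variable], model$ranges["max", variable],
              length.out = n_points)
  X <- matrix(rep(model$train_means, each = n_points),
              nrow = n_points, dimnames = list(NULL, model$predictors))
  X[, variable] <- vals
  data.frame(value = vals, prediction = predict_matrix(model, X, clamp = TRUE))
}

#' Peak location of a response curve
#'
#' Tree-ensemble response curves are step functions with flat tops, so a raw
#' argmax lands at the left edge of the plateau. The peak is therefore
#' estimated as the midpoint of the interval whose predictions are within
#' `frac` of the curve's range below the maximum.
#'
#' @param curve A [response_curve()] data.frame.
#' @param frac Fraction of the prediction range defining the near-max region
#'   (default 0.95).
#' @return Peak location in predictor units.
#' @export
curve_peak <- function(curve, frac = 0.95) {
  lo <- min(curve$prediction); hi <- max(curve$prediction)
  thr <- lo + frac * (hi - lo)
  mean(range(curve$value[curve$prediction >= thr]))
}
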