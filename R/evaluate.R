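# Model evaluation: rank-based AUC, spatially stratified (latitudinal band)
# cross-validation, ensemble averaging, Max-SSS thresholding, and omission
# error. The suitability convention everywhere is: score >= threshold means
# suitable.

#' Area under the ROC curve (rank statistic)
#'
#' Fraction of (presence, absence) score pairs in which the presence scores
#' higher, with ties counted 1/2 — the Mann-Whitney form of AUC.
#'
#' @param presence_scores,absence_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, absence_scores) {
  np <- length(presence_scores); na <- length(absence_scores)
  if (np == 0 || na == 0) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, absence_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Spatially stratified k-fold cross-validation
#'
#' Presences are partitioned into `k` latitudinal bands
#' ([assign_latitudinal_bands()]); pseudo-absences are assigned to the same
#' band boundaries by latitude. For each band, a model is trained on all
#' points outside it and AUC is computed on the points inside it. Folds in
#' which either class is empty (train or test side) are skipped with a
#' warning and excluded from the mean.
#'
#' @param presences An [occurrence_set()].
#' @param absences A pseudo-absence data.frame (`lon`, `lat`).
#' @param env An [env_stack()].
#' @param backend_id A backend name for [fit_model()], or a scorer factory
#'   `function(presences, absences, env, hyperparams, seed)` returning a
#'   function `(lon, lat) -> scores` (extension point used for oracle tests).
#' @param k Number of bands; default 5.
#' @param hyperparams Passed to [fit_model()].
#' @param seed Base seed; fold `b` uses `seed + b`.
#' @param band_method Passed to [assign_latitudinal_bands()].
#' @return A `cv_result`: list with `per_fold_auc` (NA for skipped folds),
#'   `mean_auc`, `auc_range`, `fold_definition` (band breaks), `k`.
#' @export
spatial_cv <- function(presences, absences, env, backend_id, k = 5,
                       hyperparams = list(), seed = 1,
                       band_method = "quantile") {
  bands_p <- assign_latitudinal_bands(presences, k, method = band_method)
  breaks <- attr(bands_p, "breaks")
  bands_a <- bands_from_breaks(absences$lat, breaks)
  per_fold <- rep(NA_real_, k)
  for (b in seq_len(k)) {
    tr_p <- presences[bands_p != b, , drop = FALSE]
    te_p <- presences[bands_p == b, , drop = FALSE]
    tr_a <- absences[bands_a != b, , drop = FALSE]
    te_a <- absences[bands_a == b, , drop = FALSE]
    if (nrow(te_p) == 0 || nrow(te_a) == 0 ||
        nrow(tr_p) == 0 || nrow(tr_a) == 0) {
      warning(sprintf("fold %d skipped: empty class", b))
      next
    }
    tr_p <- occurrence_set(tr_p)
    scorer <- if (is.function(backend_id)) {
      backend_id(tr_p, tr_a, env, hyperparams, seed + b)
    } else {
      model <- fit_model(backend_id, tr_p, tr_a, env, hyperparams, seed + b)
      function(lon, lat) predict_points(model, lon, lat, env)
    }
    sp <- scorer(te_p$lon, te_p$lat)
    sa <- scorer(te_a$lon, te_a$lat)
    sp <- sp[!is.na(sp)]; sa <- sa[!is.na(sa)]
    if (length(sp) == 0 || length(sa) == 0) {
      warning(sprintf("fold %d skipped: no valid scores", b))
      next
    }
    per_fold[b] <- auc(sp, sa)
  }
  ok <- per_fold[!is.na(per_fold)]
  if (length(ok) == 0) stop("all folds were skipped")
  structure(list(per_fold_auc = per_fold, mean_auc = mean(ok),
                 auc_range = range(ok), fold_definition = breaks, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("spatial CV (%d bands): mean AUC %.3f (range %.3f-%.3f)\n",
              x$k, x$mean_auc, x$auc_range[1], x$auc_range[2]))
  invisible(x)
}

#' Cellwise ensemble of suitability surfaces
#'
#' Simple arithmetic mean by default (the reference workflow's choice); with
#' `weights` a weight-normalized mean (e.g. AUC weighting). Nodata wherever
#' any input is nodata.
#'
#' @param surfaces List of co-registered [suitability_surface()] objects.
#' @param weights Optional positive weights, one per surface.
#' @return A [suitability_surface()] with provenance `"ensemble"`.
#' @export
ensemble_mean <- function(surfaces, weights = NULL) {
  stopifnot(length(surfaces) >= 1)
  g <- surfaces[[1]]$raster$grid
  for (s in surfaces)
    if (!grid_equal(g, s$raster$grid)) stop("grid mismatch between surfaces")
  if (is.null(weights)) weights <- rep(1, length(surfaces))
  if (length(weights) != length(surfaces) || any(weights <= 0))
    stop("weights must be positive, one per surface")
  weights <- weights / sum(weights)
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (i in seq_along(surfaces))
    acc <- acc + weights[i] * surfaces[[i]]$raster$values
  suitability_surface(raster_layer(g, acc), "ensemble")
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every unique observed score as a candidate threshold under the
#' convention "score >= t is suitable" and returns the candidate maximizing
#' sensitivity + specificity. Ties are broken toward the smallest threshold,
#' favoring sensitivity (false negatives are the costly error when mapping
#' invasion risk).
#'
#' @param presence_scores,absence_scores Non-empty numeric score vectors.
#' @return A `threshold_result`: list with `threshold`, `sensitivity_at`,
#'   `specificity_at`, `sss`.
#' @export
max_sss_threshold <- function(presence_scores, absence_scores) {
  np <- length(presence_scores); na <- length(absence_scores)
  if (np == 0 || na == 0) stop("both score vectors must be non-empty")
  cand <- sort(unique(c(presence_scores, absence_scores)))
  se <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  sp <- vapply(cand, function(t) mean(absence_scores < t), numeric(1))
  sss <- se + sp
  best <- which(sss >= max(sss) - 1e-12)[1]   # smallest threshold among ties
  structure(list(threshold = cand[best], sensitivity_at = se[best],
                 specificity_at = sp[best], sss = sss[best]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Max SSS: t = %.4g (Se %.3f, Sp %.3f, SSS %.3f)\n",
              x$threshold, x$sensitivity_at, x$specificity_at, x$sss))
  invisible(x)
}

#' Omission error rate
#'
#' Fraction of presence records whose cell value falls below the threshold
#' (classified unsuitable). Presences on nodata cells are excluded with a
#' warning.
#'
#' @param surface A [suitability_surface()].
#' @param threshold Binarization threshold.
#' @param presences An [occurrence_set()].
#' @return Omission rate in `[0, 1]`.
#' @export
omission_rate <- function(surface, threshold, presences) {
  idx <- cell_of(surface$raster$grid, presences$lon, presences$lat)
  vals <- rep(NA_real_, nrow(presences))
  ok <- !is.na(idx$row)
  vals[ok] <- surface$raster$values[cbind(idx$row[ok], idx$col[ok])]
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " presence(s) on nodata cells excluded")
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) stop("no presences on valid cells")
  mean(vals < threshold)
}
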