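---
title: "Methods: ensemble habitat suitability and invasion-risk mapping"
author: "invrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat suitability and invasion-risk mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invrisk)
```

## The problem

An introduced species with a handful of established populations poses a
question with two parts: *where else could it live*, and *which native
species would it meet if it spread there*. `invrisk` implements the standard
inference chain that answers both from presence-only occurrence records and
environmental rasters:

1. clean and spatially thin occurrences;
2. build a fractional wetland-cover predictor from classified water-body
   polygons;
3. screen candidate predictors with an Ecological Niche Factor Analysis
   (ENFA);
4. fit an ensemble of three presence/pseudo-absence suitability models;
5. evaluate transferability with spatially stratified cross-validation;
6. binarize the ensemble at the maximum sensitivity-plus-specificity
   (Max SSS) threshold;
7. quantify overlap with native-species ranges; and
8. restrict projected risk to cells connected to established source
   populations through suitable habitat.

Because the real inputs of such analyses (museum records, interpolated
climate, national hydrography) are large downloads, the package ships a
synthetic-landscape generator with known truth, so every stage is testable
end to end offline.

## Data model

A `grid_spec` is a regular lat/lon grid with square cells; cell (1,1) is
the north-west corner and cell intervals are half-open (west/north edges
inclusive). Rasters are matrices on a grid with `NA` as nodata; an
`env_stack` bundles co-registered layers. The standard predictors are
temperature seasonality (`bio4`, SD of monthly temperature x 100), mean
temperature of the warmest (`bio10`) and coldest (`bio11`) quarters (deg C),
and fractional wetland cover (`wetland`, in [0, 1]). The stack enforces
`bio10 >= bio11` and the wetland bounds.

## Occurrence cleaning

`filter_precision()` keeps records with reported coordinate precision
*strictly* below the cutoff (default 5 km) — a record at exactly the cutoff
is dropped, a literal reading of the "< 5 km" convention.
`thin_to_grid()` retains at most one record per thinning cell (10
arc-minutes in the reference workflow), choosing uniformly at random under
a seed rather than by record order, which would bias toward whatever
ordering the source database used. Thinning is idempotent.

`assign_latitudinal_bands()` partitions records into `k` contiguous
latitude intervals for spatial cross-validation. Whether such bands should
have equal width or equal occurrence counts is genuinely open; the default
is equal counts (quantile bands) because it guarantees non-degenerate test
folds on clustered data, with `method = "width"` available. Band labels
run south to north; the interior boundaries are returned so pseudo-absences
can be assigned to the same folds by latitude.

## Wetland layer and ENFA screening

`build_wetland_raster()` computes, per cell, the intersected area of
kept-class water-body polygons divided by the cell area, clipped to [0, 1].
Kept classes are perennial natural/artificial streams, lakes/ponds,
reservoirs, and swamps/marshes; playas, saline lakes, estuaries, peat bogs,
and intermittent streams are recognised but excluded (they are not usable
habitat for a wetland-obligate watersnake). Areas are planar in squared
degrees: the statistic is a per-cell *ratio*, so the areal unit cancels; a
spherical-area correction would matter only for statistics that mix cells
across wide latitude spans. Stream centerlines can be buffered into
per-segment rectangles (`buffer_line()`); joints are not mitred, which is
adequate for synthetic hydrography but approximate for real data.

`enfa()` implements the single-marginality-axis variant: variables are
standardized over all valid cells; marginality per variable is
`(presence mean - global mean) / global SD` over occupied cells;
specialization factors are the eigen-decomposition of the presence
covariance projected orthogonally to the marginality axis. The classical
1.96 scaling of marginality is deliberately omitted so that the statistic
is exactly the standardized mean shift. `select_variables()` ranks
variables by |marginality| (ties by specialization loading; `rank_by =
"specialization"` available, and more appropriate when the species' niche
is centred in available environmental space, where marginality is near
zero by construction) and greedily retains variables whose pairwise |r|
against all retained variables stays below `r_max` (default 0.85).

## Suitability backends

All three backends are presence/pseudo-absence classifiers returning
scores in [0, 1]:

* **`maxent_like`** — an L1-penalized logistic model over MaxEnt-style
  feature expansions (linear, quadratic, pairwise products, and two-sided
  hinge features at interior quantile knots), fitted with `glmnet`. The
  penalized log-linear formulation is statistically equivalent to MaxEnt's
  regularized density-ratio estimation with logistic output, without
  porting the original software. Predictors are rescaled to [0, 1] over
  the training range before feature construction (raw bioclim scales make
  quadratic features ill-conditioned), the regularization path is stopped
  at `lambda.min.ratio = 1e-3` before its ill-conditioned tail, and
  cross-validation folds are assigned by sorted data order so the fit is
  invariant to row permutation. The background equals the pseudo-absence
  set, mirroring the reference workflow.
* **`boosted_trees`** — stagewise logistic gradient boosting of shallow
  CART trees (default depth 3, shrinkage 0.01, bag fraction 0.5) with
  early stopping on the deviance of an internal stratified 20% holdout,
  capped at 3000 trees.
* **`random_forest`** — 500 bagged probability trees with per-split
  random predictor subsetting (`mtry = floor(sqrt(p))`, minimum node size
  5).

The CART engine is compiled (Rcpp) with squared-error splits; all
randomness flows through R's RNG, so every backend is a pure function of
`(data, hyperparameters, seed)`. Defaults stand in for the reference
methods' cited defaults and are all overridable via `hyperparams`.

**Clamping.** Training min/max per predictor are stored in the fit;
`predict_surface(..., clamp = TRUE)` truncates predictors to that range, so
projections are constant along any ray leaving the training hypercube in
one coordinate — the standard guard against extrapolation artifacts.

**Response curves.** `response_curve()` uses the evaluation-strip method:
vary one predictor over its training range with the others held at their
training means. For tree ensembles these curves are step functions with
flat tops, so `curve_peak()` estimates the peak as the midpoint of the
interval within 95% of the curve maximum rather than a raw argmax (which
systematically lands on the left edge of a plateau).

## Pseudo-absences and accessible area

`accessible_area()` buffers the convex hull of the presences by
`buffer_deg` in the Euclidean degree metric (the constraint the reference
workflow states is in degrees, so no great-circle correction is applied);
with fewer than three non-collinear presences it falls back to point
buffers. `sample_pseudo_absences()` draws cell centers uniformly, one per
cell, over the admissible region: accessible, valid data, and at least
`min_dist_deg` (default 2) from every presence. A deficit (fewer
admissible cells than requested points) is a hard error naming the
shortfall. The single pseudo-absence set is shared across CV folds and
assigned to bands by latitude; per-fold resampling is possible by calling
the sampler inside a custom scorer, but pooling is the default because the
reference workflow gives no indication of per-fold background resampling.

## Evaluation, ensemble, threshold

`auc()` is the Mann-Whitney rank form (ties count 1/2). `spatial_cv()`
trains on all points outside a latitudinal band and scores the points
inside it; folds with an empty class are skipped with a warning and
excluded from the mean — small synthetic runs must degrade gracefully
rather than abort. `ensemble_mean()` is a cellwise simple average by
default, with optional positive weights (e.g. AUC weighting; with
near-equal AUCs the two differ negligibly, which is why the simple mean is
the default). `max_sss_threshold()` scans all unique observed scores under
the single package-wide convention *score >= t means suitable* and breaks
ties toward the smallest threshold: for invasion-risk mapping a false
negative (missing a potentially invasible area) costs more than a false
positive. `omission_rate()` is the fraction of presences in cells below
the threshold.

## Risk and connectivity

`range_overlap()` reports, per native range, the suitability distribution
(five-number boxplot summary; whiskers extend to the most extreme point
within 1.5 x IQR of the box) and the proportion of range cells at or above
the threshold. Cells with nodata suitability are excluded from numerator
and denominator, with the excluded count recorded. Polygon ranges are
rasterized by cell-center containment — simple, deterministic, and exactly
consistent with the per-cell statistic.

`connected_suitable()` is a zero-cost flood fill from the source cells
through suitable cells; unsuitable cells are barriers. 8-connectivity is
the default (queen-move adjacency, matching GIS cost-distance tools), with
4-connectivity for sensitivity analysis. Accumulated-cost surfaces are
deliberately not implemented: the underlying question is binary
(connected or not), so reachability suffices. `overlap_decline()` then
reports how much each species' overlap proportion drops when only
source-connected suitable cells count.

## The synthetic world

`generate_environment()` builds temperature layers as a linear trend plus
Gaussian-smoothed noise, and an independent sparse, patchy wetland layer
(thresholded smoothed noise; ~15% of cells non-zero), emulating the
contrast between interpolated-climate smoothness and fine-scale wetland
fragmentation. Two generator choices deserve explanation:

* the default temperature trend has an east-west component
  (`lon_gradient = 0.4` deg C per degree longitude, cooler west) in
  addition to the latitudinal gradient. With a purely latitudinal field,
  background points flanking a native range east/west are climatically
  identical to presences at the same latitude, and presence/background
  discrimination is impossible *by construction* — a degenerate test
  world. Real continental temperature fields vary along both axes.
  Setting `lon_gradient = 0` and `roughness = 0` recovers the exact
  linear latitudinal gradient limit.
* the default truth (`default_truth_params()`) is wetland-dominant:
  logit-scale intercept -4, unimodal `bio10` response (optimum 26 deg C,
  width 3), saturating wetland response (slope 14, plateau at 0.3 cover).
  A wetland-obligate species has near-zero suitability without wetland
  even at its thermal optimum (~0.02 here), and the resulting suitability
  surface is fragmented the way a fine-scale wetland predictor fragments
  real model output.

`sample_occurrences()` assumes uniform collecting effort within the native
window (no model of opportunistic museum sampling exists to emulate, so
this assumption is explicit); reported coordinate precision is drawn
lognormally around a 4-km median so the 5-km filter is exercised from both
sides, and the actual coordinate displacement is an independent
half-normal draw — museum precision metadata only approximates true error.

The demonstration configuration (`demo_config()`) uses a 100 x 100 grid of
0.25-degree cells (25 x 25 degrees). The analysis resolution of the
reference workflow (2.5 arc-minutes) is supported and unit-tested, but a
100 x 100 grid at that resolution spans ~4 degrees, inside which the
2-degree pseudo-absence exclusion leaves no admissible background — the
constraint is only geometrically meaningful at continental scale. The
thinning grid scales correspondingly to 0.5 degrees.

**What a green test establishes.** The synthetic world has smooth
gradients, rectangle hydrography and ranges, uniform sampling effort, and
a truth of exactly the assumed functional form. Passing the recovery
benchmark shows the chain is implemented correctly and can recover a known
signal at realistic sample sizes; it does not show that any particular
real dataset satisfies those assumptions, and says nothing about
georeferencing quality, taxonomic error, or sampling bias in real museum
data.

## Reproducibility and numerical choices

* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage offsets from one master seed, and two runs from the same
  configuration are byte-identical in their `summary.json`.
* The recovery benchmark in the test suite is pinned to one committed
  seed. At that seed all criteria hold with margin; across other seeds
  the mean 5-band AUC of each backend stays in the high 0.8s-0.9s and the
  recovered thermal optimum within about +/- 2 deg C, occasionally
  touching the boundary — the margin reflects genuine presence-only
  estimation noise at n = 300, not implementation error.
* Stage-output caching was considered and rejected: at synthetic scale
  the full chain runs in seconds, and a content-hash cache would be more
  code than the pipeline. Configurations are JSON (one file drives both
  synthetic and real runs).
* Ties: Max SSS ties break toward the smallest threshold; within-cell
  thinning choice is seeded-uniform; band boundaries are midpoints
  between adjacent sorted latitudes.

## Limitations

* Distances are Euclidean in degrees throughout (as the reference
  constraints are stated); none of the defaults are appropriate for
  high-latitude domains without rescaling.
* The ENFA screen ranks by marginality by default, which is weak when the
  species occupies the centre of available environmental space (the
  synthetic demo is such a case — there the screen may retain a
  correlated proxy rather than the causal variable; the ensemble is
  robust to this, but single-variable interpretation is not).
* Stream buffering double-counts areas at sharp bends.
* No dispersal kernels, least-cost paths, or landscape resistance — the
  connectivity analysis is strictly binary barrier reachability.
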