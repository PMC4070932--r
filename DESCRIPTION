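Package: invrisk
Title: Ensemble Species Distribution Modeling and Invasion Risk Mapping
Version: 0.1.0
Authors@R: person("Jordan", "Wells", email = "jwells.eco@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting the invasion risk of
    introduced species from presence-only occurrence records and
    environmental raster layers. Cleans and spatially thins occurrences,
    builds a fractional wetland-cover predictor from classified water-body
    polygons, screens candidate predictors with an Ecological Niche Factor
    Analysis, fits an ensemble of three presence/pseudo-absence suitability
    models (a MaxEnt-style penalized log-linear model, boosted regression
    trees, and a random forest), evaluates transferability with spatially
    stratified (latitudinal band) cross-validation, binarizes suitability at
    the maximum sensitivity-plus-specificity threshold, quantifies overlap
    with native species ranges, and restricts projected risk to areas
    connected to established source populations through suitable habitat.
    Includes a synthetic-landscape generator so the whole chain is testable
    against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
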