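# End-to-end pipeline: clean -> thin -> wetland/ENFA screen ->
# pseudo-absences -> per-backend spatial CV -> final fits on all data ->
# ensemble -> Max SSS -> omission -> overlap -> connectivity -> decline.
# One configuration object drives both synthetic and user-supplied data;
# every stochastic stage records its seed, so any run is regenerable from
# the config alone.

#' Demonstration pipeline configuration (synthetic landscape)
#'
#' The stated benchmark world: a 100 x 100 grid of 0.25-degree cells
#' (25 x 25 degrees — continental scale, so the 2-degree pseudo-absence
#' exclusion is geometrically feasible), the default truth
#' ([default_truth_params()]: unimodal bio10 optimum 26 C, saturating
#' wetland response), 2000 raw records sampled from a native window in the
#' (warm) southeast of the domain, cleaned at the 5-km precision cutoff,
#' thinned on a 0.5-degree grid, and capped at 300 presences. Two synthetic
#' native ranges and automatically placed western source populations feed
#' the risk and connectivity stages.
#'
#' @param seed Master seed; each stochastic stage derives its own offset
#'   from it.
#' @param outdir Output directory for artifacts.
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1, outdir = tempfile("invrisk_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    synthetic = list(
      grid = list(origin_lon = -105, origin_lat = 45, cell_size = 0.25,
                  n_rows = 100, n_cols = 100),
      roughness = 0.8,
      native_window = c(-100, -85, 25, 40),
      n_raw = 2000,
      precision_sd_km = 2,
      n_presences_max = 300,
      n_ranges = 2,
      sources = "auto",
      n_sources = 2
    ),
    precision_max_km = 5,
    thinning_cell_deg = 0.5,
    enfa = list(temperature_layers = c("bio4", "bio10", "bio11"),
                always_keep = "wetland", r_max = 0.85,
                rank_by = "marginality"),
    pseudo = list(buffer_deg = 4, min_dist_deg = 2, n = NULL),
    backends = c("maxent_like", "boosted_trees", "random_forest"),
    hyperparams = list(),
    k = 5,
    band_method = "quantile",
    weighting = "equal",
    neighbors = 8
  )
}

pipeline_stages <- c("simulate", "clean", "screen", "pseudo", "evaluate",
                     "fit", "ensemble", "risk", "connect", "all")

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

plog <- function(state, fmt, ...) {
  msg <- sprintf(fmt, ...)
  state$log <- c(state$log, msg)
  message("[invrisk] ", msg)
  state
}

#' Run the invasion-risk pipeline
#'
#' Executes the stage chain on a configuration list (see [demo_config()] for
#' the synthetic layout; replace the `synthetic` block with `paths = list(
#' env = <named .asc paths>, occurrences = <csv>, water_bodies = <geojson>,
#' ranges = <geojson>, sources = <csv>)` for user data). All intermediate
#' artifacts, a machine-readable `summary.json`, and a `run.log` are written
#' to `config$outdir`. Two runs from the same config produce byte-identical
#' summaries.
#'
#' @param config Configuration list, or path to a JSON file holding one.
#' @param through Last stage to execute (default `"all"`): one of
#'   `"simulate"`, `"clean"`, `"screen"`, `"pseudo"`, `"evaluate"`, `"fit"`,
#'   `"ensemble"`, `"risk"`, `"connect"`, `"all"`.
#' @return Invisibly, a list with the computed objects (env, presences,
#'   models, cv, ensemble, threshold, overlap table, connectivity,
#'   summary).
#' @export
run_pipeline <- function(config, through = "all") {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  through <- match.arg(through, pipeline_stages)
  rank <- function(s) match(s, pipeline_stages)
  want <- function(s) rank(s) <= rank(ifelse(through == "all", "connect", through))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path
  st <- list(log = character(0))
  summary <- list(seed = config$seed)

  ## -- simulate / load ------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    g <- sy$grid
    grid <- grid_spec(g$origin_lon, g$origin_lat, g$cell_size, g$n_rows, g$n_cols)
    env <- generate_environment(grid, seed = config$seed, roughness = sy$roughness)
    truth <- true_suitability(env, default_truth_params())
    occ_raw <- sample_occurrences(truth, sy$native_window, sy$n_raw,
                                  precision_sd_km = sy$precision_sd_km,
                                  seed = config$seed + 1)
    wbs <- generate_water_bodies(grid, seed = config$seed + 2)
    # the synthetic wetland layer is replaced by the one built from polygons,
    # blended with the generator's diffuse marsh background
    wet_poly <- build_wetland_raster(wbs, grid)
    wet <- raster_layer(grid, pmin(env$layers$wetland$values + wet_poly$values, 1))
    env <- env_stack(bio4 = env$layers$bio4, bio10 = env$layers$bio10,
                     bio11 = env$layers$bio11, wetland = wet)
    truth <- true_suitability(env, default_truth_params())
    ranges <- generate_range_maps(grid, sy$n_ranges, seed = config$seed + 3)
    sources <- if (identical(sy$sources, "auto")) {
      auto_sources(truth, sy$native_window, sy$n_sources)
    } else as.data.frame(sy$sources)
    for (nm in names(env$layers))
      write_ascii_grid(env$layers[[nm]], out(config$outdir, paste0("env_", nm, ".asc")))
    write_ascii_grid(truth$raster, out(config$outdir, "truth.asc"))
    write_occurrences_csv(occ_raw, out(config$outdir, "occurrences_raw.csv"))
    write_water_bodies_geojson(wbs, out(config$outdir, "water_bodies.geojson"))
    write_ranges_geojson(ranges, out(config$outdir, "ranges.geojson"), grid)
    write_sources_csv(sources, out(config$outdir, "sources.csv"))
    st <- plog(st, "simulate: %d raw records, %d water bodies, %d ranges",
               nrow(occ_raw), length(wbs), length(ranges))
  } else {
    p <- config$paths
    env <- env_stack(lapply(p$env, read_ascii_grid))
    grid <- env$grid
    occ_raw <- read_occurrences_csv(p$occurrences)
    if (!is.null(p$water_bodies)) {
      wbs <- read_water_bodies_geojson(p$water_bodies)
      wet <- build_wetland_raster(wbs, grid)
      env$layers$wetland <- wet
    }
    ranges <- read_ranges_geojson(p$ranges)
    sources <- read_sources_csv(p$sources)
    truth <- NULL
    st <- plog(st, "load: %d raw records, %d ranges", nrow(occ_raw), length(ranges))
  }
  summary$n_raw <- nrow(occ_raw)
  res <- list(env = env, truth = truth, ranges = ranges, sources = sources)
  if (!want("clean")) return(finish_pipeline(res, st, summary, config))

  ## -- clean ----------------------------------------------------------------
  occ <- filter_precision(occ_raw, config$precision_max_km)
  tg <- grid_spec(grid$origin_lon, grid$origin_lat, config$thinning_cell_deg,
                  ceiling(grid$n_rows * grid$cell_size / config$thinning_cell_deg),
                  ceiling(grid$n_cols * grid$cell_size / config$thinning_cell_deg))
  occ <- thin_to_grid(occ, tg, seed = config$seed + 4)
  nmax <- config$synthetic$n_presences_max
  if (!is.null(nmax) && nrow(occ) > nmax) {
    set.seed(config$seed + 5)
    keep <- sort(sample.int(nrow(occ), nmax))
    occ <- occurrence_set(occ[keep, , drop = FALSE], provenance(occ))
  }
  write_occurrences_csv(occ, out(config$outdir, "occurrences_clean.csv"))
  write_json_file(provenance(occ), out(config$outdir, "provenance.json"))
  summary$n_clean <- nrow(occ)
  res$presences <- occ
  st <- plog(st, "clean: %d records after precision filter + thinning", nrow(occ))
  if (!want("screen")) return(finish_pipeline(res, st, summary, config))

  ## -- ENFA screen ----------------------------------------------------------
  temp_layers <- config$enfa$temperature_layers
  env_temp <- env_stack(env$layers[temp_layers])
  ef <- enfa(env_temp, occ)
  sel <- select_variables(ef, env_temp, r_max = config$enfa$r_max,
                          rank_by = config$enfa$rank_by)
  predictors <- union(sel, config$enfa$always_keep)
  write_json_file(list(marginality = as.list(ef$marginality),
                       specialization_eigenvalues = ef$specialization_eigenvalues,
                       selected = sel, predictors = predictors),
                  out(config$outdir, "enfa.json"))
  env_model <- env_stack(env$layers[predictors])
  summary$predictors <- predictors
  res$enfa <- ef; res$predictors <- predictors; res$env_model <- env_model
  st <- plog(st, "screen: ENFA kept {%s}; predictors {%s}",
             paste(sel, collapse = ","), paste(predictors, collapse = ","))
  if (!want("pseudo")) return(finish_pipeline(res, st, summary, config))

  ## -- pseudo-absences ------------------------------------------------------
  acc <- accessible_area(occ, config$pseudo$buffer_deg, grid)
  n_pa <- if (is.null(config$pseudo$n)) nrow(occ) else config$pseudo$n
  pa <- sample_pseudo_absences(occ, acc, config$pseudo$min_dist_deg, n_pa,
                               seed = config$seed + 6, env = env_model)
  write_sources_csv(pa, out(config$outdir, "pseudo_absences.csv"))
  summary$n_pseudo_absences <- nrow(pa)
  res$pseudo_absences <- pa
  st <- plog(st, "pseudo: %d pseudo-absences (min dist %.1f deg)",
             nrow(pa), config$pseudo$min_dist_deg)
  if (!want("evaluate")) return(finish_pipeline(res, st, summary, config))

  ## -- spatial CV -----------------------------------------------------------
  cv <- list()
  for (b in config$backends) {
    cv[[b]] <- spatial_cv(occ, pa, env_model, b, k = config$k,
                          hyperparams = config$hyperparams[[b]] %||% list(),
                          seed = config$seed + 7,
                          band_method = config$band_method)
    write.csv(data.frame(fold = seq_len(config$k),
                         auc = cv[[b]]$per_fold_auc),
              out(config$outdir, paste0("cv_", b, ".csv")), row.names = FALSE)
    st <- plog(st, "evaluate[%s]: mean AUC %.3f (%.3f-%.3f)", b,
               cv[[b]]$mean_auc, cv[[b]]$auc_range[1], cv[[b]]$auc_range[2])
  }
  summary$cv <- lapply(cv, function(x)
    list(mean_auc = x$mean_auc, auc_range = x$auc_range,
         per_fold_auc = x$per_fold_auc))
  res$cv <- cv
  if (!want("fit")) return(finish_pipeline(res, st, summary, config))

  ## -- final fits on all data ----------------------------------------------
  models <- list(); surfaces <- list()
  for (b in config$backends) {
    models[[b]] <- fit_model(b, occ, pa, env_model,
                             hyperparams = config$hyperparams[[b]] %||% list(),
                             seed = config$seed + 8)
    surfaces[[b]] <- predict_surface(models[[b]], env_model, clamp = TRUE)
    write_ascii_grid(surfaces[[b]]$raster,
                     out(config$outdir, paste0("surface_", b, ".asc")))
  }
  res$models <- models; res$surfaces <- surfaces
  st <- plog(st, "fit: %d final models", length(models))
  if (!want("ensemble")) return(finish_pipeline(res, st, summary, config))

  ## -- ensemble + threshold + omission --------------------------------------
  weights <- if (identical(config$weighting, "auc"))
    vapply(config$backends, function(b) cv[[b]]$mean_auc, numeric(1)) else NULL
  ens <- ensemble_mean(unname(surfaces), weights)
  write_ascii_grid(ens$raster, out(config$outdir, "ensemble.asc"))
  sp <- score_at(ens, occ$lon, occ$lat)
  sa <- score_at(ens, pa$lon, pa$lat)
  thr <- max_sss_threshold(sp[!is.na(sp)], sa[!is.na(sa)])
  omission <- omission_rate(ens, thr$threshold, occ)
  write_json_file(list(threshold = thr$threshold, sensitivity = thr$sensitivity_at,
                       specificity = thr$specificity_at, sss = thr$sss,
                       omission = omission),
                  out(config$outdir, "threshold.json"))
  summary$threshold <- thr$threshold
  summary$sensitivity <- thr$sensitivity_at
  summary$specificity <- thr$specificity_at
  summary$omission <- omission
  res$ensemble <- ens; res$threshold <- thr; res$omission <- omission
  st <- plog(st, "ensemble: Max SSS t=%.4f, omission %.3f", thr$threshold, omission)
  if (!want("risk")) return(finish_pipeline(res, st, summary, config))

  ## -- overlap --------------------------------------------------------------
  reports <- lapply(ranges, function(rm) range_overlap(ens, thr$threshold, rm))
  overlap_df <- do.call(rbind, lapply(reports, function(r) {
    q <- r$suitability_quartiles
    data.frame(species = r$species_id, n_cells = r$n_cells,
               min_whisker = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max_whisker = q[5], proportion_suitable = r$proportion_suitable,
               row.names = NULL)
  }))
  write.csv(overlap_df, out(config$outdir, "overlap.csv"), row.names = FALSE)
  res$overlap <- reports
  st <- plog(st, "risk: %d species overlap rows", nrow(overlap_df))
  if (!want("connect")) {
    summary$overlap <- overlap_df
    return(finish_pipeline(res, st, summary, config))
  }

  ## -- connectivity + decline ----------------------------------------------
  suit <- binarize(ens, thr$threshold)
  mask <- connected_suitable(suit, sources, neighbors = config$neighbors)
  write_ascii_grid(mask$reachable, out(config$outdir, "connected.asc"))
  declines <- lapply(ranges, function(rm)
    overlap_decline(ens, thr$threshold, rm, mask))
  overlap_df$connected_proportion <-
    vapply(declines, function(d) d$connected, numeric(1))
  overlap_df$decline <- vapply(declines, function(d) d$decline, numeric(1))
  write.csv(overlap_df, out(config$outdir, "overlap.csv"), row.names = FALSE)
  summary$overlap <- overlap_df
  summary$mean_decline <- mean(overlap_df$decline)
  res$connectivity <- mask; res$declines <- declines
  st <- plog(st, "connect: mean overlap decline %.4f", summary$mean_decline)
  finish_pipeline(res, st, summary, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

score_at <- function(surface, lon, lat) {
  idx <- cell_of(surface$raster$grid, lon, lat)
  vals <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  vals[ok] <- surface$raster$values[cbind(idx$row[ok], idx$col[ok])]
  vals
}

# Deterministic source placement for the synthetic demo: the highest-truth
# cells strictly west of the native window (an "introduced" region).
auto_sources <- function(truth, native_window, n_sources) {
  grid <- truth$raster$grid
  ctr <- grid_centers(grid)
  west <- ctr$lon < native_window[1]
  v <- truth$raster$values
  v[!west | is.na(v)] <- -Inf
  ord <- order(v, decreasing = TRUE)[seq_len(n_sources)]
  data.frame(lon = ctr$lon[ord], lat = ctr$lat[ord])
}

finish_pipeline <- function(res, st, summary, config) {
  writeLines(c(sprintf("invrisk %s | R %s", "0.1.0", getRversion()),
               format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               st$log),
             file.path(config$outdir, "run.log"))
  write_json_file(summary, file.path(config$outdir, "summary.json"))
  res$summary <- summary
  invisible(res)
}
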