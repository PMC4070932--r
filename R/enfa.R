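# Ecological Niche Factor Analysis for variable screening: marginality (the
# standardized shift of the species' environmental mean from the global mean)
# and specialization (variance restriction orthogonal to the marginality
# axis). Used here only to rank and screen predictors, not to map habitat.

#' Ecological Niche Factor Analysis
#'
#' All variables are standardized over the valid cells of the stack. Per
#' variable, marginality is `(presence mean - global mean) / global SD`,
#' computed over the distinct cells occupied by at least one presence.
#' Specialization factors are the eigen-decomposition of the presence
#' covariance of the standardized variables projected onto the orthogonal
#' complement of the marginality axis (single-marginality-axis, Hirzel-style
#' variant). Deterministic; marginality is invariant under affine rescaling
#' of any input variable.
#'
#' @param env An [env_stack()] with at least 2 layers.
#' @param presences An [occurrence_set()]; needs at least
#'   `n_variables + 1` distinct presence cells on valid data.
#' @return An `enfa_result`: list with `marginality` (named vector),
#'   `specialization_eigenvalues` (non-increasing, >= 0),
#'   `specialization_loadings` (variables x factors), `variable_scores`
#'   (data.frame with per-variable `marginality` and a specialization loading
#'   summary), and `n_presence_cells`.
#' @export
enfa <- function(env, presences) {
  stopifnot(inherits(env, "env_stack"), inherits(presences, "occurrence_set"))
  vars <- names(env$layers)
  p <- length(vars)
  if (p < 2) stop("need at least 2 variables")
  gm <- sapply(vars, function(nm) env$layers[[nm]]$values)  # cells x vars
  valid <- rowSums(is.na(gm)) == 0
  G <- gm[valid, , drop = FALSE]
  mu <- colMeans(G)
  sdev <- apply(G, 2, sd)
  if (any(sdev == 0))
    stop("zero global variance in variable(s): ",
         paste(vars[sdev == 0], collapse = ", "))
  Z <- sweep(sweep(G, 2, mu), 2, sdev, "/")

  idx <- cell_of(env$grid, presences$lon, presences$lat)
  lin <- (idx$col - 1L) * env$grid$n_rows + idx$row   # column-major linear index
  lin <- unique(lin[!is.na(lin)])
  # map linear cell index -> row of the valid-cell matrix
  pos <- match(lin, which(valid))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) stop("all presences fall on nodata cells")
  if (length(pos) < p + 1)
    stop("need at least n_variables + 1 presence cells with valid data")
  Zp <- Z[pos, , drop = FALSE]
  m <- colMeans(Zp)
  names(m) <- vars

  u <- m / sqrt(sum(m^2))
  if (!all(is.finite(u))) u <- rep(0, p)   # zero marginality: no projection
  H <- diag(p) - tcrossprod(u)
  Sp <- stats::cov(Zp)
  W <- H %*% Sp %*% H
  eig <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- seq_len(p - 1L)                 # one dimension lost to marginality
  lambda <- pmax(eig$values[keep], 0)
  loadings <- eig$vectors[, keep, drop = FALSE]
  rownames(loadings) <- vars
  spec_score <- sqrt(rowSums(sweep(loadings^2, 2, lambda, "*")) /
                       max(sum(lambda), .Machine$double.eps))
  structure(list(
    marginality = m,
    specialization_eigenvalues = lambda,
    specialization_loadings = loadings,
    variable_scores = data.frame(variable = vars, marginality = unname(m),
                                 specialization = unname(spec_score),
                                 stringsAsFactors = FALSE),
    n_presence_cells = length(pos)), class = "enfa_result")
}

#' @export
print.enfa_result <- function(x, ...) {
  cat("ENFA on", length(x$marginality), "variables,",
      x$n_presence_cells, "presence cells\n")
  print(x$variable_scores)
  invisible(x)
}

#' Screen variables by ENFA rank and pairwise correlation
#'
#' Variables are ranked by the chosen statistic (absolute marginality by
#' default, ties broken by specialization loading) and retained greedily
#' while their absolute Pearson correlation over valid cells with every
#' already-retained variable stays below `r_max`.
#'
#' @param enfa_result An [enfa()] result.
#' @param env The [env_stack()] the ENFA was run on.
#' @param r_max Correlation cutoff in (0, 1); default 0.85.
#' @param rank_by `"marginality"` (default) or `"specialization"`.
#' @return Character vector of retained variable names, in rank order.
#' @export
select_variables <- function(enfa_result, env, r_max = 0.85,
                             rank_by = c("marginality", "specialization")) {
  rank_by <- match.arg(rank_by)
  if (r_max <= 0 || r_max >= 1) stop("r_max must be in (0, 1)")
  sc <- enfa_result$variable_scores
  primary <- if (rank_by == "marginality") abs(sc$marginality) else sc$specialization
  secondary <- if (rank_by == "marginality") sc$specialization else abs(sc$marginality)
  ord <- order(-primary, -secondary, sc$variable)
  vars <- sc$variable[ord]
  gm <- sapply(vars, function(nm) env$layers[[nm]]$values)
  valid <- rowSums(is.na(gm)) == 0
  cm <- stats::cor(gm[valid, , drop = FALSE])
  kept <- character(0)
  for (v in vars) {
    if (length(kept) == 0 || all(abs(cm[v, kept]) < r_max))
      kept <- c(kept, v)
  }
  if (length(kept) == 0) stop("no variable passes the correlation screen")
  kept
}
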