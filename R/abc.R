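## ---------------------------------------------------------------------------
## Approximate Bayesian computation over simulator runs: prior specification,
## reference-table construction, rejection with optional local-linear
## adjustment, global sensitivity analysis and cross-validation.
## ---------------------------------------------------------------------------

#' Prior specification for the five free parameters
#'
#' Regional seed rain ~ U(100, 500) seeds/year; wind speed ~ U(1, 20) units;
#' log10 mutation rate ~ Normal(-4, 0.5) truncated to [-6, -2]; germination
#' rate ~ U(0.0083, 0.30); capture probability ~ U(0.01, 0.30).
#'
#' @return a `PriorSpec` list: per parameter, `sampler(n)` and `range`.
#' @export
priorSpec <- function() {
  truncNorm <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mean, sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  }
  structure(list(
    regionalSeedRain = list(
      sampler = function(n) stats::runif(n, 100, 500),
      range = c(100, 500)),
    windSpeed = list(
      sampler = function(n) stats::runif(n, 1, 20),
      range = c(1, 20)),
    mutationRate = list(
      sampler = function(n) 10^truncNorm(n, -4, 0.5, -6, -2),
      range = c(1e-6, 1e-2)),
    germinationRate = list(
      sampler = function(n) stats::runif(n, 0.0083, 0.30),
      range = c(0.0083, 0.30)),
    captureProbability = list(
      sampler = function(n) stats::runif(n, 0.01, 0.30),
      range = c(0.01, 0.30))),
    class = "PriorSpec")
}

#' Draw parameter vectors from the prior
#'
#' @param spec a [priorSpec()].
#' @param n number of draws.
#' @return numeric matrix `n x 5` with named columns, every draw inside its
#'   prior range.
#' @export
samplePrior <- function(spec = priorSpec(), n) {
  stopifnot(n >= 1)
  out <- vapply(spec, function(p) p$sampler(n), numeric(n))
  if (n == 1L) out <- matrix(out, 1L, dimnames = list(NULL, names(spec)))
  out
}

#' ReferenceTable: ABC store of (parameters, summary statistics)
#'
#' Every row is one simulator run: a parameter draw and the summary-
#' statistic vector computed from the simulated genotype sample by an
#' identical pipeline (landscape -> simulation -> sampling -> statistics).
#'
#' @slot params numeric matrix `n x 5`.
#' @slot stats numeric matrix `n x k` (K, R, H_E, F_IS, F_ST, NGW, plus
#'   abundance and nMLL for sensitivity analysis).
#' @slot metadata list (simulation configuration, seed, dropped rows).
#' @export
setClass("ReferenceTable", representation(
  params = "matrix", stats = "matrix", metadata = "list"))

setValidity("ReferenceTable", function(object) {
  if (nrow(object@params) != nrow(object@stats))
    "params and stats must have the same number of rows" else TRUE
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d simulations, %d parameters, %d statistics\n",
              nrow(object@params), ncol(object@params), ncol(object@stats)))
  if (length(object@metadata$dropped))
    cat(sprintf("  (%d failed rows dropped)\n",
                length(object@metadata$dropped)))
})

#' @describeIn ReferenceTable-class number of rows.
#' @param x a `ReferenceTable`.
#' @export
setMethod("nrow", "ReferenceTable", function(x) nrow(x@params))

#' Default simulation configuration for reference tables
#'
#' One calibration run simulates the empirical-like grove (20 trees on
#' 0.2 ha) for `years` years and samples up to 15 individuals on up to 15
#' occupied trees. Smaller configurations (fewer trees, shorter horizons)
#' trade fidelity for speed and are used in the shipped tests.
#'
#' @param landscape a [Landscape-class] (default the standard grove).
#' @param years simulated years per run.
#' @param maxTrees,perTree sampling caps.
#' @param pool founder [allelePool()].
#' @return a named list.
#' @export
abcSimConfig <- function(landscape = NULL, years = 20L, maxTrees = 15L,
                         perTree = 15L, pool = defaultAllelePool()) {
  list(landscape = landscape, years = years, maxTrees = maxTrees,
       perTree = perTree, pool = pool)
}

## one reference-table row: run the simulator under theta, return stats
.simulateRow <- function(theta, config) {
  params <- simParams(regionalSeedRain = theta[["regionalSeedRain"]],
                      windSpeed = theta[["windSpeed"]],
                      mutationRate = theta[["mutationRate"]],
                      germinationRate = theta[["germinationRate"]],
                      captureProbability = theta[["captureProbability"]])
  st <- simInit(config$landscape, params, config$pool)
  runSim(st, years = config$years)
  sm <- samplePopulation(st, config$maxTrees, config$perTree)
  c(statVector(sm), abundance = abundance(st), nMLL = nMLL(st))
}

#' Build an ABC reference table
#'
#' Draws `nSims` parameter vectors from the prior and runs the full pipeline
#' (simulation, sampling, summary statistics) for each. Rows whose summary
#' vector contains undefined statistics (e.g. extinct or single-tree
#' populations) are logged in the metadata and dropped, never imputed.
#'
#' @param spec a [priorSpec()].
#' @param nSims number of simulations.
#' @param config an [abcSimConfig()].
#' @param verbose print progress every 100 rows.
#' @return a [ReferenceTable-class].
#' @export
buildReferenceTable <- function(spec = priorSpec(), nSims,
                                config = abcSimConfig(), verbose = FALSE) {
  if (is.null(config$landscape))
    config$landscape <- standardGrove()
  theta <- samplePrior(spec, nSims)
  stats <- matrix(NA_real_, nSims, 8L)
  for (i in seq_len(nSims)) {
    stats[i, ] <- .simulateRow(theta[i, ], config)
    if (verbose && i %% 100L == 0L)
      message("reference table: ", i, "/", nSims)
  }
  colnames(stats) <- c("K", "R", "H_E", "F_IS", "F_ST", "NGW",
                       "abundance", "nMLL")
  ok <- stats::complete.cases(stats)
  new("ReferenceTable",
      params = theta[ok, , drop = FALSE],
      stats = stats[ok, , drop = FALSE],
      metadata = list(config = config[c("years", "maxTrees", "perTree")],
                      dropped = which(!ok)))
}

#' Write / read a reference table as CSV
#' @param table a [ReferenceTable-class].
#' @param file CSV path.
#' @export
writeReferenceTable <- function(table, file) {
  utils::write.csv(cbind(as.data.frame(table@params),
                         as.data.frame(table@stats)),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeReferenceTable
#' @param nParams number of leading parameter columns (default 5).
#' @export
readReferenceTable <- function(file, nParams = 5L) {
  d <- utils::read.csv(file)
  new("ReferenceTable",
      params = as.matrix(d[, seq_len(nParams), drop = FALSE]),
      stats = as.matrix(d[, -seq_len(nParams), drop = FALSE]),
      metadata = list())
}

#' Rejection ABC with optional local-linear adjustment
#'
#' Statistics are standardized by their median absolute deviation, rows
#' ranked by Euclidean distance to the observed vector, and the `tolerance`
#' fraction retained (at least one row; ties broken by row index). With
#' `adjust = "loclinear"`, retained parameters are corrected by an
#' Epanechnikov-weighted local-linear regression on the statistics
#' (Beaumont-style), clipped back to the prior ranges.
#'
#' @param observed named numeric vector of observed statistics (any subset
#'   of the table's statistic columns).
#' @param table a [ReferenceTable-class].
#' @param tolerance retained fraction (default 0.001).
#' @param adjust `"none"` or `"loclinear"`.
#' @param spec prior ranges used for clipping adjusted draws.
#' @return list with `posterior` (matrix of retained parameter vectors),
#'   `ci` (2.5/50/97.5% per parameter), `retained` (row indices),
#'   `distances`.
#' @export
abcReject <- function(observed, table, tolerance = 0.001,
                      adjust = c("none", "loclinear"), spec = priorSpec()) {
  adjust <- match.arg(adjust)
  useStats <- intersect(names(observed), colnames(table@stats))
  if (!length(useStats)) stop("no overlapping statistics")
  S <- table@stats[, useStats, drop = FALSE]
  obs <- observed[useStats]
  scale <- apply(S, 2L, stats::mad)
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warning("dropping degenerate statistic column(s): ",
            paste(useStats[degenerate], collapse = ", "))
    S <- S[, !degenerate, drop = FALSE]
    obs <- obs[!degenerate]
    scale <- scale[!degenerate]
  }
  n <- nrow(S)
  nKeep <- max(1L, as.integer(round(tolerance * n)))
  if (nKeep > n) stop("tolerance retains more rows than the table holds")
  Z <- sweep(S, 2L, scale, "/")
  zObs <- obs / scale
  d <- sqrt(rowSums(sweep(Z, 2L, zObs, "-")^2))
  retained <- order(d)[seq_len(nKeep)]   # order() breaks ties by row index
  post <- table@params[retained, , drop = FALSE]
  if (adjust == "loclinear" && nKeep >= ncol(S) + 2L) {
    dMax <- max(d[retained])
    w <- if (dMax > 0) 1 - (d[retained] / dMax)^2 else rep(1, nKeep)
    w <- pmax(w, 1e-8)
    X <- sweep(Z[retained, , drop = FALSE], 2L, zObs, "-")
    for (j in seq_len(ncol(post))) {
      fit <- stats::lm.wfit(cbind(1, X), post[, j], w)
      beta <- fit$coefficients[-1L]
      beta[is.na(beta)] <- 0
      post[, j] <- post[, j] - X %*% beta
      rng <- spec[[colnames(post)[j]]]$range
      if (!is.null(rng)) post[, j] <- pmin(pmax(post[, j], rng[1]), rng[2])
    }
  }
  ci <- apply(post, 2L, stats::quantile, c(0.025, 0.5, 0.975))
  list(posterior = post, ci = ci, retained = retained, distances = d)
}

#' Global sensitivity analysis of the reference table
#'
#' Spearman rank correlation (with sign and p-value) between each parameter
#' and each output column of the table — a variance-free screening of which
#' statistics respond to which parameters.
#'
#' @param table a [ReferenceTable-class].
#' @return data.frame with `parameter, statistic, rho, p`.
#' @export
sensitivityAnalysis <- function(table) {
  stopifnot(nrow(table@params) >= 10L)
  out <- expand.grid(parameter = colnames(table@params),
                     statistic = colnames(table@stats),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    ct <- suppressWarnings(stats::cor.test(
      table@params[, out$parameter[i]], table@stats[, out$statistic[i]],
      method = "spearman"))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Cross-validation of ABC parameter recovery
#'
#' Holds out `nFolds` randomly chosen rows one at a time, estimates each
#' held-out parameter vector by rejection ABC against the remaining rows
#' (posterior median, optionally adjusted), and reports the correlation
#' between true and estimated values per parameter.
#'
#' @param table a [ReferenceTable-class].
#' @param nFolds held-out rows (default 100).
#' @param tolerance ABC tolerance within each fold.
#' @param adjust passed to [abcReject()].
#' @param statCols statistic columns used as the ABC summary vector
#'   (default the six calibration statistics).
#' @return data.frame `parameter, r, p` (Pearson), plus attribute
#'   `"estimates"` holding the true/estimated matrix.
#' @export
crossValidate <- function(table, nFolds = 100L, tolerance = 0.01,
                          adjust = "none",
                          statCols = c("K", "R", "H_E", "F_IS", "F_ST",
                                       "NGW")) {
  n <- nrow(table@params)
  stopifnot(n >= 20L)
  statCols <- intersect(statCols, colnames(table@stats))
  folds <- sample.int(n, min(nFolds, n))
  est <- matrix(NA_real_, length(folds), ncol(table@params),
                dimnames = list(NULL, colnames(table@params)))
  for (k in seq_along(folds)) {
    i <- folds[k]
    sub <- new("ReferenceTable",
               params = table@params[-i, , drop = FALSE],
               stats = table@stats[-i, , drop = FALSE],
               metadata = list())
    res <- abcReject(table@stats[i, statCols], sub, tolerance, adjust)
    est[k, ] <- apply(res$posterior, 2L, stats::median)
  }
  truth <- table@params[folds, , drop = FALSE]
  out <- data.frame(parameter = colnames(truth), r = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(truth))) {
    ct <- stats::cor.test(truth[, j], est[, j])
    out$r[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
  }
  attr(out, "estimates") <- list(truth = truth, estimated = est)
  out
}
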