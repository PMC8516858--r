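## ---------------------------------------------------------------------------
## Experiment drivers: the three study families (time, density, dynamic),
## the standard grove layout, and programmatic fixture generators.
## ---------------------------------------------------------------------------

## deterministic per-replicate seed from a master seed
deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * i) %% 2147483647) + 1L
}

## evaluate `code` under a temporary RNG seed, restoring the caller's RNG
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a grove layout like the empirical study site
#'
#' Twenty trees on ca. 0.2 ha (50 x 40 m, ca. 100 trees/ha), pairwise
#' distances between 2.5 and 47.5 m, equal crowns, similar ages. Placement
#' is rejection-sampled from the uniform distribution under the distance
#' constraints.
#'
#' @param nTrees number of trees (default 20).
#' @param extent landscape size in metres (default 50 x 40 = 0.2 ha).
#' @param distRange admissible pairwise tree distances (m).
#' @param crownRadius common crown radius (m); the default is calibrated so
#'   the grove's one-plant-per-patch carrying capacity matches the observed
#'   stationary population size (see the methods vignette).
#' @param dbh,height tree size (similar-aged stand).
#' @param margin minimum distance from the landscape boundary (m).
#' @return a [Landscape-class].
#' @export
makeGrove <- function(nTrees = 20L, extent = c(50, 40),
                      distRange = c(2.5, 47.5), crownRadius = 1.4,
                      dbh = 25, height = 8, margin = 1.5) {
  lo <- margin
  hx <- extent[1] - margin; hy <- extent[2] - margin
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < nTrees) {
    x <- stats::runif(1, lo, hx); y <- stats::runif(1, lo, hy)
    ok <- TRUE
    if (length(xs)) {
      d <- sqrt((xs - x)^2 + (ys - y)^2)
      ok <- all(d >= distRange[1]) && all(d <= distRange[2])
    }
    if (ok) { xs <- c(xs, x); ys <- c(ys, y) }
    tries <- tries + 1L
    if (tries > 20000L) { xs <- numeric(0); ys <- numeric(0); tries <- 0L }
  }
  buildLayout(
    data.frame(id = seq_len(nTrees), x = xs, y = ys, dbh = dbh,
               height = height + stats::runif(nTrees, -1, 1),
               crown = crownRadius),
    extent = extent)
}

#' The standard study grove
#'
#' A fixed 20-tree, 0.2-ha grove layout (built once with an internal seed)
#' used as the default landscape for time simulations and ABC calibration,
#' so that all sessions simulate the same stand.
#'
#' @param ... overrides passed to [makeGrove()].
#' @return a [Landscape-class].
#' @export
standardGrove <- function(...) {
  withSeed(42L, makeGrove(...))
}

## yearly record of one simulation state
.yearRecord <- function(state, year, maxTrees, perTree, withStats = TRUE) {
  rec <- data.frame(year = year,
                    abundance = abundance(state),
                    nMLL = nMLL(state),
                    cloneFraction = cloneFraction(state),
                    treeDensity = treeDensity(state$landscape),
                    groundCover = groundCover(state$landscape))
  if (withStats) {
    sm <- samplePopulation(state, maxTrees, perTree)
    rec <- cbind(rec, as.data.frame(as.list(statVector(sm))))
    rec$A <- if (nrow(sm@genotypes))
      mean(diversityStats(sm)$perSubpop$A) else NA_real_
  } else rec$A <- NA_real_
  rec
}

#' Run the time experiment
#'
#' Replicated 50-year simulations of epiphyte spread on the static study
#' grove, recording yearly abundance, lineage counts, clone fraction and the
#' genetic summary statistics from a <= `perTree`-per-tree sample.
#'
#' @param landscape the grove (default [standardGrove()]).
#' @param params simulation parameters (default [posteriorMedianParams()]).
#' @param years simulated years (default 50).
#' @param replicates number of replicates.
#' @param seed master seed; replicate seeds derive deterministically from it.
#' @param maxTrees,perTree sampling caps (time simulations sample every
#'   occupied tree of the grove, so `maxTrees` defaults to the tree count).
#' @param pool founder [allelePool()].
#' @return list with `records` (per replicate-year data.frame), `summary`
#'   (per-year means with 95% CI of abundance/nMLL/F_ST), and `phases`
#'   (see [detectPhases()]).
#' @export
runTimeExperiment <- function(landscape = standardGrove(),
                              params = posteriorMedianParams(),
                              years = 50L, replicates = 20L, seed = 1L,
                              maxTrees = NULL, perTree = 15L,
                              pool = defaultAllelePool()) {
  if (is.null(maxTrees)) maxTrees <- sum(landscape@trees$alive)
  records <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    records[[r]] <- withSeed(deriveSeed(seed, r), {
      st <- simInit(landscape, params, pool)
      out <- vector("list", years)
      for (y in seq_len(years)) {
        runSim(st, months = 12L)
        out[[y]] <- .yearRecord(st, y, maxTrees, perTree)
      }
      cbind(replicate = r, do.call(rbind, out))
    })
  }
  records <- do.call(rbind, records)
  summary <- summarizeTrajectories(records)
  list(records = records, summary = summary,
       phases = detectPhases(summary$abundance_mean))
}

#' Pool replicate trajectories into yearly means and 95% CIs
#'
#' @param records output `records` of a time/dynamic experiment.
#' @return data.frame keyed by year with `<var>_mean, <var>_lo, <var>_hi`.
#' @export
summarizeTrajectories <- function(records) {
  vars <- setdiff(names(records), c("replicate", "year"))
  out <- data.frame(year = sort(unique(records$year)))
  for (v in vars) {
    m <- tapply(records[[v]], records$year, mean, na.rm = TRUE)
    s <- tapply(records[[v]], records$year, stats::sd, na.rm = TRUE)
    nn <- tapply(!is.na(records[[v]]), records$year, sum)
    se <- s / sqrt(pmax(nn, 1))
    out[[paste0(v, "_mean")]] <- as.numeric(m)
    out[[paste0(v, "_lo")]] <- as.numeric(m - 1.96 * se)
    out[[paste0(v, "_hi")]] <- as.numeric(m + 1.96 * se)
  }
  out
}

#' Detect Lag / Log / Stationary phases from an abundance trajectory
#'
#' Phases are read off the growth rate of the (smoothed) replicate-mean
#' abundance curve: the Lag phase ends in the last year before the yearly
#' increment first exceeds 10% of its maximum, and the Log phase ends when
#' the increment, past its maximum, falls below 50% of it. The plateau is
#' the mean abundance over the last fifth of the series.
#'
#' @param abund yearly mean abundance vector (year 1..n).
#' @return list with `lagEnd`, `logEnd`, `plateau`.
#' @export
detectPhases <- function(abund) {
  n <- length(abund)
  plateau <- mean(abund[max(1, n - floor(n / 5) + 1):n])
  inc <- diff(abund)
  if (length(inc) >= 3L)  # 3-year running mean
    inc <- stats::filter(inc, rep(1 / 3, 3), sides = 2L)
  inc[is.na(inc)] <- 0
  gmax <- max(inc)
  peakAt <- which.max(inc)
  up <- which(inc > 0.1 * gmax)
  lagEnd <- if (length(up)) max(up[1] - 1L, 1L) else n
  down <- which(seq_along(inc) > peakAt & inc < 0.5 * gmax)
  logEnd <- if (length(down)) down[1] + 1L else n
  list(lagEnd = lagEnd, logEnd = logEnd, plateau = plateau)
}

#' Run the density experiment
#'
#' Simulates `years` years of spread on random static landscapes of
#' `areaHa` hectares over a sweep of tree counts, recording the state after
#' the final year and locating the turning-point densities (lowest
#' abundance, lowest F_ST, highest abundance).
#'
#' @param nTreesSweep tree counts per landscape (default 5-150 on 0.4 ha,
#'   i.e. 12.5-375 trees/ha).
#' @param areaHa landscape area (default 0.40).
#' @param crownRadius common crown radius of the random stands.
#' @param years years per run (default 30).
#' @param replicates replicates per density.
#' @param params,pool,seed,maxTrees,perTree as in [runTimeExperiment()].
#' @return list with `records`, `byDensity` (per-density means) and
#'   `turningPoints` (D1 lowest abundance, D2 lowest F_ST, D3 highest
#'   abundance, D4 highest density).
#' @export
runDensityExperiment <- function(nTreesSweep = c(5, 25, 50, 75, 110, 150),
                                 areaHa = 0.40, crownRadius = 3,
                                 years = 30L, replicates = 3L,
                                 params = posteriorMedianParams(),
                                 pool = defaultAllelePool(), seed = 1L,
                                 maxTrees = 15L, perTree = 15L) {
  grid <- expand.grid(rep = seq_len(replicates), nTrees = nTreesSweep)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows[[i]] <- withSeed(deriveSeed(seed, i), {
      L <- buildStaticLandscape(areaHa, grid$nTrees[i],
                                crownRadius = crownRadius)
      st <- simInit(L, params, pool)
      runSim(st, years = years)
      cbind(nTrees = grid$nTrees[i], replicate = grid$rep[i],
            .yearRecord(st, years, maxTrees, perTree))
    })
  }
  records <- do.call(rbind, rows)
  records$density <- records$nTrees / areaHa
  agg <- stats::aggregate(
    records[, c("abundance", "nMLL", "F_ST", "H_E", "A")],
    by = list(density = records$density), FUN = mean, na.rm = TRUE)
  tp <- list(
    D1 = agg$density[which.min(agg$abundance)],
    D2 = agg$density[which.min(agg$F_ST)],
    D3 = agg$density[which.max(agg$abundance)],
    D4 = max(agg$density))
  list(records = records, byDensity = agg, turningPoints = tp)
}

#' Run the dynamic experiment
#'
#' Thirty years of spread on a static landscape, then an abrupt density
#' change (deforestation of a high-density stand or reforestation of a
#' low-density stand), then `yearsDynamic` further years with the stand
#' evolving through growth, Yoda self-thinning and natural regeneration.
#' Yearly records include tree density and ground cover.
#'
#' @param initialTreesPerHa starting density (175 low / 375 high).
#' @param mode,magnitude the density-change event (see
#'   [applyDensityChange()]); magnitude 0 means no anthropogenic change.
#' @param areaHa landscape area.
#' @param crownRadius initial common crown radius.
#' @param yearsStatic,yearsDynamic phase durations (default 30 + 30).
#' @param regenRate,yodaK,allometry stand dynamics (see
#'   [stepTreeDynamics()]).
#' @param params,pool,seed,maxTrees,perTree as in [runTimeExperiment()].
#' @param replicates number of replicates.
#' @return list with `records` and `summary`.
#' @export
runDynamicExperiment <- function(initialTreesPerHa = 375,
                                 mode = "deforest", magnitude = 0,
                                 areaHa = 0.40, crownRadius = 3,
                                 yearsStatic = 30L, yearsDynamic = 30L,
                                 regenRate = 0.15, yodaK = NULL,
                                 allometry = treeAllometry(),
                                 params = posteriorMedianParams(),
                                 pool = defaultAllelePool(), seed = 1L,
                                 maxTrees = 15L, perTree = 15L,
                                 replicates = 1L) {
  if (is.null(yodaK)) yodaK <- defaultYodaK()
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    out[[r]] <- withSeed(deriveSeed(seed, r), {
      L <- buildStaticLandscape(areaHa, round(initialTreesPerHa * areaHa),
                                crownRadius = crownRadius)
      st <- simInit(L, params, pool)
      recs <- vector("list", yearsStatic + yearsDynamic)
      for (y in seq_len(yearsStatic)) {
        runSim(st, months = 12L)
        recs[[y]] <- .yearRecord(st, y, maxTrees, perTree)
      }
      ev <- applyDensityChange(st$landscape, mode, magnitude, allometry)
      setLandscape(st, ev$landscape)
      for (y in yearsStatic + seq_len(yearsDynamic)) {
        dyn <- stepTreeDynamics(st$landscape, dt = 1, regenRate = regenRate,
                                yodaK = yodaK, allometry = allometry)
        setLandscape(st, dyn$landscape)
        runSim(st, months = 12L)
        recs[[y]] <- .yearRecord(st, y, maxTrees, perTree)
      }
      cbind(replicate = r, do.call(rbind, recs))
    })
  }
  records <- do.call(rbind, out)
  list(records = records, summary = summarizeTrajectories(records))
}

#' Self-thinning constant calibrated for ~180 trees/ha equilibrium
#'
#' The Yoda line `N_max/ha = (K / mean(dbh^3))^(2/3)` with this `K` makes
#' unmanaged forest stands (3 m initial crowns, 15%/yr regeneration,
#' 0.13 cm/yr growth, saplings at 5 cm DBH) converge to densities near
#' 180 trees/ha over a 60-year horizon, whatever the starting density.
#'
#' @return the constant `K`.
#' @export
defaultYodaK <- function() 3.0e8

#' Generate deterministic test fixtures
#'
#' Small, reproducible inputs for tests and examples: `toy_grove` (the
#' 20-tree layout CSV), `toy_genotypes` (founder panel, Genepop),
#' `hwe_panel` (Hardy-Weinberg genotypes, Genepop), `selfing_pedigree`
#' (parent + selfed offspring + unrelated reference pool, Genepop).
#'
#' @param kind fixture to generate.
#' @param dir output directory.
#' @param seed RNG seed.
#' @return invisible path(s) of the file(s) written.
#' @export
makeFixtures <- function(kind = c("toy_grove", "toy_genotypes", "hwe_panel",
                                  "selfing_pedigree"),
                         dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  withSeed(seed, {
    path <- file.path(dir, paste0(kind, if (kind == "toy_grove") ".csv"
                                        else ".gen"))
    if (kind == "toy_grove") {
      writeTreeLayout(makeGrove(), path)
    } else if (kind == "toy_genotypes") {
      pool <- defaultAllelePool()
      g <- randomFounderGenotype(pool, 40L)
      writeGenepop(sampleMatrix(g, rep(c("a", "b"), each = 20L)), path,
                   title = "synthetic founder panel")
    } else if (kind == "hwe_panel") {
      writeGenepop(hwePanel(nPerPop = 30L, nPops = 3L), path,
                   title = "synthetic HWE panel")
    } else {
      writeGenepop(selfingPedigree()$sample, path,
                   title = "synthetic selfing pedigree")
    }
    invisible(path)
  })
}

#' Synthetic Hardy-Weinberg genotype panel
#'
#' All subpopulations drawn from one allele pool with independent alleles —
#' the null panel for F_IS and F_ST checks.
#'
#' @param nPerPop individuals per subpopulation.
#' @param nPops subpopulations.
#' @param pool an [allelePool()].
#' @return a [SampleMatrix-class].
#' @export
hwePanel <- function(nPerPop = 30L, nPops = 2L, pool = defaultAllelePool()) {
  n <- nPerPop * nPops
  g <- drawHW(pool, n)
  sampleMatrix(g, rep(paste0("p", seq_len(nPops)), each = nPerPop),
               coords = cbind(stats::runif(n, 0, 50),
                              stats::runif(n, 0, 50)))
}

## n Hardy-Weinberg genotypes from a pool (two independent allele draws)
drawHW <- function(pool, n) {
  L <- length(pool$sizes)
  g <- matrix(0L, n, 2L * L)
  for (l in seq_len(L)) {
    a <- pool$sizes[[l]]; f <- pool$freqs[[l]]
    a1 <- a[sample.int(length(a), n, TRUE, f)]
    a2 <- a[sample.int(length(a), n, TRUE, f)]
    g[, 2L * l - 1L] <- pmin(a1, a2)
    g[, 2L * l] <- pmax(a1, a2)
  }
  g
}

#' Synthetic selfing pedigree
#'
#' Several unrelated, non-inbred (Hardy-Weinberg) parents, each with selfed
#' offspring, embedded in a large unrelated reference pool — the oracle
#' panel for kinship checks: parent-selfed-offspring kinship is 0.5 for a
#' non-inbred parent.
#'
#' @param nFamilies number of independent selfing parents.
#' @param offspringPerFamily selfed offspring per parent.
#' @param nReference unrelated reference individuals.
#' @param pool an [allelePool()].
#' @return list with `sample` (a [SampleMatrix-class]; parents first, then
#'   offspring family by family, then the reference pool) and `pairs`
#'   (matrix of parent-offspring index pairs).
#' @export
selfingPedigree <- function(nFamilies = 10L, offspringPerFamily = 2L,
                            nReference = 150L,
                            pool = defaultAllelePool()) {
  parents <- drawHW(pool, nFamilies)
  off <- selfOffspring(
    parents[rep(seq_len(nFamilies), each = offspringPerFamily), ,
            drop = FALSE], mu = 0)
  ref <- drawHW(pool, nReference)
  g <- rbind(parents, off, ref)
  nFam <- nFamilies * (1L + offspringPerFamily)
  sm <- sampleMatrix(g, rep(c("fam", "ref"), c(nFam, nReference)))
  list(sample = sm,
       pairs = cbind(rep(seq_len(nFamilies), each = offspringPerFamily),
                     nFamilies + seq_len(nFamilies * offspringPerFamily)))
}
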