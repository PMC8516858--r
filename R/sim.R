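#' @useDynLib ballmoss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Initialize a simulation state
#'
#' Builds the mutable engine state for an epiphyte spread simulation: an
#' empty plant population on the given landscape, a fresh genotype registry,
#' an occupancy raster (at most one established plant per 0.01 m2 patch) and
#' a host-ownership raster (each crown patch belongs to the tallest covering
#' tree, the one whose canopy surface an arriving seed meets first).
#'
#' @param landscape a [Landscape-class].
#' @param params a [simParams()] list.
#' @param pool an [allelePool()] supplying founder genotypes.
#' @return a `SimState` environment.
#' @export
simInit <- function(landscape, params = simParams(),
                    pool = defaultAllelePool()) {
  s <- new.env(parent = emptyenv())
  s$params <- params
  s$pool <- pool
  s$registry <- newLineageRegistry(length(pool$sizes))
  s$month <- 0L
  s$age <- integer(0); s$energy <- numeric(0)
  s$host <- integer(0); s$px <- integer(0); s$py <- integer(0)
  s$geno <- integer(0); s$mll <- integer(0)
  s$origin <- integer(0); s$repro <- logical(0)
  s$nextMll <- 0L
  s$foundersGerminated <- 0L
  class(s) <- "SimState"
  setLandscape(s, landscape)
  s$occ <- matrix(FALSE, nrow(landscape@canopy), ncol(landscape@canopy))
  s
}

#' @export
print.SimState <- function(x, ...) {
  cat(sprintf(
    "SimState: month %d (%.1f y), %d plants, %d MLLs, clone fraction %.2f\n",
    x$month, x$month / 12, length(x$age), nMLL(x), cloneFraction(x)))
  invisible(x)
}

#' Replace the landscape of a running simulation
#'
#' Used by the dynamic experiments after tree growth, thinning or abrupt
#' density changes. Host and crown bookkeeping is rebuilt; plants whose host
#' tree died are removed at the next mortality stage.
#'
#' @param state a `SimState`.
#' @param landscape the updated [Landscape-class].
#' @return the state, invisibly.
#' @export
setLandscape <- function(state, landscape) {
  state$landscape <- landscape
  tr <- landscape@trees
  ids <- tr$id
  alive <- logical(if (length(ids)) max(ids) else 0L)
  alive[ids[tr$alive]] <- TRUE
  state$treeAlive <- alive
  ny <- nrow(landscape@canopy)
  owner <- matrix(0L, ny, ncol(landscape@canopy))
  liveIds <- ids[tr$alive]
  crownIdx <- vector("list", length(liveIds))
  names(crownIdx) <- as.character(liveIds)
  for (id in liveIds[order(tr$height[match(liveIds, ids)])]) {
    cp <- crownPatches(landscape, id)
    lin <- cp[, "px"] * ny + cp[, "py"] + 1L
    owner[lin] <- id
    crownIdx[[as.character(id)]] <- lin
  }
  state$owner <- owner
  state$crownIdx <- crownIdx
  invisible(state)
}

#' Monthly energy update
#'
#' `energy + gain * (1 - shading) - maintenance`, floored at zero. Exposed
#' as a pure function so the energy arithmetic is directly testable; the
#' engine applies it with the shading each plant experiences (crown layers
#' above its host's canopy surface).
#'
#' @param energy current energy units.
#' @param shading shading fraction in `[0, 1]`.
#' @param params a [simParams()] list.
#' @export
energyUpdate <- function(energy, shading, params = simParams()) {
  stopifnot(all(shading >= 0), all(shading <= 1))
  pmax(energy + params$energyGain * (1 - shading) - params$maintenance, 0)
}

## drop plants at index `idx`, freeing their patches
removePlants <- function(state, idx) {
  if (!length(idx)) return(invisible(state))
  state$occ[cbind(state$py[idx] + 1L, state$px[idx] + 1L)] <- FALSE
  keep <- setdiff(seq_along(state$age), idx)
  for (f in c("age", "energy", "host", "px", "py", "geno", "mll",
              "origin", "repro"))
    state[[f]] <- state[[f]][keep]
  invisible(state)
}

## append plants; patches must be free (caller guarantees)
addPlants <- function(state, host, px, py, geno, mll, origin) {
  n <- length(host)
  if (!n) return(invisible(state))
  p <- state$params
  state$age <- c(state$age, integer(n))
  state$energy <- c(state$energy, rep(p$initialEnergy, n))
  state$host <- c(state$host, host)
  state$px <- c(state$px, px); state$py <- c(state$py, py)
  state$geno <- c(state$geno, geno); state$mll <- c(state$mll, mll)
  state$origin <- c(state$origin, origin)
  state$repro <- c(state$repro, logical(n))
  state$occ[cbind(py + 1L, px + 1L)] <- TRUE
  invisible(state)
}

#' Germination draws for attached seeds
#'
#' @param n number of attached seeds.
#' @param rate germination probability.
#' @return logical vector: which seeds germinate.
#' @export
germinateSeeds <- function(n, rate) {
  stopifnot(rate >= 0, rate <= 1)
  stats::runif(n) < rate
}

#' Wind dispersal from a point
#'
#' Releases `n` seeds at `(x, y)` metres and flies each in a uniform random
#' direction for up to `5 * windSpeed` patches, attempting canopy capture at
#' every crown patch crossed. Pure wrapper over the engine's dispersal
#' kernel, for inspection and tests.
#'
#' @param landscape a [Landscape-class].
#' @param x,y release point (metres).
#' @param n number of seeds.
#' @param windSpeed wind units (5 patches each).
#' @param capture canopy capture probability.
#' @param windPatchFactor patches per wind unit.
#' @return data.frame with `px, py` (0-based landing patch) and `attached`;
#'   unattached seeds have `NA` patches.
#' @export
disperseFrom <- function(landscape, x, y, n, windSpeed, capture,
                         windPatchFactor = 5L) {
  ps <- landscape@patchSize
  ny <- nrow(landscape@canopy)
  land <- .disperseSeeds(rep(x / ps, n), rep(y / ps, n),
                         as.integer(round(windSpeed * windPatchFactor)),
                         landscape@canopy, capture)
  att <- land >= 0L
  data.frame(px = ifelse(att, land %/% ny, NA_integer_),
             py = ifelse(att, land %% ny, NA_integer_),
             attached = att)
}

## entry points of regional seeds: uniform on the landscape perimeter,
## in patch units
edgeEntryPoints <- function(nx, ny, n) {
  eps <- 1e-3
  t <- stats::runif(n, 0, 2 * (nx + ny))
  x <- numeric(n); y <- numeric(n)
  b <- t < nx                        # bottom
  x[b] <- t[b];                 y[b] <- eps
  r <- t >= nx & t < nx + ny         # right
  x[r] <- nx - eps;             y[r] <- t[r] - nx
  tp <- t >= nx + ny & t < 2 * nx + ny  # top
  x[tp] <- t[tp] - nx - ny;     y[tp] <- ny - eps
  l <- t >= 2 * nx + ny              # left
  x[l] <- eps;                  y[l] <- t[l] - 2 * nx - ny
  cbind(x = x, y = y)
}

#' Advance the simulation one month
#'
#' Stage order within a step: energy update, mortality (lifespan reached,
#' energy exhausted, or host tree dead), then — in the reproductive-season
#' month — one-shot reproduction (ramet + seed cohorts), wind dispersal,
#' regional seed rain, germination and establishment, and finally the age
#' and month increments.
#'
#' @param state a `SimState` (modified in place).
#' @return the state, invisibly.
#' @export
simStep <- function(state) {
  p <- state$params
  L <- state$landscape
  ny <- nrow(L@canopy)
  n <- length(state$age)

  if (n) {
    k <- pmax(L@canopy[cbind(state$py + 1L, state$px + 1L)] - 1L, 0L)
    shade <- 1 - (1 - p$perLayerShading)^k
    state$energy <- energyUpdate(state$energy, shade, p)
    dead <- which(state$energy <= 0 |
                  state$age >= p$lifespanMonths |
                  !state$treeAlive[state$host])
    removePlants(state, dead)
  }

  if (state$month %% 12L == p$seasonMonth) {
    ## --- reproduction: ramets + seed cohorts ------------------------------
    elig <- which(state$age >= p$maturityMonths &
                  state$energy >= p$reproThreshold & !state$repro)
    sx <- numeric(0); sy <- numeric(0)
    sGeno <- integer(0); sMll <- integer(0)
    if (length(elig)) {
      for (h in unique(state$host[elig])) {
        who <- elig[state$host[elig] == h]
        free <- state$crownIdx[[as.character(h)]]
        free <- free[!state$occ[free]]
        m <- min(length(who), length(free))
        if (m > 0L) {
          sel <- if (length(free) == 1L) free else sample(free, m)
          par <- if (length(who) == 1L) who else sample(who, m)
          g <- state$geno[par]
          if (p$somaticMutationRate > 0) {
            gm <- mlgGenotypes(state$registry, g)
            gm[] <- mutateAllele(as.vector(gm), p$somaticMutationRate)
            g <- assignMLG(state$registry, gm)
          }
          addPlants(state,
                    host = rep(h, m),
                    px = (sel - 1L) %/% ny, py = (sel - 1L) %% ny,
                    geno = g, mll = state$mll[par],
                    origin = rep(2L, m))
        }
      }
      cohorts <- floor(state$energy[elig] / p$reproThreshold)
      nSeeds <- as.integer(cohorts) * p$seedsPerUnit
      sx <- rep(state$px[elig] + 0.5, nSeeds)
      sy <- rep(state$py[elig] + 0.5, nSeeds)
      sGeno <- rep(state$geno[elig], nSeeds)
      sMll <- rep(state$mll[elig], nSeeds)
      state$energy[elig] <- p$reproReserve
      state$repro[elig] <- TRUE
    }
    ## --- regional seed rain ----------------------------------------------
    nReg <- as.integer(round(p$regionalSeedRain))
    if (nReg > 0L) {
      ep <- edgeEntryPoints(ncol(L@canopy), ny, nReg)
      sx <- c(sx, ep[, "x"]); sy <- c(sy, ep[, "y"])
    }
    nLocal <- length(sGeno)
    ## --- dispersal, germination, establishment ---------------------------
    if (length(sx)) {
      land <- .disperseSeeds(sx, sy,
                             as.integer(round(p$windSpeed * p$windPatchFactor)),
                             L@canopy, p$captureProbability)
      germ <- land >= 0L & germinateSeeds(length(land), p$germinationRate)
      idx <- which(germ)
      if (length(idx)) {
        lin <- land[idx] + 1L           # R linear index into rasters
        ok <- !state$occ[lin]
        idx <- idx[ok]; lin <- lin[ok]
        if (length(idx) > 1L) {         # one winner per contested patch
          ord <- sample.int(length(idx))
          first <- !duplicated(lin[ord])
          idx <- idx[ord][first]; lin <- lin[ord][first]
        }
        if (length(idx)) {
          isLocal <- idx <= nLocal
          px <- (lin - 1L) %/% ny; py <- (lin - 1L) %% ny
          hostId <- state$owner[lin]
          if (any(isLocal)) {
            i <- which(isLocal)
            off <- selfOffspring(
              mlgGenotypes(state$registry, sGeno[idx[i]]), p$mutationRate)
            gid <- assignMLG(state$registry, off)
            addPlants(state, hostId[i], px[i], py[i], gid,
                      sMll[idx[i]], rep(1L, length(i)))
          }
          if (any(!isLocal)) {
            i <- which(!isLocal)
            fg <- randomFounderGenotype(state$pool, length(i), p$targetHet)
            gid <- assignMLG(state$registry, fg)
            mllIds <- state$nextMll + seq_along(i)
            state$nextMll <- state$nextMll + length(i)
            state$foundersGerminated <- state$foundersGerminated + length(i)
            addPlants(state, hostId[i], px[i], py[i], gid, mllIds,
                      rep(1L, length(i)))
          }
        }
      }
    }
  }

  state$age <- state$age + 1L
  state$month <- state$month + 1L
  invisible(state)
}

#' Run the simulation for a number of months or years
#'
#' @param state a `SimState`.
#' @param months,years duration (give one).
#' @return the state, invisibly.
#' @export
runSim <- function(state, months = NULL, years = NULL) {
  if (is.null(months)) months <- 12L * years
  for (i in seq_len(months)) simStep(state)
  invisible(state)
}

#' Population summaries of a simulation state
#'
#' @param state a `SimState`.
#' @return `abundance`: number of live plants; `nMLL`: number of extant
#'   multilocus lineages; `cloneFraction`: fraction of live plants of clonal
#'   origin.
#' @export
abundance <- function(state) length(state$age)

#' @rdname abundance
#' @export
nMLL <- function(state) length(unique(state$mll))

#' @rdname abundance
#' @export
cloneFraction <- function(state) {
  if (!length(state$origin)) return(NA_real_)
  mean(state$origin == 2L)
}
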