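#' Simulation parameters
#'
#' Bundles the five free parameters of the spread model with its fixed
#' life-history constants. The five free parameters are the ones estimated
#' by ABC; the constants encode the species' biology (6-year lifespan,
#' maturity at 4 years, one-shot reproduction gated by an energy budget).
#'
#' @param regionalSeedRain seeds reaching the landscape from outside per
#'   reproductive season (prior 100-500).
#' @param windSpeed seed dispersal magnitude in wind units (prior 1-20);
#'   each unit lets a seed fly 5 landscape patches (0.5 m) per dispersal
#'   step.
#' @param mutationRate per-gamete SSR stepwise mutation probability
#'   (prior 1e-6 to 1e-2, normal on the log10 scale).
#' @param germinationRate probability an attached seed germinates
#'   (prior 0.0083-0.30).
#' @param captureProbability probability a seed crossing a crown patch is
#'   captured by the canopy (prior 0.01-0.30).
#' @param lifespanMonths,maturityMonths lifespan and age at maturity.
#' @param reproThreshold minimum energy units to reproduce.
#' @param energyGain photosynthetic gain per month at zero shading.
#' @param maintenance metabolic cost per month. The default (0.55) makes a
#'   shade-free site a net energy source (+0.45/month, maturity with >= 10
#'   units at 48 months) and any site under one or more overtopping crown
#'   layers a slow sink, so plants whose expenses surpass their gain
#'   eventually starve.
#' @param initialEnergy energy of a new seedling or ramet.
#' @param reproReserve energy retained after reproduction.
#' @param seedsPerUnit seeds produced per threshold-unit of energy: a plant
#'   with energy `E` emits `floor(E / reproThreshold) * seedsPerUnit` seeds.
#' @param perLayerShading light fraction intercepted per crown layer.
#' @param seasonMonth month of the year (0-11) of the reproductive season.
#' @param windPatchFactor patches flown per wind unit (fixed at 5).
#' @param somaticMutationRate stepwise mutation rate applied to clonal
#'   (ramet) genotypes; 0 by default (clones copy the genotype exactly).
#' @param targetHet expected per-locus heterozygosity of founder genotypes.
#' @return a validated `SimParams` list.
#' @export
simParams <- function(regionalSeedRain = 176,
                      windSpeed = 17.615,
                      mutationRate = 10^-4.675,
                      germinationRate = 0.2295,
                      captureProbability = 0.223,
                      lifespanMonths = 72L,
                      maturityMonths = 48L,
                      reproThreshold = 10,
                      energyGain = 1,
                      maintenance = 0.55,
                      initialEnergy = 1,
                      reproReserve = 1,
                      seedsPerUnit = 10L,
                      perLayerShading = 0.5,
                      seasonMonth = 0L,
                      windPatchFactor = 5L,
                      somaticMutationRate = 0,
                      targetHet = 0.39) {
  p <- list(regionalSeedRain = regionalSeedRain, windSpeed = windSpeed,
            mutationRate = mutationRate, germinationRate = germinationRate,
            captureProbability = captureProbability,
            lifespanMonths = as.integer(lifespanMonths),
            maturityMonths = as.integer(maturityMonths),
            reproThreshold = reproThreshold, energyGain = energyGain,
            maintenance = maintenance, initialEnergy = initialEnergy,
            reproReserve = reproReserve,
            seedsPerUnit = as.integer(seedsPerUnit),
            perLayerShading = perLayerShading,
            seasonMonth = as.integer(seasonMonth) %% 12L,
            windPatchFactor = as.integer(windPatchFactor),
            somaticMutationRate = somaticMutationRate,
            targetHet = targetHet)
  stopifnot(p$regionalSeedRain >= 0, p$windSpeed >= 0,
            p$mutationRate >= 0, p$mutationRate <= 1,
            p$germinationRate >= 0, p$germinationRate <= 1,
            p$captureProbability >= 0, p$captureProbability <= 1,
            p$lifespanMonths > 0, p$maturityMonths >= 0,
            p$perLayerShading >= 0, p$perLayerShading <= 1)
  class(p) <- "SimParams"
  p
}

#' Posterior-median parameter vector
#'
#' Midpoints of the 95% posterior credible intervals obtained by the ABC
#' calibration against the observed grove genotypes (seed rain 88-264/yr,
#' wind 13.95-21.28 units, log10 mutation rate -5.28 to -4.07, germination
#' 0.162-0.297, capture 0.150-0.296). This is the parameter set used for
#' the time, density and dynamic experiments.
#'
#' @param ... overrides passed on to [simParams()].
#' @return a `SimParams` list.
#' @export
posteriorMedianParams <- function(...) {
  args <- utils::modifyList(
    list(regionalSeedRain = (88 + 264) / 2,
         windSpeed = (13.95 + 21.28) / 2,
         mutationRate = 10^((-5.28 + -4.07) / 2),
         germinationRate = (0.162 + 0.297) / 2,
         captureProbability = (0.150 + 0.296) / 2),
    list(...))
  do.call(simParams, args)
}

#' @export
print.SimParams <- function(x, ...) {
  cat("SimParams:\n")
  cat(sprintf("  regional seed rain : %g seeds/yr\n", x$regionalSeedRain))
  cat(sprintf("  wind speed         : %g units (%g patches/step)\n",
              x$windSpeed, x$windSpeed * x$windPatchFactor))
  cat(sprintf("  mutation rate      : %.3g /gamete\n", x$mutationRate))
  cat(sprintf("  germination rate   : %g\n", x$germinationRate))
  cat(sprintf("  capture probability: %g\n", x$captureProbability))
  cat(sprintf("  lifespan %d mo, maturity %d mo, repro threshold %g units\n",
              x$lifespanMonths, x$maturityMonths, x$reproThreshold))
  invisible(x)
}
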