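Package: ballmoss
Title: Individual-Based Simulation of Epiphyte Spread and Spatial Genetic
    Structure on Tree Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit individual-based simulation of the spread of
    a selfing, clonally growing epiphyte (ball moss, Tillandsia recurvata)
    across static and dynamic tree landscapes, together with the
    population-genetic machinery needed to study its spatial genetic
    structure: diploid microsatellite genotypes under a stepwise mutation
    model, multilocus genotype/lineage bookkeeping, summary statistics
    (allelic diversity, F_IS, Weir-Cockerham F_ST, AMOVA, Garza-Williamson M,
    Loiselle kinship correlograms and the Sp statistic, genotype turnover,
    Mantel isolation-by-distance), Genepop import/export, and an approximate
    Bayesian computation layer (prior sampling, reference tables, rejection
    with optional local-linear adjustment, sensitivity analysis and
    cross-validation) for calibrating the simulator against observed
    genotypes. Landscape dynamics include tree growth, Yoda self-thinning,
    natural regeneration and abrupt deforestation or reforestation events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
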