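test_that("population sampling honours per-tree and tree-count caps", {
  set.seed(30)
  st <- simInit(miniGrove(20), posteriorMedianParams())
  runSim(st, years = 15)
  expect_gt(length(unique(st$host)), 15L)
  sm <- samplePopulation(st, maxTrees = 15, perTree = 15)
  expect_equal(nlevels(droplevels(sm@subpop)), 15L)
  expect_true(all(table(sm@subpop) <= 15L))
  # trees holding fewer plants contribute all of them
  smallTree <- names(which(table(st$host) <= 3))[1]
  if (!is.na(smallTree)) {
    sm2 <- samplePopulation(st, maxTrees = 100, perTree = 15)
    expect_equal(sum(sm2@subpop == smallTree),
                 sum(st$host == as.integer(smallTree)))
  }
  # reproducible under a fixed seed
  set.seed(5); a <- samplePopulation(st, 15, 15)
  set.seed(5); b <- samplePopulation(st, 15, 15)
  expect_identical(a@genotypes, b@genotypes)
  # empty population: empty matrix, statistics refuse it
  st0 <- simInit(miniGrove(), simParams(regionalSeedRain = 0))
  e <- samplePopulation(st0)
  expect_equal(nrow(e@genotypes), 0L)
  expect_error(diversityStats(e), "empty")
})

test_that("diversity statistics match hand and brute-force computation", {
  # two individuals AA, AB: p(A) = 0.75, 1 - sum p^2 = 0.375, H_O = 0.5
  g <- matrix(c(10L, 10L, 10L, 12L), 2, byrow = TRUE)
  p <- naiveFreqs(g, 1)
  expect_equal(unname(p["10"]), 0.75)
  expect_equal(naiveHe(g, 1, unbiased = FALSE), 0.375)
  sm <- sampleMatrix(g, c("a", "a"))
  dv <- diversityStats(sm)
  expect_equal(dv$perSubpop$H_O, 0.5)
  expect_equal(dv$perSubpop$H_E, 0.375 * 4 / 3)  # Nei unbiased, 2N/(2N-1)
  expect_equal(dv$perSubpop$A, 2)

  # all identical homozygotes: A = 1/locus, H_E = H_O = 0
  hom <- sampleMatrix(matrix(10L, 6, 4), rep("a", 6))
  dvh <- diversityStats(hom)
  expect_equal(dvh$K, 1)
  expect_equal(dvh$perSubpop$H_E, 0)
  expect_equal(dvh$perSubpop$H_O, 0)

  # private alleles: an allele seen in exactly one subpop counts there
  gp <- rbind(matrix(c(10L, 10L), 4, 2, byrow = TRUE),
              matrix(c(10L, 16L), 4, 2, byrow = TRUE))
  dvp <- diversityStats(sampleMatrix(gp, rep(c("a", "b"), each = 4)))
  expect_equal(dvp$perSubpop$A_P, c(0, 1))

  # agreement with the naive oracle on simulated data, to 1e-10
  set.seed(31)
  panel <- hwePanel(nPerPop = 25, nPops = 3)
  dv3 <- diversityStats(panel)
  for (k in 1:3) {
    rows <- panel@subpop == paste0("p", k)
    gk <- panel@genotypes[rows, ]
    L <- length(panel@loci)
    expect_equal(dv3$perSubpop$H_E[k],
                 mean(sapply(1:L, function(l) naiveHe(gk, l))),
                 tolerance = 1e-10)
    expect_equal(dv3$perSubpop$H_O[k],
                 mean(sapply(1:L, function(l) naiveHo(gk, l))),
                 tolerance = 1e-10)
    expect_equal(dv3$perSubpop$A[k],
                 sum(sapply(1:L, function(l) length(naiveFreqs(gk, l)))),
                 tolerance = 1e-10)
  }
})

test_that("F_IS separates selfers from Hardy-Weinberg populations", {
  # polymorphic all-homozygote panel: F_IS = 1
  g <- rbind(matrix(c(10L, 10L), 5, 2, byrow = TRUE),
             matrix(c(14L, 14L), 5, 2, byrow = TRUE))
  f1 <- fis(sampleMatrix(g, rep("a", 10)))
  expect_equal(f1$mean, 1)

  # HWE panel: F_IS ~ 0 and not significant
  set.seed(32)
  hw <- hwePanel(nPerPop = 60, nPops = 2)
  fh <- fis(hw, nPerm = 199)
  expect_lt(abs(fh$mean), 0.1)
  expect_true(all(fh$perSubpop$p > 0.05))

  # several generations of selfing: high, significant F_IS
  pool <- defaultAllelePool()
  founders <- randomFounderGenotype(pool, 30, targetHet = 0.8)
  gen <- founders
  for (i in 1:3) gen <- selfOffspring(gen, 0)
  sel <- fis(sampleMatrix(gen, rep("s", 30)), nPerm = 199)
  expect_gt(sel$mean, 0.52)
  expect_lt(sel$perSubpop$p[1], 0.05)
})

test_that("Weir-Cockerham F_ST matches oracles and closed forms", {
  # two subpopulations fixed for different alleles: theta = 1
  fixed <- fixedDifferencePanel()
  expect_equal(fst(fixed)$global, 1)

  # two samples from one pool: theta ~ 0 (within permutation spread)
  set.seed(33)
  hw <- hwePanel(nPerPop = 50, nPops = 2)
  th <- fst(hw)$global
  null <- replicate(99, {
    perm <- hwePanel(nPerPop = 50, nPops = 1)
    g <- perm@genotypes[sample.int(50), ]
    fst(sampleMatrix(g, rep(c("a", "b"), each = 25)))$global
  })
  expect_lt(abs(th), max(abs(null)))

  # agreement with the independent line-by-line WC implementation
  set.seed(34)
  st <- simInit(miniGrove(), posteriorMedianParams())
  runSim(st, years = 10)
  sm <- samplePopulation(st)
  expect_equal(fst(sm)$global, naiveTheta(sm@genotypes, sm@subpop),
               tolerance = 1e-10)

  # island model at migration-drift equilibrium: theta ~ 1/(1 + 4Nm a),
  # a = (r/(r-1))^2
  set.seed(35)
  isl <- simIslandModel(nDemes = 8, N = 100, m = 0.01)
  expected <- 1 / (1 + 4 * 100 * 0.01 * (8 / 7)^2)
  got <- fst(sampleMatrix(isl$g, isl$pop))$global
  expect_lt(abs(got - expected), 0.06)

  # refuses a single pooled subpopulation rather than returning 0
  expect_error(fst(sampleMatrix(fixed@genotypes, rep("one", 24))),
               "at least two subpopulations")

  # n = 1 subpops excluded from pairwise estimates
  g1 <- rbind(fixed@genotypes, fixed@genotypes[1, , drop = FALSE])
  expect_warning(
    pw <- fst(sampleMatrix(g1, c(as.character(fixed@subpop), "c")),
              pairwise = TRUE),
    "excluded")
  expect_false("c" %in% rownames(pw$pairwise))
})

test_that("AMOVA partitions variance with an exact accounting identity", {
  # identical subpopulations: ~ 0% among
  g <- rbind(matrix(c(10L, 12L), 8, 2, byrow = TRUE),
             matrix(c(10L, 12L), 8, 2, byrow = TRUE))
  am0 <- amova(sampleMatrix(g, rep(c("a", "b"), each = 8)), nPerm = 0)
  expect_equal(am0$amongPct, 0, tolerance = 1e-9)

  # fully fixed differences: 100% among
  am1 <- amova(fixedDifferencePanel(), nPerm = 99)
  expect_equal(am1$amongPct, 100)
  expect_lt(am1$p, 0.05)

  # percentages always sum to 100 exactly
  set.seed(36)
  st <- simInit(miniGrove(), posteriorMedianParams())
  runSim(st, years = 8)
  sm <- samplePopulation(st)
  am <- amova(sm, nPerm = 49)
  expect_equal(am$amongPct + am$withinPct, 100)
  am2 <- amova(sm, nPerm = 0, metric = "size")
  expect_equal(am2$amongPct + am2$withinPct, 100)
})

test_that("Garza-Williamson M follows k/(R+1)", {
  mk <- function(a1, a2) sampleMatrix(cbind(pmin(a1, a2), pmax(a1, a2)),
                                      rep("a", length(a1)))
  # alleles {10, 12}: k = 2, R = 2, M = 2/3
  expect_equal(garzaWilliamson(mk(c(10L, 10L), c(12L, 10L)))$mean, 2 / 3)
  # a single allele: M = 1
  expect_equal(garzaWilliamson(mk(c(10L, 10L), c(10L, 10L)))$mean, 1)
  # full ladder {10, 11, 12}: M = 3/3 = 1
  expect_equal(garzaWilliamson(mk(c(10L, 11L, 12L), c(10L, 11L, 12L)))$mean, 1)
})

test_that("Loiselle kinship centres on zero and ranks relatives correctly", {
  set.seed(37)
  hw <- hwePanel(nPerPop = 40, nPops = 1)
  Fij <- loiselleKinship(hw)
  off <- Fij[upper.tri(Fij)]
  expect_lt(abs(mean(off)), 0.01)        # ~ 0 by construction

  # clonemates sit above the sample mean
  g <- hw@genotypes
  g[2, ] <- g[1, ]                       # make 1 and 2 clonemates
  Fc <- loiselleKinship(sampleMatrix(g, hw@subpop))
  expect_gt(Fc[1, 2], mean(Fc[upper.tri(Fc)], na.rm = TRUE))

  # parent-selfed-offspring kinship ~ 0.5 against an unrelated pool
  set.seed(38)
  ped <- selfingPedigree()
  Fp <- loiselleKinship(ped$sample)
  po <- Fp[ped$pairs]
  expect_lt(abs(mean(po) - 0.5), 0.1)
})

test_that("the Sp statistic detects clonal aggregation and not shuffled noise", {
  # balanced classes: 224 individuals -> C(224,2)/7 = 3568 pairs per class
  d <- runif(choose(224, 2))
  cls <- ballmoss:::.balancedClasses(d, 7)
  expect_equal(unname(range(table(cls))), c(3568, 3568))
  expect_lte(diff(range(table(ballmoss:::.balancedClasses(runif(100), 7)))), 1)

  # spatially shuffled genotypes: Sp ~ 0, not significant
  set.seed(39)
  hw <- hwePanel(nPerPop = 80, nPops = 1)   # random coords, random genotypes
  spNull <- spStatistic(hw, nPerm = 199)
  expect_lt(abs(spNull$Sp), 0.01)
  expect_gt(spNull$p, 0.02)   # inside the null distribution

  # clonal clustering: clones placed together -> positive, significant Sp
  set.seed(40)
  pool <- defaultAllelePool()
  nFam <- 8; perFam <- 12
  fams <- randomFounderGenotype(pool, nFam, targetHet = 0.6)
  g <- fams[rep(seq_len(nFam), each = perFam), ]
  centers <- cbind(runif(nFam, 5, 45), runif(nFam, 5, 45))
  xy <- centers[rep(seq_len(nFam), each = perFam), ] +
    matrix(rnorm(2 * nFam * perFam, 0, 0.8), ncol = 2)
  cl <- sampleMatrix(g, rep("a", nFam * perFam), coords = xy)
  spc <- spStatistic(cl, nPerm = 199)
  expect_gt(spc$Sp, 0)
  expect_lt(spc$p, 0.05)
  expect_gt(spc$correlogram$meanF[1], spc$correlogram$hi[1])  # first class

  # degenerate geometry is refused
  same <- sampleMatrix(g[1:5, ], rep("a", 5),
                       coords = matrix(1, 5, 2))
  expect_error(spStatistic(same, nPerm = 0), "one location")
})

test_that("turnover spans [0, 1] from shared to disjoint compositions", {
  # identical MLG composition across subpops: 0
  g <- matrix(c(10L, 12L), 8, 2, byrow = TRUE)
  sm <- sampleMatrix(g, rep(c("a", "b"), each = 4), mlg = rep(1:2, 4))
  expect_equal(turnover(sm, "mlg"), 0)
  # fully disjoint: 1
  smd <- sampleMatrix(g, rep(c("a", "b"), each = 4),
                      mlg = rep(1:2, each = 4))
  expect_equal(turnover(smd, "mlg"), 1)
  # half-shared hand case: 2 pops x 4 MLGs, 2 shared:
  # gamma = 6, mean alpha = 4 -> (6/4 - 1)/(2 - 1) = 0.5
  smh <- sampleMatrix(matrix(c(10L, 12L), 16, 2, byrow = TRUE),
                      rep(c("a", "b"), each = 8),
                      mlg = c(1:4, 1:4, c(1, 2, 5, 6), c(1, 2, 5, 6)))
  expect_equal(turnover(smh, "mlg"), 0.5)
  # allele-level edge cases
  gi <- rbind(matrix(c(10L, 10L), 4, 2, byrow = TRUE),
              matrix(c(14L, 14L), 4, 2, byrow = TRUE))
  expect_equal(turnover(sampleMatrix(gi, rep(c("a", "b"), each = 4)),
                        "allele"), 1)
  expect_equal(turnover(sampleMatrix(gi[c(1, 5, 1, 5), ],
                                     rep(c("a", "b"), each = 2)), "allele"), 0)
})

test_that("Mantel IBD flags stepping-stone structure and not permuted labels", {
  # stepping-stone chain: positive, significant correlation
  set.seed(42)
  ss <- simSteppingStone()
  sms <- sampleMatrix(ss$g, ss$pop, coords = ss$coords)
  mt <- mantelIBD(sms, "linearized_fst", nPerm = 199)
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)
  mte <- mantelIBD(sms, "edwards", nPerm = 199)
  expect_gt(mte$r, 0)

  # permuted deme labels destroy the signal
  set.seed(43)
  perm <- sampleMatrix(ss$g[sample(nrow(ss$g)), ], ss$pop,
                       coords = ss$coords)
  mtp <- mantelIBD(perm, "linearized_fst", nPerm = 199)
  expect_lt(abs(mtp$r), 0.35)
  expect_gt(mtp$p, 0.05)
})

test_that("Genepop files round-trip genotype matrices", {
  set.seed(44)
  sm <- hwePanel(nPerPop = 10, nPops = 2)
  f <- tempfile(fileext = ".gen")
  writeGenepop(sm, f)
  back <- readGenepop(f)
  expect_identical(back@genotypes, sm@genotypes)
  expect_equal(nlevels(back@subpop), 2L)
  expect_identical(back@loci, sm@loci)
})

test_that("the six-statistic summary vector is complete and finite", {
  set.seed(45)
  st <- simInit(miniGrove(), posteriorMedianParams())
  runSim(st, years = 10)
  sv <- statVector(samplePopulation(st))
  expect_named(sv, c("K", "R", "H_E", "F_IS", "F_ST", "NGW"))
  expect_true(all(is.finite(sv)))
  expect_true(sv["H_E"] >= 0 && sv["H_E"] <= 1)
  expect_true(sv["NGW"] > 0 && sv["NGW"] <= 1)
})
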