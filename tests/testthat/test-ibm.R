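oneTreeLandscape <- function(crown = 3, extent = c(20, 20)) {
  buildLayout(data.frame(x = extent[1] / 2, y = extent[2] / 2, dbh = 20,
                         height = 6, crown = crown), extent = extent)
}

test_that("an empty landscape with no seed rain stays empty forever", {
  set.seed(20)
  L <- buildStaticLandscape(0.05, 0)
  st <- simInit(L, simParams(regionalSeedRain = 0))
  runSim(st, years = 5)
  expect_equal(abundance(st), 0L)
  expect_equal(nMLL(st), 0L)
  expect_equal(st$month, 60L)

  # trees but no rain: nothing can ever colonize
  st2 <- simInit(oneTreeLandscape(), simParams(regionalSeedRain = 0))
  runSim(st2, years = 3)
  expect_equal(abundance(st2), 0L)
})

test_that("fixed seeds give bit-identical trajectories", {
  run <- function() {
    set.seed(21)
    st <- simInit(miniGrove(), posteriorMedianParams())
    runSim(st, years = 6)
    list(st$age, st$energy, st$host, st$px, st$py, st$geno, st$mll,
         st$origin, st$repro, st$month)
  }
  expect_identical(run(), run())
})

test_that("the energy budget gates survival and maturity", {
  p <- simParams()
  # full shade: strict monthly loss
  expect_lt(energyUpdate(5, 1, p), 5)
  # zero shade from seedling energy: at least 10 units by month 48
  e <- p$initialEnergy
  for (m in 1:48) e <- energyUpdate(e, 0, p)
  expect_gte(e, 10)
  # floor at zero
  expect_equal(energyUpdate(0.1, 1, p), 0)
})

test_that("reproduction respects the maturity/energy/one-shot contract", {
  L <- oneTreeLandscape()
  p <- simParams(regionalSeedRain = 0, captureProbability = 0,
                 mutationRate = 0)
  makeState <- function(age, energy) {
    set.seed(22)
    st <- simInit(L, p)
    g <- assignMLG(st$registry, randomFounderGenotype(st$pool, 1))
    ballmoss:::addPlants(st, host = 1L, px = 100L, py = 100L, geno = g,
                         mll = 1L, origin = 1L)
    st$age[1] <- age; st$energy[1] <- energy
    st
  }
  # energy below the 10-unit threshold at the season: no reproduction
  # (9.0 + the month's net gain of 0.5 stays below 10)
  st <- makeState(48L, 9.0)
  simStep(st)
  expect_equal(abundance(st), 1L)
  expect_false(st$repro[1])

  # energy above threshold: one ramet on the same host, same genotype/MLG/MLL
  st <- makeState(48L, 25)
  simStep(st)
  expect_equal(abundance(st), 2L)
  expect_true(st$repro[1])
  expect_equal(st$host[2], st$host[1])
  expect_equal(st$geno[2], st$geno[1])   # same MLG
  expect_equal(st$mll[2], st$mll[1])
  expect_equal(st$origin[2], 2L)
  expect_equal(st$energy[1], p$reproReserve)

  # the spent parent never reproduces again
  nBefore <- abundance(st)
  st$energy[1] <- 25
  for (i in 1:12) simStep(st)           # through the next season
  expect_true(st$repro[1])
  # (the ramet itself is still immature, so any growth is not from parent 1)
  expect_lte(abundance(st), nBefore + 1L)
})

test_that("wind dispersal obeys reach, capture and the absorbing boundary", {
  set.seed(23)
  L <- oneTreeLandscape(crown = 3)
  # wind 0: the seed never leaves its natal patch
  d0 <- disperseFrom(L, 10, 10, 200, windSpeed = 0, capture = 1)
  expect_true(all(d0$attached))
  expect_true(all(d0$px == 100L & d0$py == 100L))
  # capture 1 inside a crown: always attaches at the first crown patch met
  d1 <- disperseFrom(L, 10, 10, 500, windSpeed = 2, capture = 1)
  expect_true(all(d1$attached))
  dist <- sqrt((d1$px - 100)^2 + (d1$py - 100)^2)
  expect_lte(max(dist), 2)              # first patch crossed
  # capture 0: nothing ever attaches
  expect_false(any(disperseFrom(L, 10, 10, 300, 5, 0)$attached))
  # flight is bounded by 5 * windSpeed patches
  dw <- disperseFrom(L, 10, 10, 2000, windSpeed = 4, capture = 0.3)
  dd <- sqrt((dw$px - 100)^2 + (dw$py - 100)^2)
  expect_lte(max(dd, na.rm = TRUE), 20 + 1e-9)
  # attachment probability declines with distance from the source
  att <- dw[dw$attached, ]
  h <- table(cut(sqrt((att$px - 100)^2 + (att$py - 100)^2),
                 breaks = c(0, 7, 14, 21)))
  expect_true(all(diff(as.numeric(h)) <= 0))
  # releases outside any crown on a treeless landscape are always lost
  empty <- buildStaticLandscape(0.04, 0)
  expect_false(any(disperseFrom(empty, 10, 10, 100, 20, 1)$attached))
})

test_that("germination is Bernoulli at the configured rate", {
  set.seed(24)
  expect_false(any(germinateSeeds(1000, 0)))
  expect_true(all(germinateSeeds(1000, 1)))
  k <- sum(germinateSeeds(1e4, 0.2))
  expect_lt(abs(k - 2000), 4 * sqrt(1e4 * 0.2 * 0.8))
})

test_that("mortality removes the old, the starved and the orphaned", {
  L <- oneTreeLandscape()
  p <- simParams(regionalSeedRain = 0)
  set.seed(25)
  st <- simInit(L, p)
  g <- assignMLG(st$registry, randomFounderGenotype(st$pool, 3))
  ballmoss:::addPlants(st, host = rep(1L, 3), px = c(100L, 101L, 102L),
                       py = rep(100L, 3), geno = g, mll = 1:3,
                       origin = rep(1L, 3))
  st$age <- c(72L, 10L, 10L)       # plant 1 at lifespan
  st$energy <- c(5, 0.4, 5)        # plant 2 will starve (shading 0 -> +0.5,
  st$month <- 1L                   #  so force it with age instead below)
  simStep(st)
  expect_equal(abundance(st), 2L)  # the 72-month plant is gone
  expect_true(all(st$age < 72L + 1L))

  # energy hitting zero kills: shaded plant with maintenance above its gain
  two <- buildLayout(data.frame(x = c(10, 10.4), y = 10, dbh = 20,
                                height = c(6, 7), crown = 3),
                     extent = c(20, 20))
  st2 <- simInit(two, simParams(regionalSeedRain = 0, maintenance = 0.7))
  g2 <- assignMLG(st2$registry, randomFounderGenotype(st2$pool, 1))
  ballmoss:::addPlants(st2, host = 2L, px = 101L, py = 100L, geno = g2,
                       mll = 1L, origin = 1L)
  st2$energy[1] <- 0.8      # one overtopping layer: net -0.2/month
  st2$month <- 1L
  runSim(st2, months = 6)   # 0.8 -> 0.6 -> 0.4 -> 0.2 -> 0 (dead)
  expect_equal(abundance(st2), 0L)

  # deforestation kills resident epiphytes with their host
  st3 <- simInit(L, p)
  g3 <- assignMLG(st3$registry, randomFounderGenotype(st3$pool, 1))
  ballmoss:::addPlants(st3, host = 1L, px = 100L, py = 100L, geno = g3,
                       mll = 1L, origin = 1L)
  ev <- applyDensityChange(st3$landscape, "deforest", 1)
  setLandscape(st3, ev$landscape)
  simStep(st3)
  expect_equal(abundance(st3), 0L)
})

test_that("populations respect occupancy and lineage-conservation invariants", {
  set.seed(26)
  st <- simInit(miniGrove(), posteriorMedianParams())
  runSim(st, years = 12)
  expect_gt(abundance(st), 0L)
  # one established plant per patch
  expect_false(anyDuplicated(cbind(st$px, st$py)) > 0)
  # every plant sits under its host tree's crown
  tr <- st$landscape@trees
  ps <- st$landscape@patchSize
  hx <- tr$x[match(st$host, tr$id)]; hy <- tr$y[match(st$host, tr$id)]
  cr <- tr$crown[match(st$host, tr$id)]
  d <- sqrt(((st$px + 0.5) * ps - hx)^2 + ((st$py + 0.5) * ps - hy)^2)
  expect_true(all(d <= cr + ps))
  # abundance bounded by crown patches
  expect_lte(abundance(st), sum(st$landscape@canopy > 0))
  # MLL count never exceeds cumulative germinated founders
  expect_lte(nMLL(st), st$foundersGerminated)
  # with no somatic mutation every clone's genotype equals its MLG genotype
  expect_true(all(st$geno[st$origin == 2L] %in% st$geno))
})

test_that("regional rain is the only source of new lineages", {
  set.seed(27)
  p0 <- posteriorMedianParams(regionalSeedRain = 0)
  st <- simInit(miniGrove(), p0)
  g <- assignMLG(st$registry, randomFounderGenotype(st$pool, 2))
  cp <- crownPatches(st$landscape, 1L)
  ballmoss:::addPlants(st, host = c(1L, 1L), px = cp[1:2, "px"],
                       py = cp[1:2, "py"], geno = g, mll = 1:2,
                       origin = c(1L, 1L))
  st$nextMll <- 2L
  runSim(st, years = 10)
  expect_lte(nMLL(st), 2L)    # never increases without rain

  # rain with zero capture: no establishment at all
  set.seed(28)
  st2 <- simInit(miniGrove(), posteriorMedianParams(captureProbability = 0))
  runSim(st2, years = 5)
  expect_equal(abundance(st2), 0L)
})
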