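test_that("static landscapes place the requested stand reproducibly", {
  set.seed(10)
  L <- buildStaticLandscape(0.40, 150, crownRadius = 2)
  expect_equal(treeDensity(L), 375)            # 150 trees on 0.4 ha
  expect_equal(sum(L@trees$alive), 150L)
  expect_length(unique(L@trees$crown), 1L)     # same crown sizes
  expect_gt(length(unique(L@trees$height)), 1L)

  empty <- buildStaticLandscape(0.1, 0)
  expect_equal(groundCover(empty), 0)
  expect_true(all(shadingAt(empty, 0:9, 0:9) == 0))

  set.seed(77); a <- buildStaticLandscape(0.40, 5)
  set.seed(77); b <- buildStaticLandscape(0.40, 5)
  expect_identical(a@trees, b@trees)

  # area too small to hold the trunks
  expect_error(buildStaticLandscape(0.0001, 500, maxTries = 20L),
               "trunk overlap")
})

test_that("explicit layouts round-trip through CSV and reject duplicates", {
  set.seed(11)
  grove <- makeGrove()
  d <- as.matrix(stats::dist(grove@trees[, c("x", "y")]))
  dv <- d[upper.tri(d)]
  expect_true(all(dv >= 2.5 & dv <= 47.5))
  expect_equal(treeDensity(grove), 100)        # 20 trees on 0.2 ha

  f <- tempfile(fileext = ".csv")
  writeTreeLayout(grove, f)
  re <- buildLayout(readTreeLayout(f), extent = grove@extent)
  expect_equal(re@trees$x, grove@trees$x)
  expect_identical(re@canopy, grove@canopy)

  tt <- data.frame(x = c(1, 1), y = c(2, 2), dbh = 20, height = 5)
  expect_error(buildLayout(tt), "duplicate")

  # a single centred tree owns every crown patch
  one <- buildLayout(data.frame(x = 10, y = 10, dbh = 20, height = 6,
                                crown = 3), extent = c(20, 20))
  cp <- crownPatches(one, 1L)
  expect_equal(sum(one@canopy > 0), nrow(cp))
})

test_that("shading follows the layered light-interception law", {
  one <- buildLayout(data.frame(x = 10, y = 10, dbh = 20, height = 6,
                                crown = 3), extent = c(20, 20))
  # open ground: zero; under a single crown: 1 - (1 - s1)^1
  expect_equal(shadingAt(one, 0L, 0L), 0)
  expect_equal(shadingAt(one, 100L, 100L), 0.5)
  expect_equal(shadingAt(one, 100L, 100L, perLayer = 0.3), 0.3)
  # monotone in the number of overlapping crowns
  two <- buildLayout(data.frame(x = c(10, 10.4), y = 10, dbh = 20,
                                height = 6, crown = 3), extent = c(20, 20))
  k <- as.vector(two@canopy)
  sh <- 1 - 0.5^sort(unique(k))
  expect_true(all(diff(sh) >= 0))
  expect_equal(max(shadingAt(two, 101L, 100L)), 0.75)  # two layers
})

test_that("ground cover matches brute-force patch counting", {
  one <- buildLayout(data.frame(x = 10, y = 10, dbh = 20, height = 6,
                                crown = 3), extent = c(20, 20))
  grid <- gridSnapshot(one)
  expect_equal(groundCover(one), mean(grid$cover_class != "open"))
  # ~ pi r^2 / A for an interior tree (patch discretization error small)
  expect_lt(abs(groundCover(one) - pi * 9 / 400), 0.002)
})

test_that("tree dynamics grow, thin and regenerate as specified", {
  set.seed(12)
  one <- buildLayout(data.frame(x = 10, y = 10, dbh = 20, height = 6,
                                crown = 3), extent = c(20, 20))
  # DBH increases by exactly 0.13 cm/year
  out <- stepTreeDynamics(one, dt = 10, regenRate = 0)
  expect_equal(out$landscape@trees$dbh, 20 + 1.3)
  expect_length(out$diedIds, 0L)  # far below the self-thinning line

  # growth without mortality never reduces covered ground
  g0 <- groundCover(one)
  expect_gte(groundCover(out$landscape), g0)

  # recruits only ever appear on open patches
  set.seed(13)
  L <- buildStaticLandscape(0.05, 8, crownRadius = 2)
  before <- L@canopy > 0 | L@trunk
  out2 <- stepTreeDynamics(L, dt = 1, regenRate = 1)
  newTrees <- out2$landscape@trees[!(out2$landscape@trees$id %in% L@trees$id), ]
  ps <- L@patchSize
  for (i in seq_len(nrow(newTrees))) {
    px <- floor(newTrees$x[i] / ps); py <- floor(newTrees$y[i] / ps)
    expect_false(before[py + 1, px + 1])
  }

  # overcrowded stand thins toward the Yoda line, smallest trees first
  set.seed(14)
  crowded <- buildStaticLandscape(0.1, 60, crownRadius = 1,
                                  dbh = 40, heightRange = c(5, 6))
  thin <- stepTreeDynamics(crowded, dt = 1, regenRate = 0, yodaK = 3e8)
  expect_gt(length(thin$diedIds), 0L)
  dead <- thin$landscape@trees[!thin$landscape@trees$alive, ]
  alive <- thin$landscape@trees[thin$landscape@trees$alive, ]
  expect_lte(max(dead$dbh), min(alive$dbh))
})

test_that("density-change events hit the stated magnitudes exactly", {
  set.seed(15)
  L <- buildStaticLandscape(0.40, 150, crownRadius = 2)  # 375 trees/ha
  for (f in c(0, 0.10, 0.50, 0.90)) {
    out <- applyDensityChange(L, "deforest", f)
    expect_equal(sum(out$landscape@trees$alive), round((1 - f) * 150))
    if (f == 0) expect_identical(out$landscape@trees, L@trees)
  }
  out9 <- applyDensityChange(L, "deforest", 0.90)
  expect_equal(treeDensity(out9$landscape), round(0.1 * 150) / 0.4)  # 37.5/ha

  # reforestation adds saplings on open ground, capped by available patches
  set.seed(16)
  lo <- buildStaticLandscape(0.40, 70, crownRadius = 2)   # 175 trees/ha
  ref <- applyDensityChange(lo, "reforest", 225)
  expect_equal(sum(ref$landscape@trees$alive), 70 + round(225 * 0.4))
  expect_lte(treeDensity(ref$landscape), 400)
  # tiny landscape with almost no open ground: warns and adds what fits
  tiny <- buildLayout(data.frame(x = 1, y = 1, dbh = 20, height = 5,
                                 crown = 2), extent = c(2, 2))
  expect_warning(applyDensityChange(tiny, "reforest", 1e5),
                 "insufficient open ground")
})

test_that("raster refresh after any tree change equals a full rebuild", {
  set.seed(17)
  L <- buildStaticLandscape(0.1, 20, crownRadius = 1.5)
  out <- applyDensityChange(L, "deforest", 0.5)
  rebuilt <- ballmoss:::rasterizeTrees(out$landscape@trees, L@extent,
                                       L@patchSize)
  expect_identical(out$landscape@canopy, rebuilt$canopy)
  expect_identical(out$landscape@trunk, rebuilt$trunk)
})
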