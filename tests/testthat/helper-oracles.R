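# Independent oracles: naive recomputation of frequency statistics straight
# from the genotype table, and small Wright-Fisher simulators for closed-form
# expectations. Deliberately written as plain loops, independent of the
# package's estimator code paths.

# allele frequencies of one locus in one genotype matrix, as a named vector
naiveFreqs <- function(g, locus) {
  al <- c(g[, 2 * locus - 1], g[, 2 * locus])
  tab <- table(al)
  tab / sum(tab)
}

naiveHe <- function(g, locus, unbiased = TRUE) {
  p <- naiveFreqs(g, locus)
  n <- 2 * nrow(g)
  h <- 1 - sum(p^2)
  if (unbiased) h * n / (n - 1) else h
}

naiveHo <- function(g, locus) {
  mean(g[, 2 * locus - 1] != g[, 2 * locus])
}

# Weir & Cockerham (1984) theta written directly from the published
# formulas, loops over subpops/alleles, no shared code with fst()
naiveTheta <- function(g, pop) {
  pop <- factor(pop)
  L <- ncol(g) / 2
  aSum <- bSum <- cSum <- 0
  for (l in seq_len(L)) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    alleles <- sort(unique(c(a1, a2)))
    pops <- levels(pop)
    r <- length(pops)
    ni <- sapply(pops, function(k) sum(pop == k))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      p <- h <- numeric(r)
      for (k in seq_len(r)) {
        rows <- which(pop == pops[k])
        p[k] <- (sum(a1[rows] == al) + sum(a2[rows] == al)) / (2 * ni[k])
        h[k] <- mean((a1[rows] == al) != (a2[rows] == al))
      }
      pbar <- sum(ni * p) / sum(ni)
      s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h) / sum(ni)
      aa <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                 hbar / 4) / (nbar - 1))
      bb <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                   (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      aSum <- aSum + aa; bSum <- bSum + bb; cSum <- cSum + cc
    }
  }
  aSum / (aSum + bSum + cSum)
}

# finite island model at drift-migration equilibrium: returns genotypes
# sampled HW-within-deme from the evolved allele frequencies
simIslandModel <- function(nDemes = 8, N = 100, m = 0.01, nLoci = 20,
                           nAlleles = 10, generations = 400,
                           samplePerDeme = 30) {
  g <- matrix(0L, nDemes * samplePerDeme, 2 * nLoci)
  pop <- rep(seq_len(nDemes), each = samplePerDeme)
  for (l in seq_len(nLoci)) {
    freq <- matrix(1 / nAlleles, nDemes, nAlleles)
    for (t in seq_len(generations)) {
      pbar <- colMeans(freq)
      fmig <- (1 - m) * freq + m * rep(pbar, each = nDemes)
      for (d in seq_len(nDemes))
        freq[d, ] <- as.numeric(stats::rmultinom(1, 2 * N, fmig[d, ])) / (2 * N)
    }
    for (d in seq_len(nDemes)) {
      rows <- which(pop == d)
      draws <- sample.int(nAlleles, 2 * length(rows), TRUE, prob = freq[d, ])
      a1 <- draws[seq_along(rows)] + 10L
      a2 <- draws[length(rows) + seq_along(rows)] + 10L
      g[rows, 2 * l - 1] <- pmin(a1, a2)
      g[rows, 2 * l] <- pmax(a1, a2)
    }
  }
  list(g = g, pop = pop)
}

# 1-D stepping stone: nearest-neighbour migration produces isolation by
# distance along the chain
simSteppingStone <- function(nDemes = 8, N = 60, m = 0.05, nLoci = 15,
                             nAlleles = 8, generations = 150,
                             samplePerDeme = 20) {
  g <- matrix(0L, nDemes * samplePerDeme, 2 * nLoci)
  pop <- rep(seq_len(nDemes), each = samplePerDeme)
  for (l in seq_len(nLoci)) {
    freq <- matrix(1 / nAlleles, nDemes, nAlleles)
    for (t in seq_len(generations)) {
      fmig <- freq
      for (d in seq_len(nDemes)) {
        nb <- freq[c(max(1, d - 1), min(nDemes, d + 1)), , drop = FALSE]
        fmig[d, ] <- (1 - m) * freq[d, ] + m * colMeans(nb)
      }
      for (d in seq_len(nDemes))
        freq[d, ] <- as.numeric(stats::rmultinom(1, 2 * N, fmig[d, ])) / (2 * N)
    }
    for (d in seq_len(nDemes)) {
      rows <- which(pop == d)
      draws <- sample.int(nAlleles, 2 * length(rows), TRUE, prob = freq[d, ])
      a1 <- draws[seq_along(rows)] + 10L
      a2 <- draws[length(rows) + seq_along(rows)] + 10L
      g[rows, 2 * l - 1] <- pmin(a1, a2)
      g[rows, 2 * l] <- pmax(a1, a2)
    }
  }
  coords <- cbind(10 * pop, 0)   # demes strung 10 m apart
  list(g = g, pop = pop, coords = coords)
}

# two-subpopulation panel fixed for different alleles at every locus
fixedDifferencePanel <- function(nPerPop = 12, nLoci = 7) {
  g1 <- matrix(10L, nPerPop, 2 * nLoci)
  g2 <- matrix(14L, nPerPop, 2 * nLoci)
  sampleMatrix(rbind(g1, g2), rep(c("a", "b"), each = nPerPop))
}

# toy reference table with an analytically known parameter-statistic map
toyReferenceTable <- function(n, noise = 0.05) {
  theta <- samplePrior(priorSpec(), n)
  sc <- scale(theta)
  stats <- sc + matrix(stats::rnorm(length(sc), 0, noise), nrow(sc))
  colnames(stats) <- paste0("s", seq_len(ncol(stats)))
  new("ReferenceTable", params = theta, stats = stats, metadata = list())
}

# small fast grove + parameters for engine tests
miniGrove <- function(nTrees = 6) {
  withr::with_seed(99, makeGrove(nTrees = nTrees, extent = c(25, 20)))
}
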