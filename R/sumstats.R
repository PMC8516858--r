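## ---------------------------------------------------------------------------
## Genetic summary statistics. All estimators are computed from integer
## repeat-count genotype matrices (two columns per locus).
## ---------------------------------------------------------------------------

## per-locus allele counts within one group of individuals; returns a named
## integer vector of allele copy numbers
.alleleCounts <- function(g, locus) {
  a <- c(g[, 2L * locus - 1L], g[, 2L * locus])
  table(a[!is.na(a)])
}

## per-locus allele frequencies for a set of groups (list of genotype
## matrices); returns list(freqs = matrix allele x group, alleles, nGenes)
.lociFreqTables <- function(groups, locus) {
  counts <- lapply(groups, .alleleCounts, locus = locus)
  alleles <- sort(unique(unlist(lapply(counts, function(x)
    as.integer(names(x))))))
  f <- matrix(0, length(alleles), length(groups),
              dimnames = list(alleles, names(groups)))
  nGenes <- numeric(length(groups))
  for (k in seq_along(groups)) {
    ck <- counts[[k]]
    nGenes[k] <- sum(ck)
    if (nGenes[k] > 0)
      f[match(as.integer(names(ck)), alleles), k] <- ck / nGenes[k]
  }
  list(freqs = f, alleles = alleles, nGenes = nGenes)
}

## unbiased expected heterozygosity (Nei 1978): 2N/(2N-1) * (1 - sum p^2)
.heUnbiased <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

.hObs <- function(g, locus) {
  a1 <- g[, 2L * locus - 1L]; a2 <- g[, 2L * locus]
  ok <- !is.na(a1) & !is.na(a2)
  if (!any(ok)) return(NA_real_)
  mean(a1[ok] != a2[ok])
}

#' Per-subpopulation genetic diversity
#'
#' Number of alleles (A), allelic richness rarefied to the smallest
#' subpopulation (A_R), private alleles (A_P), expected heterozygosity
#' (H_E, Nei's unbiased estimator `2N/(2N-1) (1 - sum p^2)`) and observed
#' heterozygosity (H_O), per subpopulation; plus the grand means K (alleles
#' per locus) and R (allele size range per locus) used in the ABC summary
#' vector.
#'
#' @param sample a [SampleMatrix-class] with at least one individual per
#'   reported subpopulation.
#' @return list with `perSubpop` (data.frame), `K`, `R`.
#' @export
diversityStats <- function(sample) {
  g <- sample@genotypes
  if (!nrow(g)) stop("empty sample")
  sp <- droplevels(sample@subpop)
  L <- length(sample@loci)
  groups <- split.data.frame(g, sp)
  nPerPop <- vapply(groups, nrow, 1L)
  gMin <- 2L * min(nPerPop)  # rarefaction depth in gene copies
  S <- length(groups)
  A <- Ar <- Ap <- He <- Ho <- Rng <- matrix(NA_real_, S, L)
  for (l in seq_len(L)) {
    ft <- .lociFreqTables(groups, l)
    counts <- lapply(groups, .alleleCounts, locus = l)
    presence <- ft$freqs > 0
    for (k in seq_len(S)) {
      ck <- counts[[k]]
      nk <- sum(ck)
      A[k, l] <- length(ck)
      sz <- as.integer(names(ck))
      Rng[k, l] <- if (length(sz)) diff(range(sz)) else NA_real_
      # rarefied richness: expected alleles in gMin gene copies
      Ar[k, l] <- sum(1 - exp(lchoose(nk - ck, gMin) - lchoose(nk, gMin)))
      Ap[k, l] <- sum(presence[, k] & rowSums(presence) == 1L)
      He[k, l] <- .heUnbiased(ck)
      Ho[k, l] <- .hObs(groups[[k]], l)
    }
  }
  perSubpop <- data.frame(
    subpop = names(groups),
    n = as.integer(nPerPop),
    A = rowSums(A), A_R = rowMeans(Ar), A_P = rowSums(Ap),
    H_E = rowMeans(He, na.rm = TRUE), H_O = rowMeans(Ho, na.rm = TRUE))
  list(perSubpop = perSubpop,
       K = mean(A), R = mean(Rng, na.rm = TRUE))
}

#' Inbreeding coefficient with permutation HWE test
#'
#' Multilocus `F_IS = 1 - H_O / H_E` per subpopulation (ratio of sums over
#' loci, unbiased H_E), with an optional permutation test of
#' Hardy-Weinberg equilibrium obtained by shuffling alleles among
#' individuals within each subpopulation and locus (one-sided, heterozygote
#' deficit).
#'
#' @param sample a [SampleMatrix-class].
#' @param nPerm permutations (0 skips the test).
#' @return list with `perSubpop` (data.frame subpop, F_IS, p) and `mean`.
#' @export
fis <- function(sample, nPerm = 0L) {
  g <- sample@genotypes
  sp <- droplevels(sample@subpop)
  L <- length(sample@loci)
  groups <- split.data.frame(g, sp)
  fisOf <- function(gk) {
    he <- ho <- numeric(L)
    for (l in seq_len(L)) {
      he[l] <- .heUnbiased(.alleleCounts(gk, l))
      ho[l] <- .hObs(gk, l)
    }
    ok <- !is.na(he) & he > 0
    if (!any(ok)) return(NA_real_)
    1 - sum(ho[ok]) / sum(he[ok])
  }
  obs <- vapply(groups, fisOf, 1)
  pv <- rep(NA_real_, length(groups))
  if (nPerm > 0L) {
    for (k in seq_along(groups)) {
      gk <- groups[[k]]
      if (is.na(obs[k])) next
      null <- numeric(nPerm)
      for (b in seq_len(nPerm)) {
        gp <- gk
        for (l in seq_len(L)) {
          al <- sample(c(gk[, 2L * l - 1L], gk[, 2L * l]))
          m <- length(al) %/% 2L
          gp[, 2L * l - 1L] <- pmin(al[1:m], al[(m + 1):(2 * m)])
          gp[, 2L * l] <- pmax(al[1:m], al[(m + 1):(2 * m)])
        }
        null[b] <- fisOf(gp)
      }
      pv[k] <- (1 + sum(null >= obs[k], na.rm = TRUE)) / (nPerm + 1)
    }
  }
  list(perSubpop = data.frame(subpop = names(groups), F_IS = obs, p = pv),
       mean = mean(obs, na.rm = TRUE))
}

## Weir & Cockerham (1984) variance components for one locus over a list of
## genotype matrices; returns c(a, b, c) summed over alleles
.wcComponents <- function(groups, locus) {
  ni <- vapply(groups, nrow, 1L)
  keep <- ni >= 1L
  groups <- groups[keep]; ni <- ni[keep]
  r <- length(groups)
  if (r < 2L) return(c(0, 0, 0))
  ft <- .lociFreqTables(groups, locus)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  out <- c(0, 0, 0)
  for (j in seq_along(ft$alleles)) {
    al <- ft$alleles[j]
    p <- ft$freqs[j, ]
    pbar <- sum(ni * p) / sum(ni)
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    h <- vapply(groups, function(gk) {
      a1 <- gk[, 2L * locus - 1L]; a2 <- gk[, 2L * locus]
      mean((a1 != a2) & (a1 == al | a2 == al), na.rm = TRUE)
    }, 1)
    hbar <- sum(ni * h) / sum(ni)
    if (nbar <= 1 || nc <= 0) next
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out <- out + c(a, b, cc)
  }
  out
}

#' Subpopulation differentiation (Weir-Cockerham theta)
#'
#' Global and pairwise multiallelic, multilocus F_ST by the Weir & Cockerham
#' (1984) variance-components estimator (components summed over alleles and
#' loci). Subpopulations of a single individual are excluded from pairwise
#' estimates with a warning. Negative pairwise estimates are clamped to zero
#' only for the Slatkin linearization.
#'
#' @param sample a [SampleMatrix-class] with at least two subpopulations.
#' @param pairwise also compute the pairwise matrix.
#' @return list with `global`, and if requested `pairwise` and `linearized`
#'   (`F_ST/(1-F_ST)`).
#' @export
fst <- function(sample, pairwise = FALSE) {
  sp <- droplevels(sample@subpop)
  if (nlevels(sp) < 2L)
    stop("F_ST requires at least two subpopulations")
  g <- sample@genotypes
  L <- length(sample@loci)
  groups <- split.data.frame(g, sp)
  comp <- rowSums(vapply(seq_len(L), function(l) .wcComponents(groups, l),
                         numeric(3)))
  globalTheta <- if (sum(comp) > 0) comp[1] / sum(comp) else NA_real_
  out <- list(global = unname(globalTheta))
  if (pairwise) {
    ni <- vapply(groups, nrow, 1L)
    usable <- names(groups)[ni >= 2L]
    if (length(usable) < length(groups))
      warning("subpopulations with n = 1 excluded from pairwise F_ST")
    S <- length(usable)
    pw <- matrix(NA_real_, S, S, dimnames = list(usable, usable))
    diag(pw) <- 0
    for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
      cij <- rowSums(vapply(seq_len(L), function(l)
        .wcComponents(groups[c(usable[i], usable[j])], l), numeric(3)))
      pw[i, j] <- pw[j, i] <- if (sum(cij) > 0) cij[1] / sum(cij) else NA_real_
    }
    out$pairwise <- pw
    cl <- pmax(pw, 0)
    out$linearized <- cl / (1 - cl)
  }
  out
}

## squared inter-individual genetic distance matrix
## identity: number of non-matching alleles per locus (0/1/2)
## size: squared repeat-count differences under the best within-locus pairing
.genoDistance <- function(g, metric = c("identity", "size")) {
  metric <- match.arg(metric)
  n <- nrow(g)
  L <- ncol(g) %/% 2L
  D <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a <- g[, 2L * l - 1L]; b <- g[, 2L * l]
    if (metric == "identity") {
      # pairing (a-a', b-b') vs (a-b', b-a'); alleles are sorted so the
      # direct pairing already minimizes mismatches
      m1 <- outer(a, a, "!=") + outer(b, b, "!=")
      m2 <- outer(a, b, "!=") + outer(b, a, "!=")
      D <- D + pmin(m1, m2)
    } else {
      m1 <- outer(a, a, "-")^2 + outer(b, b, "-")^2
      m2 <- outer(a, b, "-")^2 + outer(b, a, "-")^2
      D <- D + pmin(m1, m2)
    }
  }
  D
}

#' Two-level analysis of molecular variance
#'
#' Partitions genetic variance among and within subpopulations from squared
#' inter-individual distances (allele identity by default, or squared
#' allele-size differences), with a permutation test of the among-group
#' component. Percentages sum to 100 exactly.
#'
#' @param sample a [SampleMatrix-class] with >= 2 subpopulations.
#' @param nPerm label permutations for the p-value (0 skips).
#' @param metric `"identity"` or `"size"`.
#' @return list with `amongPct`, `withinPct`, `sigmaAmong`, `sigmaWithin`,
#'   `phiST`, `p`.
#' @export
amova <- function(sample, nPerm = 999L, metric = c("identity", "size")) {
  sp <- droplevels(sample@subpop)
  if (nlevels(sp) < 2L) stop("AMOVA requires at least two subpopulations")
  D <- .genoDistance(sample@genotypes, match.arg(metric))
  compute <- function(lab) {
    N <- length(lab)
    r <- nlevels(lab)
    ssTotal <- sum(D[lower.tri(D)]) / N
    ssWithin <- 0
    nk <- tabulate(lab)
    for (k in seq_len(r)) {
      idx <- which(as.integer(lab) == k)
      if (length(idx) > 1L)
        ssWithin <- ssWithin + sum(D[idx, idx][lower.tri(D[idx, idx])]) /
          length(idx)
    }
    ssAmong <- ssTotal - ssWithin
    dfA <- r - 1L; dfW <- N - r
    msA <- ssAmong / dfA; msW <- ssWithin / dfW
    nPrime <- (N - sum(nk^2) / N) / dfA
    sigW <- msW
    sigA <- (msA - msW) / nPrime
    c(sigA = sigA, sigW = sigW)
  }
  obs <- compute(sp)
  tot <- obs["sigA"] + obs["sigW"]
  # no molecular variance at all: nothing is partitioned among groups
  amongPct <- if (tot > 0) unname(100 * obs["sigA"] / tot) else 0
  p <- NA_real_
  if (nPerm > 0L && tot > 0) {
    null <- replicate(nPerm, {
      v <- compute(factor(sample(as.integer(sp)), levels = seq_len(nlevels(sp))))
      v["sigA"] / (v["sigA"] + v["sigW"])
    })
    p <- (1 + sum(null >= obs["sigA"] / tot)) / (nPerm + 1)
  }
  list(amongPct = amongPct, withinPct = 100 - amongPct,
       sigmaAmong = unname(obs["sigA"]), sigmaWithin = unname(obs["sigW"]),
       phiST = if (tot > 0) unname(obs["sigA"] / tot) else 0, p = p)
}

#' Modified Garza-Williamson statistic
#'
#' Per locus and subpopulation, `M = k / (R + 1)` with `k` the number of
#' alleles and `R` the allele size range in repeat units (Arlequin's
#' modification, bounded in (0, 1]); returns the mean over loci and
#' subpopulations plus the per-subpopulation breakdown.
#'
#' @param sample a [SampleMatrix-class] of SSR repeat counts.
#' @return list with `mean` and `perSubpop` matrix (subpop x locus).
#' @export
garzaWilliamson <- function(sample) {
  g <- sample@genotypes
  sp <- droplevels(sample@subpop)
  L <- length(sample@loci)
  groups <- split.data.frame(g, sp)
  M <- matrix(NA_real_, length(groups), L,
              dimnames = list(names(groups), sample@loci))
  for (k in seq_along(groups)) for (l in seq_len(L)) {
    ck <- .alleleCounts(groups[[k]], l)
    if (!length(ck)) next
    sz <- as.integer(names(ck))
    M[k, l] <- length(ck) / (diff(range(sz)) + 1)
  }
  list(mean = mean(M, na.rm = TRUE), perSubpop = M)
}

#' Loiselle pairwise kinship
#'
#' Multilocus Loiselle et al. (1995) kinship coefficients between all pairs
#' of individuals, with the small-sample correction `p(1-p)/(n_genes - 1)`
#' added per allele; reference allele frequencies are taken from the whole
#' sample. Monomorphic loci contribute nothing (they are effectively
#' excluded).
#'
#' @param sample a [SampleMatrix-class].
#' @return symmetric `n x n` matrix of kinship coefficients (diagonal `NA`).
#' @export
loiselleKinship <- function(sample) {
  g <- sample@genotypes
  n <- nrow(g)
  L <- length(sample@loci)
  num <- matrix(0, n, n)
  den <- 0
  corr <- 0
  for (l in seq_len(L)) {
    a1 <- g[, 2L * l - 1L]; a2 <- g[, 2L * l]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2L) next
    nGenes <- 2L * n
    for (al in alleles) {
      x <- ((a1 == al) + (a2 == al)) / 2   # individual allele frequency
      p <- mean(x)
      num <- num + outer(x - p, x - p)
      den <- den + p * (1 - p)
      corr <- corr + p * (1 - p) / (nGenes - 1)
    }
  }
  if (den == 0) stop("no polymorphic loci")
  Fij <- (num + corr) / den
  diag(Fij) <- NA_real_
  Fij
}

## balanced distance classes: pair ranks split into nClasses chunks whose
## sizes differ by at most one
.balancedClasses <- function(d, nClasses) {
  P <- length(d)
  sizes <- rep(P %/% nClasses, nClasses) +
    (seq_len(nClasses) <= P %% nClasses)
  cls <- integer(P)
  cls[order(d)] <- rep(seq_len(nClasses), times = sizes)
  cls
}

#' Kinship correlogram and the Sp statistic
#'
#' Regresses pairwise Loiselle kinship on the natural log of pairwise
#' geographic distance (slope `b_F`), bins pairs into `nClasses` distance
#' classes holding equal pair counts (within one), and summarizes the
#' spatial genetic structure as `Sp = -b_F / (1 - F1)` where `F1` is the
#' mean kinship in the first class. Significance and per-class 95%
#' envelopes come from randomly shuffling individual locations.
#'
#' @param sample a georeferenced [SampleMatrix-class].
#' @param nClasses number of distance classes (default 7).
#' @param nPerm location permutations (default 1000).
#' @return list with `correlogram` (data.frame class, meanDist, meanF, lo,
#'   hi, p), `bF`, `F1`, `Sp`, `p` (one-sided, positive structure).
#' @export
spStatistic <- function(sample, nClasses = 7L, nPerm = 1000L) {
  if (!nrow(sample@coords)) stop("sample has no coordinates")
  n <- nrow(sample@genotypes)
  if (n < 3L) stop("need at least 3 individuals")
  Fij <- loiselleKinship(sample)
  ij <- which(upper.tri(Fij), arr.ind = TRUE)
  ui <- ij[, 1L]; uj <- ij[, 2L]
  fv <- Fij[ij]
  xy <- sample@coords
  dpair <- function(ord) {
    d <- sqrt((xy[ord[ui], 1] - xy[ord[uj], 1])^2 +
              (xy[ord[ui], 2] - xy[ord[uj], 2])^2)
    pmax(d, 0.1)  # pairs closer than one patch pooled at the patch scale
  }
  d <- dpair(seq_len(n))
  if (max(d) <= 0.1) stop("all individuals at one location")
  stats <- function(d) {
    ld <- log(d)
    b <- stats::cov(fv, ld) / stats::var(ld)
    cls <- .balancedClasses(d, nClasses)
    mF <- tapply(fv, cls, mean)
    sp <- -b / (1 - mF[[1L]])
    list(b = b, classMeans = mF, sp = sp,
         classDist = tapply(d, cls, mean))
  }
  obs <- stats(d)
  lo <- hi <- pcls <- rep(NA_real_, nClasses)
  p <- NA_real_
  if (nPerm > 0L) {
    permSp <- numeric(nPerm)
    permF <- matrix(NA_real_, nPerm, nClasses)
    for (b in seq_len(nPerm)) {
      st <- stats(dpair(sample.int(n)))
      permSp[b] <- st$sp
      permF[b, ] <- st$classMeans
    }
    lo <- apply(permF, 2L, stats::quantile, 0.025)
    hi <- apply(permF, 2L, stats::quantile, 0.975)
    pcls <- vapply(seq_len(nClasses), function(k)
      (1 + sum(permF[, k] >= obs$classMeans[[k]])) / (nPerm + 1), 1)
    p <- (1 + sum(permSp >= obs$sp)) / (nPerm + 1)
  }
  list(correlogram = data.frame(
         class = seq_len(nClasses),
         meanDist = as.numeric(obs$classDist),
         meanF = as.numeric(obs$classMeans),
         lo = lo, hi = hi, p = pcls),
       bF = obs$b, F1 = obs$classMeans[[1L]],
       Sp = unname(obs$sp), p = p)
}

#' Turnover of alleles, genotypes or lineages among subpopulations
#'
#' Whittaker-normalized multiplicative beta diversity of the chosen units:
#' `T/O = (gamma / alpha_bar - 1) / (S - 1)` over `S` subpopulations, on
#' presences (Hill order q = 0, the default) or on Hill numbers of order `q`
#' computed from within-subpopulation relative abundances. 0 when all
#' subpopulations share the same composition, 1 when fully disjoint.
#'
#' @param sample a [SampleMatrix-class] (with `mlg`/`mll` labels for those
#'   levels).
#' @param level `"allele"`, `"mlg"` or `"mll"`.
#' @param q Hill order (0 = presence/absence).
#' @return turnover in `[0, 1]`.
#' @export
turnover <- function(sample, level = c("allele", "mlg", "mll"), q = 0) {
  level <- match.arg(level)
  sp <- droplevels(sample@subpop)
  S <- nlevels(sp)
  if (S < 2L) stop("turnover requires at least two subpopulations")
  units <- switch(level,
    allele = {
      g <- sample@genotypes
      L <- ncol(g) %/% 2L
      locus <- rep(rep(seq_len(L), each = nrow(g)), 2L)
      data.frame(sp = rep(sp, 2L * L),
                 unit = paste0(locus, ":", c(g[, seq(1, 2 * L, 2)],
                                             g[, seq(2, 2 * L, 2)])))
    },
    mlg = {
      if (!length(sample@mlg)) stop("sample has no MLG labels")
      data.frame(sp = sp, unit = as.character(sample@mlg))
    },
    mll = {
      if (!length(sample@mll)) stop("sample has no MLL labels")
      data.frame(sp = sp, unit = as.character(sample@mll))
    })
  tab <- table(units$sp, units$unit)
  hill <- function(w, q) {
    w <- w[w > 0] / sum(w)
    if (q == 0) length(w)
    else if (q == 1) exp(-sum(w * log(w)))
    else sum(w^q)^(1 / (1 - q))
  }
  alphaBar <- if (q == 1) exp(mean(log(apply(tab, 1L, hill, q = q))))
              else mean(apply(tab, 1L, hill, q = q))
  gamma <- hill(colSums(tab / rowSums(tab)) / S, q)
  unname((gamma / alphaBar - 1) / (S - 1))
}

## per-subpopulation allele-frequency list: for each locus, matrix allele x pop
.popFreqs <- function(sample) {
  sp <- droplevels(sample@subpop)
  groups <- split.data.frame(sample@genotypes, sp)
  lapply(seq_along(sample@loci), function(l) .lociFreqTables(groups, l))
}

#' Pairwise genetic distances between subpopulations
#'
#' `linearized_fst`: Slatkin's `theta/(1-theta)` on pairwise
#' Weir-Cockerham estimates (negatives clamped to 0); `edwards`:
#' Cavalli-Sforza & Edwards chord distance; `nei`: Nei's standard distance;
#' `reynolds`: Reynolds' coancestry distance.
#'
#' @param sample a [SampleMatrix-class].
#' @param metric distance to compute.
#' @return a symmetric matrix (subpop x subpop).
#' @export
geneticDistance <- function(sample,
                            metric = c("linearized_fst", "edwards", "nei",
                                       "reynolds")) {
  metric <- match.arg(metric)
  if (metric == "linearized_fst") {
    return(fst(sample, pairwise = TRUE)$linearized)
  }
  pf <- .popFreqs(sample)
  pops <- levels(droplevels(sample@subpop))
  S <- length(pops)
  D <- matrix(0, S, S, dimnames = list(pops, pops))
  L <- length(pf)
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    if (metric == "edwards") {
      v <- mean(vapply(pf, function(ft)
        1 - sum(sqrt(ft$freqs[, i] * ft$freqs[, j])), 1))
      D[i, j] <- D[j, i] <- sqrt(max(v, 0))
    } else if (metric == "nei") {
      jxy <- sum(vapply(pf, function(ft)
        sum(ft$freqs[, i] * ft$freqs[, j]), 1))
      jx <- sum(vapply(pf, function(ft) sum(ft$freqs[, i]^2), 1))
      jy <- sum(vapply(pf, function(ft) sum(ft$freqs[, j]^2), 1))
      D[i, j] <- D[j, i] <- -log(jxy / sqrt(jx * jy))
    } else { # reynolds
      num <- sum(vapply(pf, function(ft)
        sum((ft$freqs[, i] - ft$freqs[, j])^2), 1))
      den <- 2 * sum(vapply(pf, function(ft)
        1 - sum(ft$freqs[, i] * ft$freqs[, j]), 1))
      D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
    }
  }
  D
}

#' Mantel test of isolation by distance
#'
#' Mantel correlation between a pairwise genetic distance among
#' subpopulations and the natural logarithm of the geographic distance
#' between subpopulation centroids, with a permutation p-value
#' (via [vegan::mantel()]).
#'
#' @param sample a georeferenced [SampleMatrix-class] with >= 3
#'   subpopulations.
#' @param metric see [geneticDistance()].
#' @param nPerm permutations.
#' @return list with `r` and `p`.
#' @export
mantelIBD <- function(sample,
                      metric = c("linearized_fst", "edwards", "nei",
                                 "reynolds"),
                      nPerm = 999L) {
  if (!nrow(sample@coords)) stop("sample has no coordinates")
  sp <- droplevels(sample@subpop)
  if (nlevels(sp) < 3L) stop("Mantel IBD requires at least 3 subpopulations")
  gd <- geneticDistance(sample, match.arg(metric))
  keep <- rownames(gd)
  cx <- tapply(sample@coords[, 1L], sp, mean)[keep]
  cy <- tapply(sample@coords[, 2L], sp, mean)[keep]
  geo <- log(pmax(as.matrix(stats::dist(cbind(cx, cy))), 0.1))
  if (stats::sd(gd[upper.tri(gd)]) == 0 ||
      stats::sd(geo[upper.tri(geo)]) == 0)
    stop("zero-variance distance matrix")
  mt <- vegan::mantel(stats::as.dist(gd), stats::as.dist(geo),
                      permutations = nPerm)
  list(r = unname(mt$statistic), p = mt$signif)
}

#' The six-statistic ABC summary vector
#'
#' K (mean alleles per locus), R (mean allele size range), H_E, F_IS
#' (subpopulation means), global F_ST, and the mean modified
#' Garza-Williamson statistic — the summary vector used to compare
#' simulations against observed genotype data.
#'
#' @param sample a [SampleMatrix-class].
#' @return named numeric vector `K, R, H_E, F_IS, F_ST, NGW` (NA where a
#'   statistic is undefined, e.g. F_ST with one occupied tree).
#' @export
statVector <- function(sample) {
  if (!nrow(sample@genotypes))
    return(c(K = NA_real_, R = NA_real_, H_E = NA_real_, F_IS = NA_real_,
             F_ST = NA_real_, NGW = NA_real_))
  dv <- diversityStats(sample)
  fi <- fis(sample)
  th <- if (nlevels(droplevels(sample@subpop)) >= 2L)
    fst(sample)$global else NA_real_
  gw <- garzaWilliamson(sample)
  c(K = dv$K, R = dv$R, H_E = mean(dv$perSubpop$H_E, na.rm = TRUE),
    F_IS = fi$mean, F_ST = th, NGW = gw$mean)
}
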