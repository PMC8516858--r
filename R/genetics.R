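#' Allele pools for microsatellite founder genotypes
#'
#' An allele pool describes, for each SSR locus, the repeat-count alleles
#' circulating in the regional source population and their frequencies.
#' Founder seeds arriving from outside the landscape draw their genotypes
#' from this pool.
#'
#' @param nLoci number of diploid SSR loci (default 7).
#' @param nAlleles integer vector of candidate allele counts per locus; each
#'   locus draws its richness uniformly from this set.
#' @param sizeRange range (in repeat units) within which allele ladders are
#'   placed.
#' @param concentration Dirichlet concentration for allele frequencies;
#'   smaller values give more skewed frequency spectra.
#' @return an object of class `AllelePool`: a list with elements `sizes`
#'   (list of integer allele vectors per locus) and `freqs` (list of numeric
#'   frequency vectors per locus).
#' @export
allelePool <- function(nLoci = 7L, nAlleles = 4:8, sizeRange = c(8L, 40L),
                       concentration = 1) {
  stopifnot(nLoci >= 1, all(nAlleles >= 1), concentration > 0)
  sizes <- vector("list", nLoci)
  freqs <- vector("list", nLoci)
  for (l in seq_len(nLoci)) {
    k <- if (length(nAlleles) == 1L) nAlleles else sample(nAlleles, 1L)
    base <- sample(seq(sizeRange[1], max(sizeRange[1], sizeRange[2] - k)), 1L)
    # contiguous ladder with occasional gaps, as seen in real SSR data
    steps <- cumsum(c(0L, sample(1:2, k - 1L, replace = TRUE,
                                 prob = c(0.8, 0.2))))
    sizes[[l]] <- as.integer(base + steps)
    g <- stats::rgamma(k, shape = concentration)
    freqs[[l]] <- g / sum(g)
  }
  structure(list(sizes = sizes, freqs = freqs), class = "AllelePool")
}

#' Default regional allele pool
#'
#' A fixed synthetic pool (7 loci, 4-8 alleles each) built with an internal
#' seed so that every session sees the same regional gene pool. Used as the
#' standard source of founder genotypes in all shipped experiment
#' configurations.
#'
#' @return an `AllelePool`.
#' @export
defaultAllelePool <- function() {
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
  }
  withr_seed(20211014L, allelePool())
}

#' @export
print.AllelePool <- function(x, ...) {
  cat(sprintf("AllelePool: %d loci, %s alleles/locus\n",
              length(x$sizes),
              paste(range(vapply(x$sizes, length, 1L)), collapse = "-")))
  invisible(x)
}

#' Draw founder multilocus genotypes from an allele pool
#'
#' Each founder receives two alleles per locus. With probability
#' `targetHet` the locus is made heterozygous (two distinct alleles drawn
#' with pool frequencies, conditioned on being different), otherwise a single
#' allele is drawn and duplicated; the expected per-locus heterozygosity of
#' founders therefore equals `targetHet` at polymorphic loci. The default
#' reflects the mid-range of expected heterozygosities observed within
#' ball-moss subpopulations (0.27-0.51).
#'
#' @param pool an `AllelePool`.
#' @param n number of founders.
#' @param targetHet probability that a founder locus is heterozygous.
#' @return integer matrix `n x 2*nLoci`; columns `2l-1, 2l` hold the sorted
#'   allele pair of locus `l`.
#' @export
randomFounderGenotype <- function(pool, n = 1L, targetHet = 0.39) {
  stopifnot(inherits(pool, "AllelePool"), n >= 1,
            targetHet >= 0, targetHet <= 1)
  L <- length(pool$sizes)
  out <- matrix(0L, nrow = n, ncol = 2L * L)
  for (l in seq_len(L)) {
    a <- pool$sizes[[l]]
    f <- pool$freqs[[l]]
    if (length(a) == 0L) stop("empty allele pool at locus ", l)
    a1 <- a[sample.int(length(a), n, replace = TRUE, prob = f)]
    if (length(a) == 1L) {
      a2 <- a1
    } else {
      het <- stats::runif(n) < targetHet
      a2 <- a1
      if (any(het)) {
        # redraw until distinct from a1 (frequency-weighted, conditional)
        idx <- which(het)
        while (length(idx)) {
          a2[idx] <- a[sample.int(length(a), length(idx), replace = TRUE,
                                  prob = f)]
          idx <- idx[a2[idx] == a1[idx]]
        }
      }
    }
    out[, 2L * l - 1L] <- pmin(a1, a2)
    out[, 2L * l] <- pmax(a1, a2)
  }
  out
}

#' Stepwise mutation of SSR alleles
#'
#' Strict single-step mutation model: with probability `mu` per transmission
#' an allele gains or loses one repeat (equal probability), with a reflecting
#' boundary at one repeat so counts stay positive.
#'
#' @param alleles integer vector of repeat counts.
#' @param mu per-transmission mutation probability.
#' @return integer vector of (possibly) mutated repeat counts.
#' @export
mutateAllele <- function(alleles, mu) {
  stopifnot(mu >= 0, mu <= 1)
  if (mu == 0 || length(alleles) == 0L) return(as.integer(alleles))
  hit <- stats::runif(length(alleles)) < mu
  if (any(hit)) {
    step <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
    a <- as.integer(alleles)
    a[hit] <- a[hit] + step
    a[a < 1L] <- 2L  # reflect at one repeat
    return(a)
  }
  as.integer(alleles)
}

#' Selfed offspring genotypes
#'
#' Mendelian self-fertilization: per locus each of the two transmitted
#' gametes carries one of the parent's two alleles with equal probability,
#' then undergoes stepwise mutation.
#'
#' @param parents integer matrix `m x 2L` of parent genotypes (one row per
#'   offspring to produce; repeat rows for multiple offspring of one parent).
#' @param mu per-gamete stepwise mutation probability.
#' @return integer matrix of offspring genotypes, alleles sorted within
#'   locus.
#' @export
selfOffspring <- function(parents, mu = 0) {
  parents <- rbind(parents)
  m <- nrow(parents)
  L <- ncol(parents) %/% 2L
  out <- matrix(0L, m, 2L * L)
  for (l in seq_len(L)) {
    c1 <- 2L * l - 1L
    a <- parents[, c1]
    b <- parents[, c1 + 1L]
    g1 <- ifelse(stats::runif(m) < 0.5, a, b)
    g2 <- ifelse(stats::runif(m) < 0.5, a, b)
    g1 <- mutateAllele(g1, mu)
    g2 <- mutateAllele(g2, mu)
    out[, c1] <- pmin(g1, g2)
    out[, c1 + 1L] <- pmax(g1, g2)
  }
  out
}

#' Multilocus genotype registry
#'
#' Keeps the catalogue of distinct multilocus genotypes (MLGs) seen during a
#' simulation. Identical genotypes always map to the same integer id;
#' genotypes never seen before get fresh ids. MLG ids index rows of the
#' registry's genotype pool.
#'
#' @return a `LineageRegistry` (an environment with a key map and a growing
#'   genotype pool).
#' @export
newLineageRegistry <- function(nLoci = 7L) {
  reg <- new.env(parent = emptyenv())
  reg$keys <- new.env(parent = emptyenv(), hash = TRUE)
  reg$pool <- matrix(0L, 256L, 2L * nLoci)
  reg$n <- 0L
  class(reg) <- "LineageRegistry"
  reg
}

#' @export
print.LineageRegistry <- function(x, ...) {
  cat(sprintf("LineageRegistry: %d distinct MLGs over %d loci\n",
              x$n, ncol(x$pool) %/% 2L))
  invisible(x)
}

#' Assign MLG ids to genotypes
#'
#' Idempotent: registering the same genotype twice returns the same id.
#'
#' @param registry a `LineageRegistry`.
#' @param genotypes integer matrix of genotypes (rows), alleles sorted
#'   within locus.
#' @return integer vector of MLG ids, one per row.
#' @export
assignMLG <- function(registry, genotypes) {
  genotypes <- rbind(genotypes)
  keys <- apply(genotypes, 1L, paste, collapse = ".")
  ids <- integer(length(keys))
  for (i in seq_along(keys)) {
    id <- registry$keys[[keys[i]]]
    if (is.null(id)) {
      if (registry$n == nrow(registry$pool)) {
        registry$pool <- rbind(registry$pool,
                               matrix(0L, nrow(registry$pool),
                                      ncol(registry$pool)))
      }
      registry$n <- registry$n + 1L
      id <- registry$n
      registry$pool[id, ] <- genotypes[i, ]
      registry$keys[[keys[i]]] <- id
    }
    ids[i] <- id
  }
  ids
}

#' Retrieve genotypes by MLG id
#'
#' @param registry a `LineageRegistry`.
#' @param ids integer MLG ids.
#' @return integer genotype matrix with one row per id.
#' @export
mlgGenotypes <- function(registry, ids) {
  registry$pool[ids, , drop = FALSE]
}
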