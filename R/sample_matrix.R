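#' SampleMatrix: genotyped individuals with subpopulation labels
#'
#' The input of every genetic summary statistic: `n` diploid individuals at
#' `L` microsatellite loci (integer repeat counts, two columns per locus,
#' sorted low/high), each labelled with the host tree (subpopulation) it was
#' sampled from, and optionally georeferenced and tagged with its multilocus
#' genotype (MLG) and founder lineage (MLL) ids.
#'
#' @slot genotypes integer matrix `n x 2L`.
#' @slot loci locus names (length `L`).
#' @slot subpop factor of length `n`.
#' @slot coords numeric matrix `n x 2` (metres); may have zero rows.
#' @slot mlg,mll integer vectors (may be empty).
#' @export
setClass("SampleMatrix", representation(
  genotypes = "matrix",
  loci = "character",
  subpop = "factor",
  coords = "matrix",
  mlg = "integer",
  mll = "integer"
))

setValidity("SampleMatrix", function(object) {
  n <- nrow(object@genotypes)
  msg <- character()
  if (ncol(object@genotypes) %% 2L != 0L)
    msg <- c(msg, "genotypes must have two columns per locus")
  if (length(object@loci) != ncol(object@genotypes) %/% 2L)
    msg <- c(msg, "loci names must match genotype columns")
  if (length(object@subpop) != n)
    msg <- c(msg, "subpop length must equal the number of individuals")
  if (nrow(object@coords) && nrow(object@coords) != n)
    msg <- c(msg, "coords must have one row per individual (or none)")
  if (length(object@mlg) && length(object@mlg) != n)
    msg <- c(msg, "mlg length must equal the number of individuals")
  if (length(object@mll) && length(object@mll) != n)
    msg <- c(msg, "mll length must equal the number of individuals")
  if (n && any(object@genotypes < 1, na.rm = TRUE))
    msg <- c(msg, "repeat counts must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleMatrix
#'
#' @param genotypes integer matrix `n x 2L` of repeat counts.
#' @param subpop subpopulation (host tree) label per individual.
#' @param coords optional `n x 2` coordinate matrix (metres).
#' @param mlg,mll optional integer labels.
#' @param loci optional locus names.
#' @return a [SampleMatrix-class].
#' @export
sampleMatrix <- function(genotypes, subpop, coords = NULL, mlg = NULL,
                         mll = NULL, loci = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  L <- ncol(genotypes) %/% 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  new("SampleMatrix",
      genotypes = genotypes,
      loci = as.character(loci),
      subpop = factor(subpop),
      coords = if (is.null(coords)) matrix(numeric(0), 0, 2)
               else as.matrix(coords),
      mlg = if (is.null(mlg)) integer(0) else as.integer(mlg),
      mll = if (is.null(mll)) integer(0) else as.integer(mll))
}

setMethod("show", "SampleMatrix", function(object) {
  cat(sprintf("SampleMatrix: %d individuals, %d loci, %d subpopulations\n",
              nrow(object@genotypes), length(object@loci),
              nlevels(object@subpop)))
})

#' @describeIn SampleMatrix-class number of individuals.
#' @param x a `SampleMatrix`.
#' @export
setMethod("nrow", "SampleMatrix", function(x) nrow(x@genotypes))

#' Accessors for SampleMatrix
#' @param object a [SampleMatrix-class].
#' @return `genotypes`: the integer genotype matrix; `subpop`: the factor of
#'   subpopulation labels; `coords`: the coordinate matrix.
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname genotypes
#' @export
setMethod("genotypes", "SampleMatrix", function(object) object@genotypes)
#' @rdname genotypes
#' @export
setGeneric("subpop", function(object) standardGeneric("subpop"))
#' @rdname genotypes
#' @export
setMethod("subpop", "SampleMatrix", function(object) object@subpop)
#' @rdname genotypes
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname genotypes
#' @export
setMethod("coords", "SampleMatrix", function(object) object@coords)

#' Sample established plants from a simulation
#'
#' Draws, without replacement, up to `perTree` plants from each of up to
#' `maxTrees` occupied trees (trees in excess of `maxTrees` are themselves a
#' random subset). Trees holding fewer plants contribute all of them.
#'
#' @param state a `SimState`.
#' @param maxTrees maximum number of occupied trees to sample.
#' @param perTree maximum individuals per tree.
#' @return a [SampleMatrix-class]; empty population gives a 0-row matrix.
#' @export
samplePopulation <- function(state, maxTrees = 15L, perTree = 15L) {
  n <- length(state$age)
  L <- ncol(state$registry$pool) %/% 2L
  if (!n) {
    return(sampleMatrix(matrix(integer(0), 0, 2L * L),
                        subpop = factor(character(0))))
  }
  occTrees <- unique(state$host)
  if (length(occTrees) > maxTrees)
    occTrees <- sample(occTrees, maxTrees)
  pick <- integer(0)
  for (h in occTrees) {
    who <- which(state$host == h)
    if (length(who) > perTree) who <- sample(who, perTree)
    pick <- c(pick, who)
  }
  ps <- state$landscape@patchSize
  sampleMatrix(
    genotypes = mlgGenotypes(state$registry, state$geno[pick]),
    subpop = factor(state$host[pick]),
    coords = cbind((state$px[pick] + 0.5) * ps, (state$py[pick] + 0.5) * ps),
    mlg = state$geno[pick],
    mll = state$mll[pick])
}

#' Read and write Genepop files
#'
#' Standard Genepop format with 2-digit allele codes (4-digit genotypes;
#' 6-digit files are also read): a title line, one locus name per line,
#' and `POP`-delimited subpopulations with lines `id ,  0102 0304 ...`.
#' Missing data (code 0) become `NA`.
#'
#' @param file path.
#' @return `readGenepop`: a [SampleMatrix-class] (without coordinates).
#' @export
readGenepop <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  popAt <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(popAt)) stop("no POP lines: not a Genepop file")
  loci <- trimws(lines[2:(popAt[1] - 1L)])
  if (length(loci) == 1L && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  L <- length(loci)
  rows <- list(); pops <- character(0)
  bounds <- c(popAt, length(lines) + 1L)
  for (b in seq_along(popAt)) {
    block <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2L) stop("malformed Genepop line: ", ln)
      al <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(al) != L) stop("wrong number of loci in line: ", ln)
      w <- nchar(al[1]) %/% 2L
      g <- integer(2L * L)
      for (l in seq_len(L)) {
        a1 <- as.integer(substr(al[l], 1L, w))
        a2 <- as.integer(substr(al[l], w + 1L, 2L * w))
        g[2L * l - 1L] <- min(a1, a2)
        g[2L * l] <- max(a1, a2)
      }
      rows[[length(rows) + 1L]] <- g
      pops <- c(pops, paste0("pop", b))
    }
  }
  g <- do.call(rbind, rows)
  g[g == 0L] <- NA_integer_
  sampleMatrix(g, subpop = pops, loci = loci)
}

#' @rdname readGenepop
#' @param sample a [SampleMatrix-class] to write.
#' @param title title line.
#' @export
writeGenepop <- function(sample, file, title = "ballmoss export") {
  g <- sample@genotypes
  if (any(g > 99L, na.rm = TRUE))
    stop("2-digit Genepop export requires repeat counts <= 99")
  g[is.na(g)] <- 0L
  out <- c(title, sample@loci)
  for (lev in levels(sample@subpop)) {
    out <- c(out, "POP")
    for (i in which(sample@subpop == lev)) {
      codes <- sprintf("%02d%02d",
                       g[i, seq(1L, ncol(g), 2L)], g[i, seq(2L, ncol(g), 2L)])
      out <- c(out, paste0(lev, "_", i, " ,  ", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, file)
  invisible(file)
}
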