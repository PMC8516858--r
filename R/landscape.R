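#' @import methods
NULL

#' Landscape: a patch grid with a tree stand
#'
#' The landscape is a rectangular grid of 0.01 m2 soil patches (0.1 m side)
#' holding a stand of trees, each with a trunk, a circular crown and a
#' height. Two rasters are derived from the live trees: `canopy`, the number
#' of crowns covering each patch, and `trunk`, whether a trunk occupies the
#' patch. Patch indices are 0-based and half-open: a point at coordinate
#' `x` metres lies in patch column `floor(x / patchSize)`.
#'
#' @slot extent numeric length-2, landscape size in metres (x, y).
#' @slot patchSize patch side length in metres (default 0.1).
#' @slot trees data.frame with columns `id, x, y, dbh, height, crown, alive`
#'   (metres, cm for dbh).
#' @slot canopy integer matrix `[ny, nx]`, crowns covering each patch.
#' @slot trunk logical matrix `[ny, nx]`.
#' @export
setClass("Landscape", representation(
  extent = "numeric",
  patchSize = "numeric",
  trees = "data.frame",
  canopy = "matrix",
  trunk = "matrix"
))

setValidity("Landscape", function(object) {
  nx <- as.integer(round(object@extent[1] / object@patchSize))
  ny <- as.integer(round(object@extent[2] / object@patchSize))
  msg <- character()
  if (length(object@extent) != 2L || any(object@extent <= 0))
    msg <- c(msg, "extent must be two positive lengths (metres)")
  if (!identical(dim(object@canopy), c(ny, nx)))
    msg <- c(msg, "canopy raster does not match extent/patchSize")
  if (!identical(dim(object@trunk), c(ny, nx)))
    msg <- c(msg, "trunk raster does not match extent/patchSize")
  tr <- object@trees
  need <- c("id", "x", "y", "dbh", "height", "crown", "alive")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("trees must have columns:", paste(need, collapse = ", ")))
  else if (nrow(tr)) {
    if (any(tr$dbh <= 0)) msg <- c(msg, "tree dbh must be positive")
    if (any(tr$crown < tr$dbh / 200))
      msg <- c(msg, "crown radius must be at least the trunk radius")
    if (any(tr$x < 0 | tr$x > object@extent[1] |
            tr$y < 0 | tr$y > object@extent[2]))
      msg <- c(msg, "tree coordinates outside the landscape extent")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Landscape", function(object) {
  alive <- sum(object@trees$alive)
  cat(sprintf(
    "Landscape: %.1f x %.1f m (%.3f ha), %d live trees (%.1f trees/ha)\n",
    object@extent[1], object@extent[2],
    prod(object@extent) / 1e4, alive, treeDensity(object)))
  cat(sprintf("  patches: %d x %d (%.2f m); covered ground: %.1f%%\n",
              ncol(object@canopy), nrow(object@canopy), object@patchSize,
              100 * groundCover(object)))
})

#' @describeIn Landscape-class tree table accessor (live and dead trees).
#' @param object a `Landscape`.
#' @export
setGeneric("trees", function(object) standardGeneric("trees"))

#' @rdname Landscape-class
#' @export
setMethod("trees", "Landscape", function(object) object@trees)

#' Live-tree density in trees per hectare
#' @param landscape a `Landscape`.
#' @export
treeDensity <- function(landscape) {
  sum(landscape@trees$alive) / (prod(landscape@extent) / 1e4)
}

## rasterize live trees onto canopy-count and trunk rasters
rasterizeTrees <- function(trees, extent, patchSize) {
  nx <- as.integer(round(extent[1] / patchSize))
  ny <- as.integer(round(extent[2] / patchSize))
  canopy <- matrix(0L, ny, nx)
  trunk <- matrix(FALSE, ny, nx)
  live <- trees[trees$alive, , drop = FALSE]
  cx <- (seq_len(nx) - 0.5) * patchSize
  cy <- (seq_len(ny) - 0.5) * patchSize
  for (i in seq_len(nrow(live))) {
    for (pass in 1:2) {
      r <- if (pass == 1L) live$crown[i] else max(live$dbh[i] / 200, patchSize / 2)
      jx <- which(abs(cx - live$x[i]) <= r)
      jy <- which(abs(cy - live$y[i]) <= r)
      if (!length(jx) || !length(jy)) next
      d2 <- outer((cy[jy] - live$y[i])^2, (cx[jx] - live$x[i])^2, "+")
      inside <- d2 <= r^2
      if (pass == 1L) {
        canopy[jy, jx][inside] <- canopy[jy, jx][inside] + 1L
      } else {
        trunk[jy, jx][inside] <- TRUE
      }
    }
  }
  list(canopy = canopy, trunk = trunk)
}

newLandscape <- function(trees, extent, patchSize = 0.1) {
  ras <- rasterizeTrees(trees, extent, patchSize)
  new("Landscape", extent = as.numeric(extent), patchSize = patchSize,
      trees = trees, canopy = ras$canopy, trunk = ras$trunk)
}

## refresh rasters after any change to the tree table
refreshRasters <- function(landscape) {
  ras <- rasterizeTrees(landscape@trees, landscape@extent, landscape@patchSize)
  landscape@canopy <- ras$canopy
  landscape@trunk <- ras$trunk
  landscape
}

#' Tree allometry constants
#'
#' Crown radius and height are linear in DBH; saplings recruit at a minimum
#' DBH. The defaults give a 2 m crown at 33 cm DBH.
#'
#' @param crownPerDBH crown radius gained per cm of DBH (m/cm).
#' @param heightPerDBH height gained per cm of DBH (m/cm).
#' @param saplingDBH DBH of newly recruited trees (cm).
#' @return a named list.
#' @export
treeAllometry <- function(crownPerDBH = 0.06, heightPerDBH = 0.4,
                          saplingDBH = 5) {
  list(crownPerDBH = crownPerDBH, heightPerDBH = heightPerDBH,
       saplingDBH = saplingDBH)
}

#' Build a random static landscape
#'
#' Places `nTrees` trees uniformly at random (no trunk overlap) on a square
#' landscape of `areaHa` hectares, with identical crown radii and random
#' heights — the layout used for density sweeps.
#'
#' @param areaHa landscape area in hectares (default 0.40).
#' @param nTrees number of trees.
#' @param crownRadius common crown radius (m).
#' @param heightRange range of random tree heights (m).
#' @param dbh tree DBH in cm (default from crown allometry).
#' @param allometry see [treeAllometry()].
#' @param patchSize patch side (m).
#' @param maxTries placement retries per tree before failing.
#' @return a [Landscape-class] object.
#' @export
buildStaticLandscape <- function(areaHa = 0.40, nTrees, crownRadius = 2,
                                 heightRange = c(4, 12), dbh = NULL,
                                 allometry = treeAllometry(),
                                 patchSize = 0.1, maxTries = 1000L) {
  stopifnot(nTrees >= 0, areaHa > 0)
  side <- sqrt(areaHa * 1e4)
  extent <- c(side, side)
  if (is.null(dbh)) dbh <- crownRadius / allometry$crownPerDBH
  trunkR <- dbh / 200
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nTrees)) {
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      x <- stats::runif(1, trunkR, side - trunkR)
      y <- stats::runif(1, trunkR, side - trunkR)
      if (!length(xs) || min((xs - x)^2 + (ys - y)^2) > (2 * trunkR)^2) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", nTrees, " trees without trunk overlap")
    xs <- c(xs, x); ys <- c(ys, y)
  }
  tr <- data.frame(
    id = seq_len(nTrees),
    x = xs, y = ys, dbh = rep(dbh, nTrees),
    height = if (nTrees) stats::runif(nTrees, heightRange[1], heightRange[2])
             else numeric(0),
    crown = rep(crownRadius, nTrees),
    alive = rep(TRUE, nTrees))
  newLandscape(tr, extent, patchSize)
}

#' Build a landscape from an explicit tree layout
#'
#' @param treeTable data.frame with columns `x, y, dbh, height` (and
#'   optionally `id` and `crown`, the crown radius in metres; missing crowns
#'   come from the allometry).
#' @param extent landscape extent in metres; default is the bounding box of
#'   the trees plus `margin` (expanded so all crowns fit).
#' @param margin boundary margin (m) used when `extent` is derived.
#' @inheritParams buildStaticLandscape
#' @return a [Landscape-class] object.
#' @export
buildLayout <- function(treeTable, extent = NULL, margin = 2.5,
                        allometry = treeAllometry(), patchSize = 0.1) {
  stopifnot(all(c("x", "y", "dbh", "height") %in% names(treeTable)))
  if (anyDuplicated(treeTable[, c("x", "y")]))
    stop("duplicate tree coordinates")
  tr <- data.frame(
    id = if ("id" %in% names(treeTable)) treeTable$id
         else seq_len(nrow(treeTable)),
    x = treeTable$x, y = treeTable$y,
    dbh = treeTable$dbh, height = treeTable$height,
    crown = if ("crown" %in% names(treeTable)) treeTable$crown
            else treeTable$dbh * allometry$crownPerDBH,
    alive = TRUE)
  if (is.null(extent)) {
    pad <- margin + max(tr$crown, 0)
    extent <- c(max(tr$x) + pad, max(tr$y) + pad)
    tr$x <- tr$x - min(tr$x) + pad
    tr$y <- tr$y - min(tr$y) + pad
    extent <- c(max(tr$x) + pad, max(tr$y) + pad)
  }
  newLandscape(tr, extent, patchSize)
}

#' Shading fraction at patches
#'
#' Light interception at ground level: each crown layer over a patch removes
#' a fraction `perLayer` of the remaining light, so a patch under `k` crowns
#' is shaded by `1 - (1 - perLayer)^k`. Open ground has shading 0.
#'
#' @param landscape a `Landscape`.
#' @param px,py 0-based patch indices (vectors).
#' @param perLayer light fraction removed per crown layer.
#' @return shading fractions in `[0, 1]`.
#' @export
shadingAt <- function(landscape, px, py, perLayer = 0.5) {
  k <- landscape@canopy[cbind(py + 1L, px + 1L)]
  1 - (1 - perLayer)^k
}

## shading experienced by an epiphyte attached at a patch: its own host
## crown does not shade it, only layers above (k - 1)
epiphyteShadingAt <- function(landscape, px, py, perLayer = 0.5) {
  k <- pmax(landscape@canopy[cbind(py + 1L, px + 1L)] - 1L, 0L)
  1 - (1 - perLayer)^k
}

#' Covered ground fraction
#'
#' Fraction of patches covered by at least one crown or a trunk, i.e.
#' `1 - open/total`. The complement (`1 - groundCover`) is the open-ground
#' fraction that limits tree regeneration.
#'
#' @param landscape a `Landscape`.
#' @export
groundCover <- function(landscape) {
  mean(landscape@canopy > 0L | landscape@trunk)
}

#' Patches under the crown of one tree
#'
#' @param landscape a `Landscape`.
#' @param treeId a tree id.
#' @return integer matrix with columns `px, py` (0-based patch indices).
#' @export
crownPatches <- function(landscape, treeId) {
  tr <- landscape@trees[match(treeId, landscape@trees$id), ]
  ps <- landscape@patchSize
  nx <- ncol(landscape@canopy); ny <- nrow(landscape@canopy)
  cx <- (seq_len(nx) - 0.5) * ps
  cy <- (seq_len(ny) - 0.5) * ps
  jx <- which(abs(cx - tr$x) <= tr$crown)
  jy <- which(abs(cy - tr$y) <= tr$crown)
  if (!length(jx) || !length(jy))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("px", "py"))))
  g <- expand.grid(px = jx, py = jy)
  keep <- (cx[g$px] - tr$x)^2 + (cy[g$py] - tr$y)^2 <= tr$crown^2
  cbind(px = g$px[keep] - 1L, py = g$py[keep] - 1L)
}

#' Advance tree stand dynamics by `dt` years
#'
#' Growth (DBH +0.13 cm/year, crown and height following the allometry),
#' Yoda self-thinning, and natural regeneration (each live tree recruits a
#' sapling with probability `regenRate` per year, placed on a random open
#' patch; recruitment stops when open ground drops below `minOpenFrac`).
#'
#' Self-thinning follows the -3/2 line `N_max/ha = (yodaK / mean(dbh^3))^(2/3)`:
#' while the stand sits above the line, suppressed (smallest-DBH) trees die,
#' at most a fraction `maxThinFrac` of the stand per year so that
#' overcrowded stands converge to the line gradually rather than in one
#' step.
#'
#' @param landscape a `Landscape`.
#' @param dt years to advance.
#' @param regenRate per-tree annual recruitment probability (default 0.15).
#' @param growthRate mean DBH increment, cm/year (default 0.13).
#' @param yodaK self-thinning constant, calibrated so unmanaged stands
#'   equilibrate near 180 trees/ha (see [defaultYodaK()]).
#' @param maxThinFrac maximum fraction of live trees lost to thinning per
#'   year.
#' @param minOpenFrac open-ground fraction below which recruitment stops.
#' @param allometry see [treeAllometry()].
#' @return a list with elements `landscape` (updated) and `diedIds`
#'   (ids of trees that died, whose resident epiphytes must die too).
#' @export
stepTreeDynamics <- function(landscape, dt = 1, regenRate = 0.15,
                             growthRate = 0.13, yodaK = defaultYodaK(),
                             maxThinFrac = 0.20, minOpenFrac = 0.2,
                             allometry = treeAllometry()) {
  stopifnot(dt > 0)
  tr <- landscape@trees
  live <- which(tr$alive)
  areaHa <- prod(landscape@extent) / 1e4
  # growth
  inc <- growthRate * dt
  tr$dbh[live] <- tr$dbh[live] + inc
  tr$crown[live] <- tr$crown[live] + inc * allometry$crownPerDBH
  tr$height[live] <- tr$height[live] + inc * allometry$heightPerDBH
  diedIds <- integer(0)
  # Yoda self-thinning: mean mass proxy w = dbh^3, taken over the
  # established cohort (suppressed saplings do not set the line)
  live <- which(tr$alive)
  if (length(live)) {
    est <- live[tr$dbh[live] >= 10]
    wbar <- mean(tr$dbh[if (length(est)) est else live]^3)
    nMax <- (yodaK / wbar)^(2 / 3) * areaHa
    excess <- length(live) - floor(nMax)
    excess <- min(excess, ceiling(maxThinFrac * dt * length(live)))
    if (excess > 0) {
      kill <- live[order(tr$dbh[live])[seq_len(excess)]]
      tr$alive[kill] <- FALSE
      diedIds <- tr$id[kill]
    }
  }
  landscape@trees <- tr
  landscape <- refreshRasters(landscape)
  # regeneration on open ground
  nLive <- sum(tr$alive)
  recruits <- stats::rbinom(1L, nLive, min(1, regenRate * dt))
  if (recruits > 0 && (1 - groundCover(landscape)) >= minOpenFrac) {
    landscape <- addSaplings(landscape, recruits, allometry)
  }
  list(landscape = landscape, diedIds = diedIds)
}

## place n saplings on random open patches; returns updated landscape
addSaplings <- function(landscape, n, allometry = treeAllometry(),
                        warnOnShortfall = FALSE) {
  open <- which(!(landscape@canopy > 0L | landscape@trunk))
  n <- as.integer(n)
  if (length(open) < n) {
    if (warnOnShortfall)
      warning("insufficient open ground: adding ", length(open),
              " of ", n, " trees")
    n <- length(open)
  }
  if (n == 0L) return(landscape)
  ny <- nrow(landscape@canopy)
  pick <- sample(open, n)
  py <- (pick - 1L) %% ny
  px <- (pick - 1L) %/% ny
  ps <- landscape@patchSize
  tr <- landscape@trees
  newIds <- if (nrow(tr)) max(tr$id) + seq_len(n) else seq_len(n)
  sap <- data.frame(
    id = newIds,
    x = (px + 0.5) * ps, y = (py + 0.5) * ps,
    dbh = allometry$saplingDBH,
    height = allometry$saplingDBH * allometry$heightPerDBH,
    crown = allometry$saplingDBH * allometry$crownPerDBH,
    alive = TRUE)
  landscape@trees <- rbind(tr, sap)
  refreshRasters(landscape)
}

#' Abrupt anthropogenic change in tree density
#'
#' Deforestation removes a fraction of the live trees uniformly at random,
#' leaving exactly `round((1 - magnitude) * N)` alive. Reforestation adds
#' `magnitude` saplings per hectare on random open patches; if open ground is
#' insufficient, as many as fit are added with a warning.
#'
#' @param landscape a `Landscape`.
#' @param mode `"deforest"` or `"reforest"`.
#' @param magnitude fraction removed (deforest, e.g. 0/0.10/0.50/0.90) or
#'   trees per hectare added (reforest, e.g. 0/25/125/225).
#' @param allometry see [treeAllometry()].
#' @return list with `landscape` and `diedIds` (empty for reforestation).
#' @export
applyDensityChange <- function(landscape, mode = c("deforest", "reforest"),
                               magnitude, allometry = treeAllometry()) {
  mode <- match.arg(mode)
  diedIds <- integer(0)
  if (mode == "deforest") {
    stopifnot(magnitude >= 0, magnitude <= 1)
    live <- which(landscape@trees$alive)
    keep <- round((1 - magnitude) * length(live))
    nKill <- length(live) - keep
    if (nKill > 0) {
      kill <- sample(live, nKill)
      landscape@trees$alive[kill] <- FALSE
      diedIds <- landscape@trees$id[kill]
      landscape <- refreshRasters(landscape)
    }
  } else {
    stopifnot(magnitude >= 0)
    areaHa <- prod(landscape@extent) / 1e4
    n <- round(magnitude * areaHa)
    landscape <- addSaplings(landscape, n, allometry, warnOnShortfall = TRUE)
  }
  list(landscape = landscape, diedIds = diedIds)
}

#' Read / write tree layout CSV
#'
#' The layout exchange format has a header with columns
#' `id,x_m,y_m,dbh_cm,height_m` and optionally `crown_m`.
#'
#' @param file path to a CSV file.
#' @return `readTreeLayout`: a data.frame suitable for [buildLayout()].
#' @export
readTreeLayout <- function(file) {
  d <- utils::read.csv(file)
  need <- c("id", "x_m", "y_m", "dbh_cm", "height_m")
  if (!all(need %in% names(d)))
    stop("layout CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(id = d$id, x = d$x_m, y = d$y_m, dbh = d$dbh_cm,
                    height = d$height_m)
  if ("crown_m" %in% names(d)) out$crown <- d$crown_m
  out
}

#' @rdname readTreeLayout
#' @param landscape a `Landscape` to export.
#' @export
writeTreeLayout <- function(landscape, file) {
  tr <- landscape@trees[landscape@trees$alive, ]
  utils::write.csv(
    data.frame(id = tr$id, x_m = tr$x, y_m = tr$y, dbh_cm = tr$dbh,
               height_m = tr$height, crown_m = tr$crown),
    file, row.names = FALSE)
  invisible(file)
}

#' Export the patch grid as a tidy raster table
#'
#' @param landscape a `Landscape`.
#' @param perLayer shading per crown layer (see [shadingAt()]).
#' @return data.frame with `patch_x, patch_y, cover_class, shading`.
#' @export
gridSnapshot <- function(landscape, perLayer = 0.5) {
  ny <- nrow(landscape@canopy); nx <- ncol(landscape@canopy)
  px <- rep(0:(nx - 1L), each = ny)
  py <- rep(0:(ny - 1L), times = nx)
  cls <- ifelse(as.vector(landscape@trunk), "trunk",
                ifelse(as.vector(landscape@canopy) > 0L, "crown", "open"))
  data.frame(patch_x = px, patch_y = py, cover_class = cls,
             shading = shadingAt(landscape, px, py, perLayer))
}
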