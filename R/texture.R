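# Gray-level texture matrix builders (GLCM, GLRLM, GLSZM, GLDM, NGTDM).
# All builders take the integer level volume of a DiscretizedImage (0 marks
# out-of-mask voxels) and work on a zero-padded copy so neighbourhood
# arithmetic needs no boundary checks.

padLevels <- function(L) {
  d <- dim(L)
  out <- array(0L, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- L
  out
}

linOffsets <- function(offs, d) offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]

#' Gray level co-occurrence matrices
#'
#' Symmetric pair counts at Chebyshev distance 1 over the 13 unique 3D
#' directions. Returns one count matrix per direction (the aggregation mode
#' is applied at the feature stage).
#'
#' @param disc a `DiscretizedImage` from [discretize()], or its level volume.
#' @param nLevels number of gray levels (taken from `disc` when omitted).
#' @return list of 13 `nLevels x nLevels` symmetric count matrices.
#' @export
glcmMatrices <- function(disc, nLevels = NULL) {
  L <- if (inherits(disc, "DiscretizedImage")) disc$levels else disc
  Ng <- nLevels %||% if (inherits(disc, "DiscretizedImage")) disc$nLevels else max(L)
  Lp <- padLevels(L)
  d <- dim(Lp)
  vox <- which(Lp > 0L)
  lev <- Lp[vox]
  dirs <- directions13()
  louts <- linOffsets(dirs, d)
  lapply(seq_len(nrow(dirs)), function(k) {
    nb <- Lp[vox + louts[k]]
    keep <- nb > 0L
    cnt <- tabulate((nb[keep] - 1L) * Ng + lev[keep], Ng * Ng)
    m <- matrix(cnt, Ng, Ng)
    m + t(m)
  })
}

#' Gray level run length matrices
#'
#' Run counts per direction: entry (i, j) is the number of maximal runs of
#' level i and length j along the direction. One matrix per direction.
#'
#' @inheritParams glcmMatrices
#' @return list of 13 `nLevels x maxRunLength` count matrices.
#' @export
glrlmMatrices <- function(disc, nLevels = NULL) {
  L <- if (inherits(disc, "DiscretizedImage")) disc$levels else disc
  Ng <- nLevels %||% if (inherits(disc, "DiscretizedImage")) disc$nLevels else max(L)
  Lp <- padLevels(L)
  d <- dim(Lp)
  dirs <- directions13()
  louts <- linOffsets(dirs, d)
  inm <- Lp > 0L
  lapply(seq_len(nrow(dirs)), function(k) {
    o <- louts[k]
    vox <- which(inm)
    starts <- vox[Lp[vox - o] != Lp[vox]]
    lev <- Lp[starts]
    len <- rep(1L, length(starts))
    cur <- starts
    active <- seq_along(starts)
    while (length(active)) {
      nxt <- cur[active] + o
      ok <- Lp[nxt] == lev[active]
      cur[active[ok]] <- nxt[ok]
      len[active[ok]] <- len[active[ok]] + 1L
      active <- active[ok]
    }
    maxLen <- max(len)
    matrix(tabulate((len - 1L) * Ng + lev, Ng * maxLen), Ng, maxLen)
  })
}

#' Gray level size zone matrix
#'
#' Zones are 26-connected components of equal gray level; entry (i, s) counts
#' zones of level i and size s voxels.
#'
#' @inheritParams glcmMatrices
#' @return a `nLevels x maxZoneSize` count matrix.
#' @export
glszmMatrix <- function(disc, nLevels = NULL) {
  L <- if (inherits(disc, "DiscretizedImage")) disc$levels else disc
  Ng <- nLevels %||% if (inherits(disc, "DiscretizedImage")) disc$nLevels else max(L)
  Lp <- padLevels(L)
  d <- dim(Lp)
  louts <- linOffsets(neighbours26(), d)
  todo <- Lp > 0L
  zoneLev <- integer(0); zoneSize <- integer(0)
  seeds <- which(todo)
  for (s in seeds) {
    if (!todo[s]) next
    lev <- Lp[s]
    todo[s] <- FALSE
    frontier <- s
    size <- 1L
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, louts, "+")))
      cand <- cand[todo[cand] & Lp[cand] == lev]
      todo[cand] <- FALSE
      size <- size + length(cand)
      frontier <- cand
    }
    zoneLev <- c(zoneLev, lev); zoneSize <- c(zoneSize, size)
  }
  maxSize <- max(zoneSize)
  matrix(tabulate((zoneSize - 1L) * Ng + zoneLev, Ng * maxSize), Ng, maxSize)
}

#' Gray level dependence matrix
#'
#' For each in-mask voxel, the dependence is the number of 26-neighbours with
#' the same gray level (tolerance alpha = 0). Entry (i, j) counts voxels of
#' level i with dependence j - 1 (the column index includes the centre voxel
#' so it starts at 1).
#'
#' @inheritParams glcmMatrices
#' @return a `nLevels x (maxDependence + 1)` count matrix.
#' @export
gldmMatrix <- function(disc, nLevels = NULL) {
  L <- if (inherits(disc, "DiscretizedImage")) disc$levels else disc
  Ng <- nLevels %||% if (inherits(disc, "DiscretizedImage")) disc$nLevels else max(L)
  Lp <- padLevels(L)
  d <- dim(Lp)
  louts <- linOffsets(neighbours26(), d)
  vox <- which(Lp > 0L)
  lev <- Lp[vox]
  dep <- integer(length(vox))
  for (o in louts) dep <- dep + (Lp[vox + o] == lev)
  j <- dep + 1L
  maxJ <- max(j)
  matrix(tabulate((j - 1L) * Ng + lev, Ng * maxJ), Ng, maxJ)
}

#' Neighbouring gray tone difference matrix
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' neighbourhood mean gray level A is computed over in-mask neighbours; the
#' matrix stores, per level i, the voxel count n_i and the summed absolute
#' deviation s_i = sum |i - A|.
#'
#' @inheritParams glcmMatrices
#' @return data.frame with columns `level`, `n`, `s`.
#' @export
ngtdmTable <- function(disc, nLevels = NULL) {
  L <- if (inherits(disc, "DiscretizedImage")) disc$levels else disc
  Ng <- nLevels %||% if (inherits(disc, "DiscretizedImage")) disc$nLevels else max(L)
  Lp <- padLevels(L)
  d <- dim(Lp)
  louts <- linOffsets(neighbours26(), d)
  vox <- which(Lp > 0L)
  lev <- Lp[vox]
  nbSum <- numeric(length(vox)); nbCnt <- integer(length(vox))
  for (o in louts) {
    v <- Lp[vox + o]
    inn <- v > 0L
    nbSum[inn] <- nbSum[inn] + v[inn]
    nbCnt <- nbCnt + inn
  }
  has <- nbCnt > 0L
  devs <- abs(lev[has] - nbSum[has] / nbCnt[has])
  data.frame(
    level = seq_len(Ng),
    n = tabulate(lev[has], Ng),
    s = vapply(seq_len(Ng), function(i) sum(devs[lev[has] == i]), numeric(1)))
}
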