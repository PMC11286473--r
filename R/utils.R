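# Internal array / RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# linear indices of the sub-block xs x ys x zs of an array with dim d
blockIndices <- function(xs, ys, zs, d) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  ix <- rep.int(xs, ny * nz)
  iy <- rep.int(rep(ys, each = nx), nz)
  iz <- rep(zs, each = nx * ny)
  ix + (iy - 1L) * d[1] + (iz - 1L) * d[1] * d[2]
}

# voxel pairs (from, to = from + off) with both endpoints inside the grid
offsetPairs <- function(d, off) {
  xs <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  ys <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  zs <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
  if (!length(xs) || !length(ys) || !length(zs))
    return(list(from = integer(0), to = integer(0)))
  from <- blockIndices(xs, ys, zs, d)
  list(from = from, to = from + off[1] + off[2] * d[1] + off[3] * d[1] * d[2])
}

# out[p] = a[p - off], fill outside
arrayShift <- function(a, off, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  p <- offsetPairs(d, off)
  out[p$to] <- a[p$from]
  out
}

# the 13 unique 3D direction offsets (one of each +/- pair)
directions13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE]
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[length(nz)] > 0  # keep the representative whose last nonzero entry is +
  })
  unname(offs[keep, , drop = FALSE])
}

# all 26 neighbour offsets
neighbours26 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE])
}

# solid ellipsoid mask |(p - center)/radii|^2 <= 1
ellipsoidMask <- function(d, center, radii) {
  x <- (seq_len(d[1]) - center[1]) / radii[1]
  y <- (seq_len(d[2]) - center[2]) / radii[2]
  z <- (seq_len(d[3]) - center[3]) / radii[3]
  q <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(q <= 1, d)
}

# shift along one axis by +/-1 with fill, via cheap slab indexing
shiftAxis1 <- function(a, axis, k, fill = FALSE) {
  d <- dim(a)
  idx <- seq_len(d[axis]) - k
  pad <- idx < 1 | idx > d[axis]
  idx[pad] <- 1L
  out <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  if (any(pad)) {
    switch(axis, out[pad, , ] <- fill, out[, pad, ] <- fill,
           out[, , pad] <- fill)
  }
  out
}

# binary dilation by the 6-neighbourhood (cross) or 26-neighbourhood
# (Chebyshev ball, computed separably)
dilateMask <- function(mask, iter = 1L, conn = c("6", "26")) {
  out <- mask
  conn <- match.arg(conn)
  for (i in seq_len(iter)) {
    if (conn == "6") {
      acc <- out
      for (ax in 1:3) for (k in c(-1L, 1L))
        acc <- acc | shiftAxis1(out, ax, k, FALSE)
      out <- acc
    } else {
      for (ax in 1:3)
        out <- out | shiftAxis1(out, ax, -1L, FALSE) | shiftAxis1(out, ax, 1L, FALSE)
    }
  }
  out
}

# dilation restricted to the mask bounding box (padded), for small masks in
# large volumes
dilateInBox <- function(mask, iter = 1L, conn = "26") {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - iter, 1L)
  hi <- pmin(apply(idx, 2, max) + iter, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- mask
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dilateMask(sub, iter, conn)
  out
}

maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  colMeans(idx)
}

# crop an array to the bounding box of `mask`; returns list(arr, mask)
cropToMask <- function(arr, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rx <- range(idx[, 1]); ry <- range(idx[, 2]); rz <- range(idx[, 3])
  list(arr = arr[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE],
       mask = mask[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE])
}

# Draws from a normal truncated at `lower` whose location is adjusted so the
# realized expectation equals `mean` (used so physical floors do not bias the
# configured regional targets).
rtruncnormMeanMatched <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  ploss <- pnorm(lower, mean, sd)
  if (ploss < 1e-10) return(rnorm(n, mean, sd))
  truncMean <- function(m) {
    a <- (lower - m) / sd
    m + sd * dnorm(a) / (1 - pnorm(a))
  }
  f <- function(m) truncMean(m) - mean
  lo <- mean - 6 * sd
  m0 <- uniroot(f, lower = lo, upper = mean + sd, tol = 1e-10)$root
  a <- (lower - m0) / sd
  u <- runif(n)
  m0 + sd * qnorm(pnorm(a) + u * (1 - pnorm(a)))
}

ensure3d <- function(a, what = "volume") {
  if (is.null(dim(a)) || length(dim(a)) != 3)
    stop(what, " must be a 3D array")
  invisible(a)
}

sameDim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) stop(what, " must share the same dimensions")
  invisible(TRUE)
}
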