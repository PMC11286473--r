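# Brute-force oracles for the texture matrices, written as plain coordinate
# loops -- deliberately independent of the vectorized builders they check.

oracleDirections <- function() {
  dirs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nz <- c(dx, dy, dz)[c(dx, dy, dz) != 0]
    if (nz[length(nz)] > 0) dirs[[length(dirs) + 1]] <- c(dx, dy, dz)
  }
  dirs
}

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

bfGLCM <- function(L, off) {
  d <- dim(L); Ng <- max(L)
  m <- matrix(0L, Ng, Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (a == 0) next
    for (s in c(1L, -1L)) {  # symmetric: both directions
      q <- c(x, y, z) + s * off
      if (!inGrid(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (b > 0) m[a, b] <- m[a, b] + 1L
    }
  }
  m
}

bfGLRLM <- function(L, off) {
  d <- dim(L); Ng <- max(L)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - off
    if (inGrid(prev, d) && L[prev[1], prev[2], prev[3]] == a) next  # not a run start
    len <- 1L
    q <- c(x, y, z) + off
    while (inGrid(q, d) && L[q[1], q[2], q[3]] == a) {
      len <- len + 1L
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  if (!length(runs)) return(matrix(0L, Ng, 1))
  rm <- do.call(rbind, runs)
  m <- matrix(0L, Ng, max(rm[, 2]))
  for (r in seq_len(nrow(rm))) m[rm[r, 1], rm[r, 2]] <- m[rm[r, 1], rm[r, 2]] + 1L
  m
}

bfGLSZM <- function(L) {
  d <- dim(L); Ng <- max(L)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || L[x, y, z] == 0) next
    lev <- L[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (inGrid(q, d) && !seen[q[1], q[2], q[3]] &&
            L[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zm <- do.call(rbind, zones)
  m <- matrix(0L, Ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) m[zm[r, 1], zm[r, 2]] <- m[zm[r, 1], zm[r, 2]] + 1L
  m
}

bfGLDM <- function(L) {
  d <- dim(L); Ng <- max(L)
  rows <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (a == 0) next
    dep <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (inGrid(q, d) && L[q[1], q[2], q[3]] == a) dep <- dep + 1L
    }
    rows[[length(rows) + 1]] <- c(a, dep + 1L)
  }
  rm <- do.call(rbind, rows)
  m <- matrix(0L, Ng, max(rm[, 2]))
  for (r in seq_len(nrow(rm))) m[rm[r, 1], rm[r, 2]] <- m[rm[r, 1], rm[r, 2]] + 1L
  m
}

bfNGTDM <- function(L) {
  d <- dim(L); Ng <- max(L)
  n <- integer(Ng); s <- numeric(Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (a == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (inGrid(q, d) && L[q[1], q[2], q[3]] > 0)
        nb <- c(nb, L[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    n[a] <- n[a] + 1L
    s[a] <- s[a] + abs(a - mean(nb))
  }
  data.frame(level = seq_len(Ng), n = n, s = s)
}

# brute-force all-pairs AUC oracle
bfAUC <- function(scores, truth) {
  pos <- scores[truth == "poor"]; neg <- scores[truth == "good"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

randomLevelVolume <- function(dim3, nLevels, maskProb = 0.85) {
  L <- array(sample.int(nLevels, prod(dim3), replace = TRUE), dim3)
  L[runif(prod(dim3)) > maskProb] <- 0L
  if (all(L == 0)) L[1] <- 1L
  L
}
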