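# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no cpp_* calls, no shared helpers).

# flood-fill connected-component labeling, queue-based
oracleLabels <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (conn == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_along(dr)) {
        r <- p[1] + dr[k]; c <- p[2] + dc[k]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# per-pixel 3x3 median by explicit window sort with edge replication
oracleMedian3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- pmin(pmax(r + (-1:1), 1), nr)
    cs <- pmin(pmax(c + (-1:1), 1), nc)
    out[r, c] <- sort(as.vector(m[rs, cs]))[5]
  }
  out
}

# per-component area / perimeter (exposed 4-edges, border counts) from a
# label map
oracleAreaPerim <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  K <- max(lab)
  area <- integer(K); perim <- integer(K)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- lab[r, c]
    if (k == 0L) next
    area[k] <- area[k] + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc
      if (outside || lab[rr, cc] == 0L) perim[k] <- perim[k] + 1L
    }
  }
  list(area = area, perim = perim)
}

# exact Euclidean distance of every in-mask pixel to the nearest out-of-mask
# pixel (image border is NOT background), by full pairwise distances
oracleDistmap <- function(mask) {
  inn <- which(mask, arr.ind = TRUE)
  out <- which(!mask, arr.ind = TRUE)
  d <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(out) == 0L) return(d)
  for (i in seq_len(nrow(inn))) {
    d[inn[i, 1], inn[i, 2]] <-
      sqrt(min((inn[i, 1] - out[, 1])^2 + (inn[i, 2] - out[, 2])^2))
  }
  d
}

# neighbor census on a skeleton: 8-neighbor degree of every skeleton pixel
oracleSkeletonCensus <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  nodes <- 0L; endpoints <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    deg <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (skel[rr, cc]) deg <- deg + 1L
    }
    if (deg == 1L) endpoints <- endpoints + 1L
    if (deg >= 3L) nodes <- nodes + 1L
  }
  list(nodes = nodes, endpoints = endpoints)
}

# tie-corrected pairwise concordance AUC by explicit double loop
oraclePairAUC <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    if (p > n) tot <- tot + 1 else if (p == n) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# expand a 2x3 contingency matrix into per-subject scores/outcomes
expandTable <- function(cnt) {
  scores <- integer(0); outcomes <- integer(0)
  for (i in 1:2) for (j in 1:3) {
    k <- cnt[i, j]
    scores <- c(scores, rep(j - 1L, k))
    outcomes <- c(outcomes, rep(2L - i, k)) # row 1 = fractured = 1
  }
  list(scores = scores, outcomes = outcomes)
}

# random blobby binary image: thresholded sum of gaussian bumps
randomBlobs <- function(side, nBlobs = 6, seed = 1) {
  set.seed(seed)
  f <- matrix(0, side, side)
  for (b in seq_len(nBlobs)) {
    cr <- runif(1, 1, side); cc <- runif(1, 1, side); s <- runif(1, 2, side / 5)
    rr <- matrix(seq_len(side), side, side)
    cc2 <- matrix(seq_len(side), side, side, byrow = TRUE)
    f <- f + exp(-((rr - cr)^2 + (cc2 - cc)^2) / (2 * s^2))
  }
  f + matrix(rnorm(side * side, sd = 0.02), side, side) >
    quantile(f, runif(1, 0.4, 0.8))
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1]
rot90cw <- function(m) t(m[nrow(m):1, ]) # 90-degree clockwise rotation
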