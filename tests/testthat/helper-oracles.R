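# Independent brute-force oracles used to check the package's
# implementations. They deliberately avoid the package's internal code
# paths: plain double loops, base-R svd, grid searches.

# trajectory with random coordinates (no structure): frames x n x 3
randomTrajectory <- function(nFrames, n, seed = 1, spread = 10) {
  set.seed(seed)
  coords <- array(rnorm(nFrames * n * 3, sd = spread), c(nFrames, n, 3))
  CalphaTrajectory(coords)
}

# pairwise distance-variance matrix by explicit double loop
oracleDfm <- function(coords) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- numeric(nf)
    for (f in seq_len(nf))
      d[f] <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
    A[i, j] <- A[j, i] <- mean((d - mean(d))^2)
  }
  A
}

# strain by explicit double loop: p_i = sum_j A_ij f(mean d_ij)
oracleStrain <- function(coords, cutoff = 5, width = 0.5) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  p <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- numeric(nf)
    for (f in seq_len(nf))
      d[f] <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
    p[i] <- p[i] + mean((d - mean(d))^2) /
      (1 + exp((mean(d) - cutoff) / width))
  }
  p
}

# exhaustive minimum cross-pair distance per frame
oracleMinDist <- function(coords, idxA, idxB) {
  nf <- dim(coords)[1]
  vapply(seq_len(nf), function(f) {
    best <- Inf
    for (i in idxA) for (j in idxB)
      best <- min(best, sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)))
    best
  }, numeric(1))
}

# independent Kabsch residual via base-R svd (for partition SSE)
oracleKabschSse <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  sum(Pc^2) + sum(Qc^2) - 2 * sum(s$d * c(1, 1, d))
}

# total rigid-fit SSE of a partition against a reference frame
oraclePartitionSse <- function(coords, assign, refFrame) {
  nf <- dim(coords)[1]
  total <- 0
  for (l in unique(assign)) {
    idx <- which(assign == l)
    P <- coords[refFrame, idx, , drop = TRUE]
    for (f in seq_len(nf))
      total <- total + oracleKabschSse(P, coords[f, idx, , drop = TRUE])
  }
  total
}

# all 2-partitions of n residues with both parts >= minSize
allTwoPartitions <- function(n, minSize = 3) {
  out <- list()
  for (k in minSize:(n - minSize)) {
    cmb <- utils::combn(n, k)
    for (c in seq_len(ncol(cmb))) {
      if (1 %in% cmb[, c]) {  # fix residue 1 in part 1: avoid mirrored duplicates
        a <- rep(2L, n); a[cmb[, c]] <- 1L
        out[[length(out) + 1L]] <- a
      }
    }
  }
  out
}

# 0.01-degree grid search for the optimal rotation angle about an axis
oracleAngleGrid <- function(refPoints, framePoints, anchor, u,
                            stepDeg = 0.01) {
  u <- u / sqrt(sum(u^2))
  grid <- seq(-180, 180, by = stepDeg)
  best <- NA; bestSse <- Inf
  for (th in grid) {
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    R <- diag(3) + sin(th * pi / 180) * K +
      (1 - cos(th * pi / 180)) * (K %*% K)
    pred <- sweep(sweep(refPoints, 2, anchor) %*% t(R), 2, anchor, "+")
    sse <- sum((pred - framePoints)^2)
    if (sse < bestSse) { bestSse <- sse; best <- th }
  }
  best
}

# Rand index between two partitions
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# apply an independent random rigid motion to every frame
randomlyRotateFrames <- function(traj, seed = 1) {
  set.seed(seed)
  coords <- trajCoords(traj)
  for (f in seq_len(dim(coords)[1])) {
    M <- matrix(rnorm(9), 3, 3)
    R <- qr.Q(qr(M))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- rnorm(3, sd = 20)
    coords[f, , ] <- sweep(coords[f, , ] %*% t(R), 2, shift, "+")
  }
  CalphaTrajectory(coords, residueIds(traj))
}

# angle (degrees) between two orientations, sign-resolved
orientationError <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
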