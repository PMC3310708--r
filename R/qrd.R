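# Quasi-rigid domain decomposition: partition the residues into q units
# whose per-frame motion is best explained by rigid-body roto-translation
# of a reference conformation, minimising the Kabsch fit residual by an
# essential-dynamics-seeded stochastic search with full rotation matrices.

#' Construct a Partition
#'
#' @param assignment integer domain labels (1..q), one per residue.
#' @param q number of domains; defaults to \code{max(assignment)}.
#' @param contiguityRequired logical flag recorded with the partition.
#' @return a \linkS4class{Partition}.
#' @export
Partition <- function(assignment, q = max(assignment),
                      contiguityRequired = FALSE) {
  new("Partition", assignment = as.integer(assignment), q = as.integer(q),
      contiguityRequired = contiguityRequired)
}

# iterative mean structure: superpose all frames onto the running mean
# until it moves by < tol RMSD; returns list(mean, superposed cube, rmsd)
.convergedMean <- function(traj, tol = 1e-6, maxIter = 100) {
  cube <- .asCube(trajCoords(traj))
  n <- nResidues(traj)
  refIdx <- seq_len(n)
  m <- cube[, , 1]
  for (it in seq_len(maxIter)) {
    sup <- .cpp_superpose_frames(cube, m, refIdx)
    newMean <- apply(sup, c(1, 2), mean)
    delta <- sqrt(mean(rowSums((newMean - m)^2)))
    m <- newMean
    if (delta < tol) break
  }
  sup <- .cpp_superpose_frames(cube, m, refIdx)
  rmsd <- vapply(seq_len(dim(sup)[3]), function(f)
    sqrt(mean(rowSums((sup[, , f] - m)^2))), numeric(1))
  list(mean = m, superposed = sup, rmsd = rmsd)
}

#' Select the reference frame of a trajectory
#'
#' The conformation closest to the (iteratively superposed) average
#' structure: frames are repeatedly superposed onto their running mean
#' until the mean changes by < 1e-6 Angstrom RMSD, then the frame with
#' minimum RMSD to the converged mean is returned (ties broken by lowest
#' index).
#'
#' @param traj a \linkS4class{CalphaTrajectory} (>= 2 frames).
#' @return reference frame index.
#' @export
selectReference <- function(traj) {
  stopifnot(is(traj, "CalphaTrajectory"), nFrames(traj) >= 2L)
  which.min(.convergedMean(traj)$rmsd)
}

#' Fit rigid-body domain motion for a given partition
#'
#' For every frame and domain, the optimal least-squares (Kabsch) rigid
#' placement of the reference-frame domain onto the frame's coordinates.
#' The residual is the per-coordinate mean squared deviation between
#' placed and actual positions; the captured fraction compares it with a
#' baseline in which the whole molecule is superposed as a single body
#' per frame, so it measures what domain-relative rigid motion explains
#' beyond a global superposition.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param partition a \linkS4class{Partition} (every domain >= 3
#'   non-collinear residues).
#' @param referenceFrame reference frame index; defaults to
#'   \code{\link{selectReference}}.
#' @return a \linkS4class{RigidFitResult}.
#' @export
fitRigidDomains <- function(traj, partition, referenceFrame = NULL) {
  stopifnot(is(traj, "CalphaTrajectory"), is(partition, "Partition"))
  n <- nResidues(traj); nf <- nFrames(traj)
  if (length(partition@assignment) != n)
    stop("partition length does not match residue count", call. = FALSE)
  if (is.null(referenceFrame)) referenceFrame <- selectReference(traj)
  referenceFrame <- as.integer(referenceFrame)
  if (referenceFrame < 1L || referenceFrame > nf)
    stop("referenceFrame out of range", call. = FALSE)
  ref <- .frameMatrix(traj, referenceFrame)
  q <- partition@q
  for (l in seq_len(q))
    .checkDomainGeometry(ref, which(partition@assignment == l), l)
  cube <- .asCube(trajCoords(traj))
  fit <- .cpp_rigid_fit(ref, cube, partition@assignment, q)
  rawSse <- sum(fit$frame_sse)
  residual <- rawSse / (3 * n * nf)
  totalSse <- .cpp_partition_sse(ref, cube, rep(1L, n), 1L)
  totalMsf <- totalSse / (3 * n * nf)
  captured <- if (totalMsf < 1e-12) 1 else
    min(1, max(0, 1 - residual / totalMsf))
  new("RigidFitResult",
      rotations = array(fit$rotations, c(3, 3, q * nf)),
      translations = fit$translations,
      residualMsf = residual, rawSse = rawSse, totalMsf = totalMsf,
      capturedFraction = captured,
      perFrameRmsd = sqrt(as.numeric(fit$frame_sse) / n),
      referenceFrame = referenceFrame, partition = partition)
}

#' Essential-dynamics initial partition
#'
#' Seeds the stochastic search from the essential dynamical space:
#' frames are superposed onto the converged mean structure, the 3N x 3N
#' coordinate covariance is diagonalised, the trajectory is filtered
#' through its top \code{nModes} eigenvectors (essential-subspace
#' reconstruction), and the pairwise distance-fluctuation matrix of the
#' filtered motion is used as the clustering dissimilarity for
#' k-medoids (PAM): residues of one quasi-rigid body have near-zero
#' mutual distance fluctuation, which is the defining property of the
#' decomposition. (Raw mode components cannot be clustered instead,
#' because a rigid rotation is a spatially varying displacement field.)
#' Domains that come out with fewer than 3 residues are repaired by
#' pulling in the spatially nearest residues of larger domains.
#'
#' @param traj a \linkS4class{CalphaTrajectory} (>= 2 frames).
#' @param q number of domains (>= 2).
#' @param nModes number of essential modes (>= 1, capped at frames - 1);
#'   default 10 (ample
#'   for a handful of quasi-rigid bodies; the seed only needs the
#'   large-scale motion).
#' @return a \linkS4class{Partition}.
#' @export
initialPartition <- function(traj, q, nModes = 10) {
  stopifnot(is(traj, "CalphaTrajectory"))
  q <- as.integer(q); nModes <- as.integer(nModes)
  if (q < 2L) stop("q must be >= 2 for an initial partition", call. = FALSE)
  if (nModes < 1L) stop("nModes must be >= 1", call. = FALSE)
  if (nFrames(traj) < 2L) stop("need at least 2 frames", call. = FALSE)
  # the covariance has at most nFrames - 1 informative modes
  nModes <- min(nModes, nFrames(traj) - 1L)
  cm <- .convergedMean(traj)
  n <- nResidues(traj); nf <- nFrames(traj)
  X <- matrix(aperm(cm$superposed, c(3, 1, 2)), nf, 3 * n)  # frame rows
  X <- sweep(X, 2, colMeans(X))
  if (sum(X^2) / (3 * n * nf) < 1e-14)
    stop("degenerate covariance: the trajectory looks rigid; ",
         "an essential-dynamics seed is undefined", call. = FALSE)
  cov <- crossprod(X) / nf
  eig <- eigen(cov, symmetric = TRUE)
  # Keep at most nModes modes, dropping those close to the noise floor:
  # uncorrelated coordinate noise gives a flat eigenvalue tail, so the
  # spectrum median estimates the floor and genuine collective modes
  # stand well above it. Noise-dominated modes would blur the rigid
  # block structure of the filtered fluctuations.
  posVals <- eig$values[eig$values > 0]
  floorEst <- stats::median(posVals)
  strong <- sum(eig$values > 10 * floorEst)
  nModes <- max(1L, min(nModes, max(strong, 1L),
                        sum(eig$values > 1e-12)))
  # filter the motion through the essential subspace (note the columns
  # of X are residue-major per Cartesian axis, matching matrix(., n, 3))
  V <- eig$vectors[, seq_len(nModes), drop = FALSE]
  Xrec <- (X %*% V) %*% t(V)
  meanX <- colMeans(matrix(aperm(cm$superposed, c(3, 1, 2)), nf, 3 * n))
  recTraj <- CalphaTrajectory(
    array(sweep(Xrec, 2, meanX, "+"), c(nf, n, 3)),
    residueIds(traj))
  # The distance-fluctuation matrix of the filtered motion is the
  # natural dissimilarity: residues of one rigid body have near-zero
  # mutual distance fluctuation. A minuscule spatial term breaks the
  # exact ties of ideal rigid blocks (PAM can cycle on tied zeros) and
  # biases tie resolution toward spatially compact domains.
  Fed <- fluctuationValues(distanceFluctuationMatrix(recTraj))
  Fed <- Fed + 1e-9 * as.matrix(stats::dist(cm$mean))
  cl <- cluster::pam(stats::as.dist(Fed), k = q, diss = TRUE,
                     cluster.only = TRUE, pamonce = 5)
  assign <- as.integer(cl)
  # repair: every domain needs >= 3 residues
  refC <- cm$mean
  repeat {
    sizes <- tabulate(assign, q)
    small <- which(sizes < 3L)
    if (!length(small)) break
    l <- small[1]
    centroid <- if (sizes[l] > 0)
      colMeans(refC[assign == l, , drop = FALSE]) else colMeans(refC)
    donors <- which(assign != l & tabulate(assign, q)[assign] > 3L)
    if (!length(donors)) stop("cannot repair tiny domains", call. = FALSE)
    d2 <- rowSums(sweep(refC[donors, , drop = FALSE], 2, centroid)^2)
    assign[donors[which.min(d2)]] <- l
  }
  Partition(assign, q)
}

# X layout note: eigenvectors of the 3N covariance are indexed with the
# coordinate blocks matching matrix(X[f,], n, 3), i.e. residues vary
# fastest within each Cartesian component.

#' Stochastic search for the optimal quasi-rigid partition
#'
#' Starts from the essential-dynamics partition (or a supplied warm
#' start) plus a spatial k-means start, explores single-residue
#' relabelling moves with boundary residues preferred, accepted by
#' simulated annealing on the rigid-fit residual evaluated with full
#' (not small-angle) rotation matrices. Every candidate is settled by
#' alternating k-means-style reassignment sweeps (each residue moves to
#' the domain whose fitted rigid transforms predict its trajectory
#' best; monotone descent that can shift coherent blocks) with a greedy
#' single-residue polish; the lowest-residual partition wins.
#' Deterministic given \code{seed}; \code{q = 1} short-circuits to the
#' trivial partition.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param q number of domains (>= 1).
#' @param seed RNG seed.
#' @param nModes essential modes used for the seeding.
#' @param nMoves annealing move budget; default \code{q * N * 50}.
#' @param restarts independent annealing restarts from the same seed
#'   partition (best kept); default 1.
#' @param init optional warm-start \linkS4class{Partition}.
#' @param referenceFrame reference frame; default
#'   \code{\link{selectReference}}.
#' @return list with elements \code{partition} and \code{fit}
#'   (a \linkS4class{RigidFitResult}).
#' @export
searchPartition <- function(traj, q, seed = 1, nModes = 10, nMoves = NULL,
                            restarts = 1, init = NULL,
                            referenceFrame = NULL) {
  stopifnot(is(traj, "CalphaTrajectory"))
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  n <- nResidues(traj)
  if (is.null(referenceFrame)) referenceFrame <- selectReference(traj)
  if (q == 1L) {
    part <- Partition(rep(1L, n), 1L)
    return(list(partition = part,
                fit = fitRigidDomains(traj, part, referenceFrame)))
  }
  if (is.null(nMoves)) nMoves <- q * n * 50L
  start <- if (is.null(init)) initialPartition(traj, q, nModes) else init
  if (start@q != q)
    stop("warm-start partition has wrong q", call. = FALSE)
  ref <- .frameMatrix(traj, referenceFrame)
  cube <- .asCube(trajCoords(traj))
  nbr <- .neighbourList(ref)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  bestAssign <- start@assignment
  bestSse <- .cpp_partition_sse(ref, cube, bestAssign, q)
  # each candidate goes through reassignment sweeps (block moves),
  # greedy polish (single-residue moves), and is kept if it improves
  settle <- function(assignment) {
    rs <- .cpp_reassign(ref, cube, assignment, q, 3L, 50L)
    pol <- .cpp_polish(ref, cube, rs$assignment, q, nbr, 3L, 100L)
    rs2 <- .cpp_reassign(ref, cube, pol$assignment, q, 3L, 50L)
    if (rs2$sse < pol$sse) rs2 else pol
  }
  consider <- function(assignment) {
    out <- settle(assignment)
    if (out$sse < bestSse) {
      bestSse <<- out$sse
      bestAssign <<- out$assignment
    }
  }
  consider(start@assignment)
  if (is.null(init)) {
    # second deterministic start: spatial k-means on the reference
    # (quasi-rigid domains are spatially compact); the residual still
    # decides which basin wins
    km <- stats::kmeans(ref, centers = q, nstart = 5)
    if (min(tabulate(km$cluster, q)) >= 3L) consider(km$cluster)
  }
  for (r in seq_len(max(1L, as.integer(restarts)))) {
    ann <- .cpp_anneal(ref, cube, start@assignment, q, nbr,
                       as.integer(nMoves), 3L, 0.05, 1e-5)
    consider(ann$assignment)
  }
  part <- Partition(as.integer(bestAssign), q)
  list(partition = part, fit = fitRigidDomains(traj, part, referenceFrame))
}

# split one domain of a partition into two by 2-means on reference
# coordinates, choosing the domain with the largest fit residual that is
# big enough to split; used to warm-start q+1 from the best q partition.
.splitPartition <- function(assign, q, ref, cube) {
  fit <- .cpp_rigid_fit(ref, cube, assign, q)
  dres <- rowSums(fit$domain_frame_sse)
  sizes <- tabulate(assign, q)
  cand <- order(dres, decreasing = TRUE)
  for (l in cand) {
    if (sizes[l] < 6L) next
    idx <- which(assign == l)
    km <- stats::kmeans(ref[idx, , drop = FALSE], centers = 2,
                        nstart = 5)
    if (min(tabulate(km$cluster, 2)) < 3L) next
    out <- assign
    out[idx[km$cluster == 2]] <- q + 1L
    return(out)
  }
  NULL
}

#' Scan the number of quasi-rigid domains
#'
#' Runs \code{\link{searchPartition}} for each q, warm-starting q+1 by
#' splitting the highest-residual domain of the best q partition (so the
#' captured fraction is non-decreasing in q), and reports the smallest q
#' whose marginal gain in captured fraction falls below
#' \code{gainThreshold}.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param qValues integer vector of domain counts (each >= 1).
#' @param seed RNG seed.
#' @param gainThreshold marginal-gain threshold (default 0.05).
#' @param ... further arguments passed to \code{\link{searchPartition}}.
#' @return data.frame with columns \code{q}, \code{epsilon2} (residual
#'   per-coordinate mean square, Angstrom^2) and \code{capturedFraction};
#'   attributes \code{suggestedQ} and \code{partitions} (list of
#'   \linkS4class{Partition} per q).
#' @export
scanQ <- function(traj, qValues, seed = 1, gainThreshold = 0.05, ...) {
  qValues <- sort(unique(as.integer(qValues)))
  if (!length(qValues) || any(qValues < 1L))
    stop("qValues must be non-empty positive integers", call. = FALSE)
  referenceFrame <- selectReference(traj)
  ref <- .frameMatrix(traj, referenceFrame)
  cube <- .asCube(trajCoords(traj))
  res <- data.frame(q = qValues, epsilon2 = NA_real_,
                    capturedFraction = NA_real_)
  parts <- vector("list", length(qValues))
  prev <- NULL
  for (k in seq_along(qValues)) {
    q <- qValues[k]
    warm <- NULL
    if (!is.null(prev) && q == prev@q + 1L) {
      sp <- .splitPartition(prev@assignment, prev@q, ref, cube)
      if (!is.null(sp)) warm <- Partition(sp, q)
    }
    sr <- searchPartition(traj, q, seed = seed, init = NULL,
                          referenceFrame = referenceFrame, ...)
    if (!is.null(warm)) {
      sw <- searchPartition(traj, q, seed = seed, init = warm,
                            referenceFrame = referenceFrame, ...)
      if (sw$fit@residualMsf < sr$fit@residualMsf) sr <- sw
    }
    res$epsilon2[k] <- sr$fit@residualMsf
    res$capturedFraction[k] <- sr$fit@capturedFraction
    parts[[k]] <- sr$partition
    prev <- sr$partition
  }
  gains <- diff(res$capturedFraction)
  suggested <- NA_integer_
  if (length(gains)) {
    low <- which(gains < gainThreshold)
    if (length(low)) suggested <- res$q[low[1]]
  } else suggested <- res$q[1]
  attr(res, "suggestedQ") <- suggested
  attr(res, "partitions") <- parts
  res
}

#' Write a partition (with its fit summary) as JSON
#'
#' @param fit a \linkS4class{RigidFitResult}.
#' @param path output path.
#' @param seed seed recorded in the artifact.
#' @export
writePartitionJson <- function(fit, path, seed = NA) {
  p <- fit@partition
  jsonlite::write_json(
    list(q = p@q, assignment = p@assignment,
         epsilon2 = fit@residualMsf,
         captured_fraction = fit@capturedFraction,
         reference_frame = fit@referenceFrame, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
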