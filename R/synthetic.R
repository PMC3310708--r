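# Planted-ground-truth trajectory generator: compact random blobs moving
# as rigid bodies about fixed hinge axes, plus isotropic Gaussian
# coordinate noise. Stands in for long atomistic simulations in every
# test: recovery of the planted partition, axes and angles is the
# yardstick for the decomposition machinery.

#' Construct a SyntheticSpec
#'
#' @param domainSizes residues per domain (each >= 3).
#' @param hinges list of hinges (see \linkS4class{SyntheticSpec}); by
#'   default no hinge, i.e. a globally rigid molecule.
#' @param noiseSigma per-coordinate Gaussian noise s.d. (Angstrom).
#' @param nFrames number of frames.
#' @param seed RNG seed (generation is deterministic given the spec).
#' @param scale blob packing scale factor.
#' @param tag protein tag stamped on the residues.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
SyntheticSpec <- function(domainSizes, hinges = list(), noiseSigma = 0,
                          nFrames = 50, seed = 1, scale = 1,
                          tag = "synth") {
  new("SyntheticSpec", domainSizes = as.integer(domainSizes),
      hinges = hinges, noiseSigma = as.numeric(noiseSigma),
      nFrames = as.integer(nFrames), seed = as.integer(seed),
      scale = as.numeric(scale), tag = tag)
}

# Sample n points uniformly in a sphere of radius r around centre with a
# minimum pair distance (also against already `placed` points).
.sampleBlob <- function(n, centre, r, placed, minDist = 3.5,
                        maxAttempts = 1e4) {
  pts <- matrix(NA_real_, n, 3)
  attempts <- 0L
  k <- 0L
  while (k < n) {
    if (attempts >= maxAttempts)
      stop("impossible blob geometry after ", maxAttempts,
           " placement attempts", call. = FALSE)
    attempts <- attempts + 1L
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) > 1) next
    p <- centre + r * p
    if (k > 0 &&
        min(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2, p)^2)) <
          minDist^2) next
    if (nrow(placed) &&
        min(rowSums(sweep(placed, 2, p)^2)) < minDist^2) next
    k <- k + 1L
    pts[k, ] <- p
  }
  pts
}

# Lateral (y, z) grid positions for a contact patch: spacing `sp`,
# ordered from the patch centre outwards.
.patchGrid <- function(k, radius, sp = 4.2) {
  g <- seq(-floor(radius / sp), floor(radius / sp)) * sp
  pos <- expand.grid(y = g, z = g)
  pos <- pos[order(pos$y^2 + pos$z^2), , drop = FALSE]
  if (nrow(pos) < k)
    stop("domain cross-section too small for its contact patch",
         call. = FALSE)
  as.matrix(pos[seq_len(k), , drop = FALSE])
}

# Default hinge kinematics. Successive hinges get distinct axis
# orientations and phase-distinct schedules so that a multi-hinge system
# has genuinely independent degrees of freedom (two parallel axes with
# one shared schedule would collapse into a near-global rotation).
.defaultOrientation <- function(k) {
  rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))[(k - 1) %% 3 + 1, ]
}

.defaultAngles <- function(nFrames, k = 1) {
  amp <- c(25, 20, 15)[(k - 1) %% 3 + 1]
  if (k %% 2 == 1)  # smooth ramp 0 -> amp
    amp * sin(seq(0, pi / 2, length.out = nFrames))^2
  else              # there-and-back sweep 0 -> amp -> 0
    amp * sin(seq(0, pi, length.out = nFrames))^2
}

#' Generate a trajectory with planted ground truth
#'
#' Builds a reference structure of compact self-avoiding random blobs
#' (minimum pair distance 3.5 Angstrom, mimicking Calpha packing) placed
#' adjacently along a chain. Adjacent domains are joined by an explicit
#' contact patch: matched residue pairs facing each other at ~4.4
#' Angstrom across a planar interface, while the domain bulks stay more
#' than 7.9 Angstrom from the other domain. Cross-domain distances
#' therefore avoid the ambiguous 5-7.5 Angstrom band, so the declared
#' interface set (cross-domain neighbour under 5 Angstrom) coincides
#' exactly with the residues that carry appreciable weight in the ~5
#' Angstrom strain contact function. Every frame applies the scheduled
#' rotations about the planted axes to the moving domains and then adds
#' isotropic Gaussian noise to every coordinate.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{trajectory} (a \linkS4class{CalphaTrajectory})
#'   and \code{truth}: \code{assignment} (planted partition),
#'   \code{hinges} (anchor residue, unit orientation, angle schedule per
#'   hinge), \code{interface} (residues with a cross-domain neighbour
#'   under 5 Angstrom in the reference), \code{reference} (N x 3 matrix).
#' @export
generateTrajectory <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  sizes <- spec@domainSizes
  nd <- length(sizes)
  radii <- pmax(4, 2.6 * sizes^(1/3)) * spec@scale

  # contact-patch size per adjacent pair, out of each domain's budget
  kPatch <- if (nd > 1)
    vapply(seq_len(nd - 1), function(d)
      max(3L, as.integer(min(sizes[d], sizes[d + 1]) %/% 10)),
      integer(1)) else integer(0)
  bulkSizes <- sizes
  if (nd > 1) {
    bulkSizes[1] <- bulkSizes[1] - kPatch[1]
    if (nd > 2)
      for (d in 2:(nd - 1))
        bulkSizes[d] <- bulkSizes[d] - kPatch[d - 1] - kPatch[d]
    bulkSizes[nd] <- bulkSizes[nd] - kPatch[nd - 1]
    if (any(bulkSizes < 0L))
      stop("a domain is too small for its contact patch(es)",
           call. = FALSE)
  }

  # chain layout along x: bulk spheres separated so that only the patch
  # residues come within 5 A of the other domain (bulk >= 7.9 A away)
  centres <- matrix(0, nd, 3)
  edges <- numeric(nd)   # nominal right edge of each bulk sphere
  edges[1] <- radii[1]
  if (nd > 1)
    for (d in 2:nd) {
      centres[d, 1] <- edges[d - 1] + 11.8 + radii[d]
      edges[d] <- centres[d, 1] + radii[d]
    }

  ref <- matrix(NA_real_, sum(sizes), 3)
  assign <- rep(seq_len(nd), sizes)
  placedSoFar <- matrix(numeric(0), 0, 3)
  offsets <- c(0L, cumsum(sizes))
  # bulks first
  for (d in seq_len(nd)) {
    pts <- .sampleBlob(bulkSizes[d], centres[d, ], radii[d], placedSoFar)
    ref[offsets[d] + seq_len(bulkSizes[d]), ] <- pts
    placedSoFar <- rbind(placedSoFar, pts)
  }
  # then the contact patches (left side of each domain gets filled after
  # its bulk; patch rows follow the bulk rows within each domain block)
  if (nd > 1) for (d in seq_len(nd - 1)) {
    k <- kPatch[d]
    lat <- .patchGrid(k, min(radii[d], radii[d + 1]) + 1)
    x0 <- edges[d]
    jit <- function(m) matrix(stats::runif(2 * m, -0.3, 0.3), m, 2)
    pA <- cbind(x0 + 3.6 + stats::runif(k, 0, 0.3), lat + jit(k))
    pB <- cbind(x0 + 8.0 + stats::runif(k, 0, 0.3), lat + jit(k))
    rowsA <- offsets[d] + bulkSizes[d] +
      (if (d > 1) kPatch[d - 1] else 0L) + seq_len(k)
    rowsB <- offsets[d + 1] + bulkSizes[d + 1] + seq_len(k)
    ref[rowsA, ] <- pA
    ref[rowsB, ] <- pB
  }
  n <- nrow(ref)

  # Resolve hinges: anchors default to the core residue closest to the
  # moving domain's centroid; orientations are normalised; angle
  # schedules default to a smooth 0-25 degree ramp. The actual rotation
  # axis passes 0.3 A from the anchor Calpha (perpendicular offset):
  # a hinge axis through an atom would make that atom's domain label
  # degenerate (it is invariant under both domains' motions), whereas a
  # physical axis passes between atoms; the Calpha-anchored search is an
  # approximation the recovery tests are meant to exercise.
  hinges <- lapply(seq_along(spec@hinges), function(k) {
    h <- spec@hinges[[k]]
    if (is.null(h$anchor) || is.na(h$anchor)) {
      movC <- colMeans(ref[assign == h$moving, , drop = FALSE])
      coreIdx <- which(assign == h$core)
      h$anchor <- coreIdx[which.min(rowSums(sweep(
        ref[coreIdx, , drop = FALSE], 2, movC)^2))]
    }
    if (assign[h$anchor] != h$core)
      stop("hinge anchor must belong to its core domain", call. = FALSE)
    if (is.null(h$orientation)) h$orientation <- .defaultOrientation(k)
    h$orientation <- h$orientation / sqrt(sum(h$orientation^2))
    if (is.null(h$angles)) h$angles <- .defaultAngles(spec@nFrames, k)
    if (is.null(h$axisPoint)) {
      u <- h$orientation
      perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * u) * u
      perp <- perp / sqrt(sum(perp^2))
      h$axisPoint <- ref[h$anchor, ] + 0.3 * perp
    }
    h
  })

  coords <- array(NA_real_, c(spec@nFrames, n, 3))
  for (f in seq_len(spec@nFrames)) {
    X <- ref
    for (h in hinges) {
      if (h$angles[f] == 0) next  # exact identity, bitwise
      R <- .rotationAbout(h$orientation, .rad(h$angles[f]))
      a <- h$axisPoint
      movIdx <- which(assign == h$moving)
      X[movIdx, ] <- sweep(sweep(ref[movIdx, , drop = FALSE], 2, a) %*%
                             t(R), 2, a, "+")
    }
    if (spec@noiseSigma > 0)
      X <- X + matrix(stats::rnorm(3 * n, sd = spec@noiseSigma), n, 3)
    coords[f, , ] <- X
  }

  dm <- as.matrix(stats::dist(ref))
  cross <- outer(assign, assign, "!=") & dm < 5
  interface <- which(rowSums(cross) > 0)

  traj <- new("CalphaTrajectory", coords = coords,
              residueIds = data.frame(proteinTag = spec@tag, chain = "A",
                                      resno = seq_len(n),
                                      resname = "ALA",
                                      stringsAsFactors = FALSE),
              frameTimes = numeric(0),
              source = sprintf("synthetic (seed %d)", spec@seed))
  list(trajectory = traj,
       truth = list(assignment = assign,
                    hinges = lapply(hinges, function(h)
                      list(moving = h$moving, core = h$core,
                           anchor = h$anchor, axisPoint = h$axisPoint,
                           orientation = h$orientation,
                           angles = h$angles)),
                    interface = interface, reference = ref))
}

#' Correspondence table linking synthetic proteins
#'
#' Maps the first \code{ceiling(overlapFraction * N)} residues of each
#' synthetic protein into shared groups (the proteins must have equal
#' residue counts and domain structure), enabling meta-trajectory tests
#' with known ground truth.
#'
#' @param specs list of \linkS4class{SyntheticSpec} with identical
#'   \code{domainSizes}; their tags must be distinct.
#' @param overlapFraction fraction in (0, 1] of residues to map.
#' @return a \linkS4class{CorrespondenceTable}.
#' @export
makeCorrespondence <- function(specs, overlapFraction = 1) {
  stopifnot(length(specs) >= 1L, overlapFraction > 0,
            overlapFraction <= 1)
  sizes <- specs[[1]]@domainSizes
  for (s in specs)
    if (!identical(s@domainSizes, sizes))
      stop("specs must share domain counts", call. = FALSE)
  n <- sum(sizes)
  keep <- ceiling(overlapFraction * n)
  assign <- rep(seq_along(sizes), sizes)
  kept <- tabulate(assign[seq_len(keep)], length(sizes))
  if (any(kept < 3L))
    stop("overlap leaves a domain with fewer than 3 residues",
         call. = FALSE)
  rows <- do.call(rbind, lapply(specs, function(s)
    data.frame(groupId = seq_len(keep), proteinTag = s@tag, chain = "A",
               resno = seq_len(keep), stringsAsFactors = FALSE)))
  CorrespondenceTable(rows)
}
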