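# Superposition-free fluctuation analysis: the matrix of pairwise
# Calpha distance variances and minimum-distance time series.

# streaming two-pass over frames: mean distances, then variance.
# Returns list(mean, var) as full symmetric matrices.
.pairDistanceStats <- function(traj, frames) {
  n <- nResidues(traj)
  sumd <- 0
  for (f in frames) sumd <- sumd + stats::dist(.frameMatrix(traj, f))
  meand <- sumd / length(frames)
  ss <- 0
  for (f in frames) {
    dv <- stats::dist(.frameMatrix(traj, f))
    ss <- ss + (dv - meand)^2
  }
  vard <- ss / length(frames)  # population variance: plain time average
  toMat <- function(v) {
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- as.vector(v)
    m + t(m)
  }
  list(mean = toMat(meand), var = toMat(vard))
}

#' Matrix of distance fluctuations
#'
#' For every residue pair (i, j), the time variance of the inter-Calpha
#' distance over the selected frames:
#' \eqn{A_{ij} = \langle (d_{ij} - \langle d_{ij}\rangle)^2 \rangle},
#' with \eqn{\langle\cdot\rangle} the plain time average (population
#' variance). A is invariant under per-frame global roto-translations, so
#' no superposition is performed or needed.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param frameRange optional (first, last) frame indices; defaults to
#'   all frames. At least 2 frames are required.
#' @return a \linkS4class{DistanceFluctuationMatrix} (Angstrom^2), which
#'   also carries the time-mean distance matrix.
#' @export
distanceFluctuationMatrix <- function(traj, frameRange = NULL) {
  stopifnot(is(traj, "CalphaTrajectory"))
  fr <- .resolveFrameRange(traj, frameRange)
  frames <- seq.int(fr[1], fr[2])
  if (length(frames) < 2L)
    stop("need at least 2 frames to compute fluctuations", call. = FALSE)
  st <- .pairDistanceStats(traj, frames)
  new("DistanceFluctuationMatrix", values = st$var,
      meanDistances = st$mean, residueIds = residueIds(traj),
      frameRange = fr)
}

#' Mean distance fluctuation between two residue ranges
#'
#' Arithmetic mean of A(i, j) over i in \code{rangeA}, j in
#' \code{rangeB}, excluding diagonal entries when the ranges overlap
#' (the style of block summaries used to quantify inter-segment
#' mobility).
#'
#' @param dfm a \linkS4class{DistanceFluctuationMatrix}.
#' @param rangeA,rangeB integer residue index vectors (or length-2
#'   (from, to) ranges).
#' @return mean fluctuation (Angstrom^2).
#' @export
blockSummary <- function(dfm, rangeA, rangeB) {
  stopifnot(is(dfm, "DistanceFluctuationMatrix"))
  expand <- function(r) {
    r <- as.integer(r)
    if (length(r) == 2L && r[2] >= r[1]) seq.int(r[1], r[2]) else r
  }
  a <- expand(rangeA); b <- expand(rangeB)
  n <- nrow(dfm@values)
  if (!length(a) || !length(b) || any(c(a, b) < 1L) || any(c(a, b) > n))
    stop("empty or out-of-bounds residue range", call. = FALSE)
  sub <- dfm@values[a, b, drop = FALSE]
  mask <- outer(a, b, "!=")  # drop i == j entries
  if (!any(mask)) stop("ranges contain no off-diagonal pair", call. = FALSE)
  mean(sub[mask])
}

#' Minimum-distance time series between two selections
#'
#' Per frame, the distance between the closest pair of atoms across two
#' disjoint selections; reports the final-frame and time-average values
#' alongside the series.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param selA,selB \linkS4class{AtomSelection}s or selection expressions;
#'   must be non-empty and disjoint.
#' @return a \linkS4class{DistanceSeries}.
#' @export
minDistanceSeries <- function(traj, selA, selB) {
  stopifnot(is(traj, "CalphaTrajectory"))
  sa <- selectResidues(traj, selA)
  sb <- selectResidues(traj, selB)
  if (!length(sa@indices) || !length(sb@indices))
    stop("selections must be non-empty", call. = FALSE)
  if (length(intersect(sa@indices, sb@indices)))
    stop("selections overlap", call. = FALSE)
  nf <- nFrames(traj)
  mins <- vapply(seq_len(nf), function(f) {
    X <- .frameMatrix(traj, f)
    A <- X[sa@indices, , drop = FALSE]
    B <- X[sb@indices, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  new("DistanceSeries", perFrameMin = mins, selectionA = sa,
      selectionB = sb, finalValue = mins[nf], averageValue = mean(mins))
}

#' Write a distance-fluctuation matrix as TSV (upper triangle)
#'
#' Columns: residue index i, residue index j, fluctuation (Angstrom^2).
#'
#' @param dfm a \linkS4class{DistanceFluctuationMatrix}.
#' @param path output path.
#' @export
writeFluctuationTsv <- function(dfm, path) {
  v <- dfm@values
  ut <- which(upper.tri(v), arr.ind = TRUE)
  utils::write.table(
    data.frame(i = ut[, 1], j = ut[, 2], fluctuation = v[ut]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
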