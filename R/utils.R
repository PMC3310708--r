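# internal helpers shared across modules

# coords array (F x N x 3) -> arma cube layout (N x 3 x F)
.asCube <- function(coords) aperm(coords, c(2, 3, 1))

# cube (N x 3 x F) -> coords array (F x N x 3)
.fromCube <- function(cube) aperm(cube, c(3, 1, 2))

# single frame as N x 3 matrix
.frameMatrix <- function(traj, f) {
  x <- trajCoords(traj)[f, , , drop = FALSE]
  dim(x) <- dim(x)[2:3]
  x
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares rotation and translation placing reference points
#' \code{P} onto target points \code{Q} (both n x 3 matrices), the
#' elementary fit inside the quasi-rigid decomposition objective.
#'
#' @param P,Q numeric n x 3 coordinate matrices (Angstrom).
#' @return list with \code{rotation} (3 x 3 proper orthogonal),
#'   \code{translation} (length 3) and \code{sse} (residual sum of
#'   squares, Angstrom^2); predicted target is \code{P %*% t(rotation) +
#'   translation} rowwise.
#' @export
kabschFit <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q), nrow(P) >= 3)
  .cpp_kabsch(P, Q)
}

# rank check: a rigid fit needs >= 3 non-collinear points
.checkDomainGeometry <- function(refCoords, members, label) {
  if (length(members) < 3L)
    stop("domain ", label, " has fewer than 3 residues", call. = FALSE)
  X <- scale(refCoords[members, , drop = FALSE], scale = FALSE)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8)
    stop("domain ", label, " has collinear reference geometry",
         call. = FALSE)
  invisible(TRUE)
}

# neighbour list (1-based) from reference coordinates, pairs within cutoff
.neighbourList <- function(refCoords, cutoff = 8) {
  n <- nrow(refCoords)
  dm <- as.matrix(stats::dist(refCoords))
  lapply(seq_len(n), function(i) {
    j <- which(dm[i, ] <= cutoff)
    as.integer(j[j != i])
  })
}

.resolveFrameRange <- function(traj, frameRange) {
  nf <- nFrames(traj)
  if (is.null(frameRange)) return(c(1L, nf))
  fr <- as.integer(frameRange)
  if (length(fr) != 2L || fr[1] < 1L || fr[2] > nf || fr[1] > fr[2])
    stop("frameRange (", paste(frameRange, collapse = ", "),
         ") outside trajectory with ", nf, " frames", call. = FALSE)
  fr
}

# degrees <-> radians
.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

# rotation matrix about unit axis u by angle rad (Rodrigues)
.rotationAbout <- function(u, rad) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(rad) * K + (1 - cos(rad)) * (K %*% K)
}
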