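# Geometric strain: deformation of a residue's local (~5 Angstrom)
# contact network over the trajectory. High strain marks hinge regions
# and mechanically stressed sites.

#' Logistic contact weight
#'
#' Smooth neighbourhood weight \eqn{f(x) = 1 / (1 + \exp((x - c)/w))}
#' with midpoint \code{cutoff} c and \code{width} w: strictly decreasing,
#' f(cutoff) = 0.5, and ~1 for x well below the cutoff, restricting
#' strain contributions to residues within about 5 Angstrom.
#'
#' @param x distance(s), Angstrom (>= 0).
#' @param cutoff sigmoid midpoint, Angstrom (> 0); default 5.
#' @param width sigmoid width, Angstrom (> 0); default 0.5.
#' @return weights in (0, 1).
#' @export
sigmoidWeight <- function(x, cutoff = 5, width = 0.5) {
  stopifnot(cutoff > 0, width > 0, all(x >= 0))
  1 / (1 + exp((x - cutoff) / width))
}

# strain from precomputed distance statistics
.strainFromStats <- function(A, meanD, cutoff, width) {
  W <- sigmoidWeight(meanD, cutoff, width)
  diag(W) <- 0
  rowSums(A * W)
}

#' Per-residue geometric strain profile
#'
#' Strain of residue i is the sigmoid-weighted sum of its pairwise
#' distance fluctuations, \eqn{p_i = \sum_{j \ne i} A_{ij}
#' f(\langle d_{ij}\rangle)}, where A is the distance-fluctuation matrix
#' and the weight is evaluated at the time-mean distance so the
#' neighbour set is fixed over the analysis range. Residues whose local
#' contact network deforms (hinges, domain interfaces) carry high strain.
#'
#' @param traj a \linkS4class{CalphaTrajectory} (>= 2 frames).
#' @param cutoff,width logistic weight parameters (Angstrom); see
#'   \code{\link{sigmoidWeight}}.
#' @param frameRange optional (first, last) frames.
#' @param instantaneous if TRUE, weight each frame's squared deviation by
#'   that frame's distance instead of the time mean (sensitivity flag).
#' @return a \linkS4class{StrainProfile} (Angstrom^2).
#' @export
strainProfile <- function(traj, cutoff = 5, width = 0.5,
                          frameRange = NULL, instantaneous = FALSE) {
  stopifnot(is(traj, "CalphaTrajectory"))
  fr <- .resolveFrameRange(traj, frameRange)
  frames <- seq.int(fr[1], fr[2])
  if (length(frames) < 2L)
    stop("need at least 2 frames to compute strain", call. = FALSE)
  st <- .pairDistanceStats(traj, frames)
  if (!instantaneous) {
    p <- .strainFromStats(st$var, st$mean, cutoff, width)
  } else {
    # per-frame weighting: p_i = < sum_j (d_ij - <d_ij>)^2 f(d_ij(t)) >
    n <- nResidues(traj)
    acc <- numeric(n)
    for (f in frames) {
      D <- as.matrix(stats::dist(.frameMatrix(traj, f)))
      W <- sigmoidWeight(D, cutoff, width)
      diag(W) <- 0
      acc <- acc + rowSums((D - st$mean)^2 * W)
    }
    p <- acc / length(frames)
  }
  new("StrainProfile", perResidue = pmax(p, 0), cutoff = cutoff,
      width = width, residueIds = residueIds(traj))
}

#' Time-resolved strain over non-overlapping windows
#'
#' Splits the trajectory into consecutive non-overlapping windows of
#' \code{windowFrames} frames (trailing frames that do not fill a window
#' are dropped) and evaluates the strain profile within each window using
#' window-local averages.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param windowFrames window length in frames (>= 2, <= frame count);
#'   default 10\% of the trajectory (at least 2).
#' @param cutoff,width logistic weight parameters (Angstrom).
#' @return a \linkS4class{StrainProfile} whose \code{perWindow} matrix
#'   holds one row per window and whose \code{perResidue} is the mean
#'   over windows.
#' @export
strainTimeResolved <- function(traj, windowFrames = NULL, cutoff = 5,
                               width = 0.5) {
  stopifnot(is(traj, "CalphaTrajectory"))
  nf <- nFrames(traj)
  if (is.null(windowFrames)) windowFrames <- max(2L, nf %/% 10L)
  windowFrames <- as.integer(windowFrames)
  if (windowFrames < 2L || windowFrames > nf)
    stop("windowFrames must lie in [2, ", nf, "]", call. = FALSE)
  nw <- nf %/% windowFrames
  prof <- matrix(NA_real_, nw, nResidues(traj))
  for (w in seq_len(nw)) {
    fr <- c((w - 1L) * windowFrames + 1L, w * windowFrames)
    prof[w, ] <- strainValues(strainProfile(traj, cutoff, width,
                                            frameRange = fr))
  }
  new("StrainProfile", perResidue = colMeans(prof), perWindow = prof,
      windowLengthFrames = windowFrames, cutoff = cutoff, width = width,
      residueIds = residueIds(traj))
}

#' Rank strain hotspots
#'
#' @param profile a \linkS4class{StrainProfile}.
#' @param n number of top residues to report.
#' @return data.frame of the n highest-strain residues with their
#'   residue numbers and strain values, ordered by decreasing strain.
#' @export
strainHotspots <- function(profile, n = 10) {
  ord <- order(profile@perResidue, decreasing = TRUE)
  top <- utils::head(ord, n)
  data.frame(index = top,
             resno = profile@residueIds$resno[top],
             chain = profile@residueIds$chain[top],
             strain = profile@perResidue[top])
}

#' Write a strain profile as TSV
#'
#' Columns: residue number and strain; windowed profiles add one column
#' per window.
#'
#' @param profile a \linkS4class{StrainProfile}.
#' @param path output path.
#' @export
writeStrainTsv <- function(profile, path) {
  df <- data.frame(resno = profile@residueIds$resno,
                   strain = profile@perResidue)
  if (nrow(profile@perWindow)) {
    w <- t(profile@perWindow)
    colnames(w) <- paste0("window", seq_len(nrow(profile@perWindow)))
    df <- cbind(df, w)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
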