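# Fixed-axis hinge fitting: model a moving domain's motion, in the
# core-domain frame, as pure rotation about one time-independent axis
# anchored on a Calpha; the per-frame angle is the only time-dependent
# parameter.

#' Sample orientations uniformly on the unit sphere
#'
#' @param n number of unit vectors (>= 1).
#' @param seed RNG seed (deterministic output).
#' @return n x 3 matrix of unit vectors; antipodal duplicates are
#'   allowed (the orientation sign is resolved later).
#' @export
sampleOrientations <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Optimal rotation angle about a fixed axis
#'
#' Closed-form least-squares angle rotating \code{refPoints} about the
#' line through \code{anchor} with direction \code{orientation} onto
#' \code{framePoints}: with each point decomposed into axial and
#' perpendicular components, the residual is sinusoidal in the angle and
#' minimised at atan2 of the two cross-correlation sums.
#'
#' @param refPoints,framePoints n x 3 matrices (n >= 1), core-fixed
#'   coordinates.
#' @param anchor point on the axis (length 3).
#' @param orientation axis direction (length 3; normalised internally).
#' @return optimal angle in degrees (in (-180, 180]).
#' @export
optimalAngle <- function(refPoints, framePoints, anchor, orientation) {
  stopifnot(is.matrix(refPoints), ncol(refPoints) == 3,
            all(dim(refPoints) == dim(framePoints)))
  u <- orientation / sqrt(sum(orientation^2))
  V <- sweep(refPoints, 2, anchor)
  par <- drop(V %*% u)
  Vperp <- V - outer(par, u)
  if (max(sqrt(rowSums(Vperp^2))) < 1e-9)
    stop("all points lie on the axis; the angle is undefined",
         call. = FALSE)
  W <- cbind(u[2] * V[, 3] - u[3] * V[, 2],
             u[3] * V[, 1] - u[1] * V[, 3],
             u[1] * V[, 2] - u[2] * V[, 1])  # u x v == u x vperp
  C <- sweep(framePoints, 2, anchor) - outer(par, u)
  A <- sum(Vperp * C); B <- sum(W * C)
  if (A == 0 && B == 0) return(0)
  .deg(atan2(B, A))
}

# superpose frames onto the reference by the core domain; returns cube
.coreFixedFrames <- function(traj, coreIdx, referenceFrame) {
  ref <- .frameMatrix(traj, referenceFrame)
  cube <- .asCube(trajCoords(traj))
  .cpp_superpose_frames(cube, ref, as.integer(coreIdx))
}

# refine orientation on the sphere (anchor fixed) by Nelder-Mead on
# spherical coordinates around the discrete optimum
.refineOrientation <- function(refmov, movcube, anchor, u0) {
  # local frame with u0 as pole avoids coordinate singularities nearby
  e3 <- u0
  aux <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- aux - sum(aux * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  obj <- function(th) {
    u <- cos(th[1]) * e3 + sin(th[1]) * (cos(th[2]) * e1 + sin(th[2]) * e2)
    .cpp_axis_eval(refmov, movcube, anchor, u)$sse
  }
  op <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 400))
  th <- op$par
  u <- cos(th[1]) * e3 + sin(th[1]) * (cos(th[2]) * e1 + sin(th[2]) * e2)
  list(orientation = u / sqrt(sum(u^2)), sse = op$value)
}

#' Fit a fixed hinge axis for a moving domain
#'
#' Every frame is superposed onto the reference conformation by the core
#' domain, making the axis literally fixed in the core frame. All
#' candidate anchors (every Calpha of the molecule by default, optionally
#' subsampled) are combined with \code{nOrientations} orientations drawn
#' uniformly on the unit sphere; for each candidate axis the per-frame
#' optimal rotation angles of the moving domain are computed in closed
#' form and the axis with minimal residual is kept, followed by a local
#' continuous refinement of the orientation (the discrete-scan result is
#' also reported). The axis is not constrained to the domain boundary and
#' need not pass through the domain centre of mass.
#'
#' @param traj a \linkS4class{CalphaTrajectory} (>= 2 frames).
#' @param partition a \linkS4class{Partition}.
#' @param core,moving domain labels.
#' @param nOrientations number of sampled orientations (default 500).
#' @param seed orientation-sampling seed.
#' @param anchorStride keep every anchorStride-th candidate Calpha
#'   (default 1 = full scan).
#' @param refine apply continuous orientation refinement (default TRUE).
#' @param referenceFrame reference frame; default
#'   \code{\link{selectReference}}.
#' @return a \linkS4class{HingeAxis}. If the moving domain is static in
#'   the core frame the captured fraction is NA and a warning is issued.
#' @export
fitFixedAxis <- function(traj, partition, core, moving,
                         nOrientations = 500, seed = 1, anchorStride = 1,
                         refine = TRUE, referenceFrame = NULL) {
  stopifnot(is(traj, "CalphaTrajectory"), is(partition, "Partition"))
  assign <- partition@assignment
  coreIdx <- which(assign == core)
  movIdx <- which(assign == moving)
  if (!length(coreIdx) || !length(movIdx) || core == moving)
    stop("core and moving must be distinct non-empty domains",
         call. = FALSE)
  if (nFrames(traj) < 2L) stop("need >= 2 frames", call. = FALSE)
  if (is.null(referenceFrame)) referenceFrame <- selectReference(traj)
  ref <- .frameMatrix(traj, referenceFrame)
  sup <- .coreFixedFrames(traj, coreIdx, referenceFrame)
  refmov <- ref[movIdx, , drop = FALSE]
  movcube <- sup[movIdx, , , drop = FALSE]
  nf <- dim(movcube)[3]; m <- length(movIdx)

  # moving-domain displacement baseline in the core frame
  totalSse <- sum(vapply(seq_len(nf), function(f)
    sum((movcube[, , f] - refmov)^2), numeric(1)))
  totalMsf <- totalSse / (3 * m * nf)

  anchorCand <- seq(1L, nResidues(traj), by = max(1L, as.integer(anchorStride)))
  if (length(anchorCand) < 1L) stop("no anchor candidates", call. = FALSE)
  anchors <- ref[anchorCand, , drop = FALSE]
  orients <- sampleOrientations(nOrientations, seed)

  if (totalMsf < 1e-12) {
    warning("moving domain is static in the core frame; ",
            "axis is degenerate", call. = FALSE)
    return(new("HingeAxis", anchorResidue = anchorCand[1],
               orientation = c(0, 0, 1), perFrameAngle = numeric(nf),
               movingDomain = as.integer(moving),
               coreDomain = as.integer(core), residualMsf = 0,
               capturedFraction = NA_real_,
               discreteOrientation = c(0, 0, 1), discreteResidualMsf = 0,
               nOrientations = as.integer(nOrientations),
               seed = as.integer(seed)))
  }

  scan <- .cpp_axis_scan(refmov, movcube, anchors, orients)
  anchorRes <- anchorCand[scan$anchor_index]
  anchor <- ref[anchorRes, ]
  uDisc <- orients[scan$orientation_index, ]
  discreteResidual <- scan$sse / (3 * m * nf)

  u <- uDisc; sse <- scan$sse
  if (isTRUE(refine)) {
    # alternate continuous orientation refinement with an anchor rescan
    # at the refined orientation, until the residual stops improving
    for (round in 1:3) {
      rf <- .refineOrientation(refmov, movcube, anchor, u)
      if (rf$sse < sse - 1e-12 * (1 + sse)) {
        u <- rf$orientation; sse <- rf$sse
      }
      rescan <- .cpp_axis_scan(refmov, movcube, anchors,
                               matrix(u, 1, 3))
      if (rescan$sse < sse - 1e-12 * (1 + sse)) {
        anchorRes <- anchorCand[rescan$anchor_index]
        anchor <- ref[anchorRes, ]
        sse <- rescan$sse
      } else break
    }
  }
  ev <- .cpp_axis_eval(refmov, movcube, anchor, u)
  angles <- .deg(as.numeric(ev$angles_rad))
  if (mean(angles) < 0) { u <- -u; angles <- -angles }
  residual <- ev$sse / (3 * m * nf)
  new("HingeAxis", anchorResidue = as.integer(anchorRes),
      orientation = as.numeric(u), perFrameAngle = angles,
      movingDomain = as.integer(moving), coreDomain = as.integer(core),
      residualMsf = residual,
      capturedFraction = min(1, max(0, 1 - residual / totalMsf)),
      discreteOrientation = as.numeric(uDisc),
      discreteResidualMsf = discreteResidual,
      nOrientations = as.integer(nOrientations), seed = as.integer(seed))
}

#' Fit fixed axes for every non-core domain
#'
#' Runs \code{\link{fitFixedAxis}} independently for each non-core domain
#' against the same core, then evaluates the restricted whole-molecule
#' model in which the core sits at its reference position and every side
#' domain moves only by its fitted fixed-axis rotation. The combined
#' captured fraction uses the same whole-molecule single-body
#' superposition baseline as \code{\link{fitRigidDomains}}, so the two
#' are directly comparable (the restricted model can never capture more).
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param partition a \linkS4class{Partition} with >= 2 domains.
#' @param core core domain label.
#' @param ... passed to \code{\link{fitFixedAxis}}.
#' @return a \linkS4class{HingeAxisSet}.
#' @export
fitAllHinges <- function(traj, partition, core, ...) {
  stopifnot(is(partition, "Partition"), partition@q >= 2L)
  assign <- partition@assignment
  if (!any(assign == core)) stop("core domain is empty", call. = FALSE)
  referenceFrame <- selectReference(traj)
  others <- setdiff(seq_len(partition@q), core)
  axes <- lapply(others, function(l)
    fitFixedAxis(traj, partition, core, l,
                 referenceFrame = referenceFrame, ...))
  names(axes) <- paste0("domain", others)

  # restricted whole-molecule model, evaluated in core-fixed coordinates
  n <- nResidues(traj); nf <- nFrames(traj)
  ref <- .frameMatrix(traj, referenceFrame)
  coreIdx <- which(assign == core)
  sup <- .coreFixedFrames(traj, coreIdx, referenceFrame)
  pred <- array(rep(ref, nf), c(n, 3, nf))
  for (k in seq_along(others)) {
    ax <- axes[[k]]
    movIdx <- which(assign == others[k])
    a <- ref[ax@anchorResidue, ]
    for (f in seq_len(nf)) {
      R <- .rotationAbout(ax@orientation, .rad(ax@perFrameAngle[f]))
      P <- sweep(ref[movIdx, , drop = FALSE], 2, a)
      pred[movIdx, , f] <- sweep(P %*% t(R), 2, a, "+")
    }
  }
  frameSse <- vapply(seq_len(nf), function(f)
    sum((sup[, , f] - pred[, , f])^2), numeric(1))
  residual <- sum(frameSse) / (3 * n * nf)
  cube <- .asCube(trajCoords(traj))
  totalMsf <- .cpp_partition_sse(ref, cube, rep(1L, n), 1L) / (3 * n * nf)
  captured <- if (totalMsf < 1e-12) 1 else
    min(1, max(0, 1 - residual / totalMsf))
  new("HingeAxisSet", axes = axes, coreDomain = as.integer(core),
      combinedCapturedFraction = captured, residualMsf = residual,
      perFrameRmsd = sqrt(frameSse / n))
}

#' Write hinge axes as JSON (plus a viewer-friendly pseudo-atom PDB)
#'
#' The JSON records anchor, orientation, per-frame angles, residuals and
#' sampling settings for each axis; the optional PDB holds two
#' pseudo-atoms per axis so the axis renders as a cylinder end-to-end in
#' molecular viewers.
#'
#' @param axisSet a \linkS4class{HingeAxisSet} (or list of
#'   \linkS4class{HingeAxis}).
#' @param path JSON output path.
#' @param traj trajectory the axes were fitted on (for anchor
#'   coordinates); required for PDB output.
#' @param pdbPath optional pseudo-atom PDB path.
#' @param halfLength half-length of the rendered axis segment (Angstrom).
#' @export
writeAxesJson <- function(axisSet, path, traj = NULL, pdbPath = NULL,
                          halfLength = 25) {
  axes <- if (is(axisSet, "HingeAxisSet")) axisSet@axes else axisSet
  rec <- lapply(axes, function(ax) list(
    anchor_residue = ax@anchorResidue,
    orientation = ax@orientation,
    angles_deg = ax@perFrameAngle,
    moving_domain = ax@movingDomain, core_domain = ax@coreDomain,
    residual_msf = ax@residualMsf,
    captured_fraction = ax@capturedFraction,
    n_orientations = ax@nOrientations, seed = ax@seed))
  out <- list(axes = rec)
  if (is(axisSet, "HingeAxisSet"))
    out$combined_captured_fraction = axisSet@combinedCapturedFraction
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pdbPath) && !is.null(traj)) {
    refFrame <- selectReference(traj)
    ref <- .frameMatrix(traj, refFrame)
    xyz <- do.call(rbind, lapply(axes, function(ax) {
      a <- ref[ax@anchorResidue, ]
      rbind(a - halfLength * ax@orientation,
            a + halfLength * ax@orientation)
    }))
    bio3d::write.pdb(file = pdbPath,
                     xyz = as.vector(t(xyz)),
                     resno = seq_len(nrow(xyz)),
                     resid = rep("AXS", nrow(xyz)),
                     chain = rep("X", nrow(xyz)),
                     elety = rep("CA", nrow(xyz)))
  }
  invisible(path)
}
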