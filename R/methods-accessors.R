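#' @rdname CalphaTrajectory-class
#' @export
setMethod("trajCoords", "CalphaTrajectory", function(x) x@coords)

#' @rdname CalphaTrajectory-class
#' @export
setMethod("residueIds", "CalphaTrajectory", function(x) x@residueIds)

#' @rdname CalphaTrajectory-class
#' @export
setMethod("residueIds", "DistanceFluctuationMatrix", function(x) x@residueIds)

#' @rdname CalphaTrajectory-class
#' @export
setMethod("residueIds", "StrainProfile", function(x) x@residueIds)

#' @rdname CalphaTrajectory-class
#' @export
setMethod("nFrames", "CalphaTrajectory", function(x) dim(x@coords)[1])

#' @rdname CalphaTrajectory-class
#' @export
setMethod("nResidues", "CalphaTrajectory", function(x) dim(x@coords)[2])

#' @rdname CalphaTrajectory-class
#' @export
setMethod("frameTimes", "CalphaTrajectory", function(x) x@frameTimes)

#' @rdname DistanceFluctuationMatrix-class
#' @export
setMethod("fluctuationValues", "DistanceFluctuationMatrix",
          function(x) x@values)

#' @rdname DistanceFluctuationMatrix-class
#' @export
setMethod("meanDistances", "DistanceFluctuationMatrix",
          function(x) x@meanDistances)

#' @rdname StrainProfile-class
#' @export
setMethod("strainValues", "StrainProfile", function(x) x@perResidue)

#' @rdname Partition-class
#' @export
setMethod("domainAssignment", "Partition", function(x) x@assignment)

#' @rdname Partition-class
#' @export
setMethod("domainAssignment", "RigidFitResult",
          function(x) x@partition@assignment)

#' @rdname Partition-class
#' @export
setMethod("nDomains", "Partition", function(x) x@q)

#' @rdname Partition-class
#' @export
setMethod("nDomains", "RigidFitResult", function(x) x@partition@q)

#' @rdname RigidFitResult-class
#' @export
setMethod("capturedFraction", "RigidFitResult", function(x) x@capturedFraction)

#' @rdname RigidFitResult-class
#' @export
setMethod("capturedFraction", "HingeAxis", function(x) x@capturedFraction)

#' @rdname RigidFitResult-class
#' @export
setMethod("capturedFraction", "HingeAxisSet",
          function(x) x@combinedCapturedFraction)

#' @rdname RigidFitResult-class
#' @export
setMethod("residualMsf", "RigidFitResult", function(x) x@residualMsf)

#' @rdname RigidFitResult-class
#' @export
setMethod("residualMsf", "HingeAxis", function(x) x@residualMsf)

#' @rdname RigidFitResult-class
#' @export
setMethod("residualMsf", "HingeAxisSet", function(x) x@residualMsf)

#' @rdname RigidFitResult-class
#' @export
setMethod("perFrameRmsd", "RigidFitResult", function(x) x@perFrameRmsd)

#' @rdname RigidFitResult-class
#' @export
setMethod("perFrameRmsd", "HingeAxisSet", function(x) x@perFrameRmsd)

#' @rdname HingeAxis-class
#' @export
setMethod("axisOrientation", "HingeAxis", function(x) x@orientation)

#' @rdname HingeAxis-class
#' @export
setMethod("axisAnchor", "HingeAxis", function(x) x@anchorResidue)

#' @rdname HingeAxis-class
#' @export
setMethod("frameAngles", "HingeAxis", function(x) x@perFrameAngle)

#' @rdname MetaTrajectory-class
#' @export
setMethod("frameProvenance", "MetaTrajectory", function(x) x@frameProvenance)

setMethod("show", "CalphaTrajectory", function(object) {
  d <- dim(object@coords)
  cat(class(object), "with", d[1], "frames x", d[2], "residues\n")
  cat("  proteins:", paste(unique(object@residueIds$proteinTag),
                           collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
  if (length(object@frameTimes))
    cat("  time span:", object@frameTimes[1], "-",
        object@frameTimes[length(object@frameTimes)], "ns\n")
  if (is(object, "MetaTrajectory"))
    cat("  sources:", nrow(unique(object@frameProvenance[,
        c("proteinTag", "ligandState")])), "trajectory block(s)\n")
})

setMethod("show", "DistanceFluctuationMatrix", function(object) {
  cat("DistanceFluctuationMatrix:", nrow(object@values), "residues,",
      "frames", object@frameRange[1], "-", object@frameRange[2], "\n")
  cat("  mean off-diagonal fluctuation:",
      signif(mean(object@values[upper.tri(object@values)]), 4), "A^2\n")
})

setMethod("show", "StrainProfile", function(object) {
  cat("StrainProfile:", length(object@perResidue), "residues,",
      "sigmoid cutoff", object@cutoff, "A / width", object@width, "A\n")
  top <- order(object@perResidue, decreasing = TRUE)[1:min(5,
         length(object@perResidue))]
  cat("  top strain residues:", paste(top, collapse = ", "), "\n")
  if (nrow(object@perWindow))
    cat("  time-resolved:", nrow(object@perWindow), "windows of",
        object@windowLengthFrames, "frames\n")
})

setMethod("show", "Partition", function(object) {
  sizes <- tabulate(object@assignment, object@q)
  cat("Partition into", object@q, "quasi-rigid domain(s); sizes:",
      paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "RigidFitResult", function(object) {
  cat("RigidFitResult: q =", object@partition@q,
      " residualMsf =", signif(object@residualMsf, 4), "A^2\n")
  cat("  captured fraction:", signif(object@capturedFraction, 4),
      " mean fit RMSD:", signif(mean(object@perFrameRmsd), 4), "A\n")
})

setMethod("show", "HingeAxis", function(object) {
  cat("HingeAxis: domain", object@movingDomain, "about core",
      object@coreDomain, "\n")
  cat("  anchor residue:", object@anchorResidue, " orientation: (",
      paste(signif(object@orientation, 4), collapse = ", "), ")\n")
  cat("  angle range:", signif(min(object@perFrameAngle), 4), "-",
      signif(max(object@perFrameAngle), 4), "deg;",
      "captured fraction:", signif(object@capturedFraction, 4), "\n")
})

setMethod("show", "HingeAxisSet", function(object) {
  cat("HingeAxisSet:", length(object@axes), "axes about core domain",
      object@coreDomain, "\n")
  cat("  combined captured fraction:",
      signif(object@combinedCapturedFraction, 4),
      " mean RMSD:", signif(mean(object@perFrameRmsd), 4), "A\n")
})

setMethod("show", "CorrespondenceTable", function(object) {
  cat("CorrespondenceTable:", length(unique(object@table$groupId)),
      "groups x", length(unique(object@table$proteinTag)), "proteins\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", paste(object@domainSizes, collapse = "+"),
      "residues,", object@nFrames, "frames,",
      length(object@hinges), "hinge(s), sigma =", object@noiseSigma,
      "A, seed", object@seed, "\n")
})
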