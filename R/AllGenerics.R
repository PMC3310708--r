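#' @rdname CalphaTrajectory-class
#' @param object,x a \linkS4class{CalphaTrajectory} (or subclass).
#' @export
setGeneric("trajCoords", function(x) standardGeneric("trajCoords"))

#' @rdname CalphaTrajectory-class
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname CalphaTrajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname CalphaTrajectory-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname CalphaTrajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname DistanceFluctuationMatrix-class
#' @param x object to extract values from.
#' @export
setGeneric("fluctuationValues", function(x) standardGeneric("fluctuationValues"))

#' @rdname DistanceFluctuationMatrix-class
#' @export
setGeneric("meanDistances", function(x) standardGeneric("meanDistances"))

#' @rdname StrainProfile-class
#' @param x a \linkS4class{StrainProfile}.
#' @export
setGeneric("strainValues", function(x) standardGeneric("strainValues"))

#' @rdname Partition-class
#' @param x a \linkS4class{Partition} (or an object carrying one).
#' @export
setGeneric("domainAssignment", function(x) standardGeneric("domainAssignment"))

#' @rdname Partition-class
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' @rdname RigidFitResult-class
#' @param x a fit result.
#' @export
setGeneric("capturedFraction", function(x) standardGeneric("capturedFraction"))

#' @rdname RigidFitResult-class
#' @export
setGeneric("residualMsf", function(x) standardGeneric("residualMsf"))

#' @rdname RigidFitResult-class
#' @export
setGeneric("perFrameRmsd", function(x) standardGeneric("perFrameRmsd"))

#' @rdname HingeAxis-class
#' @param x a \linkS4class{HingeAxis}.
#' @export
setGeneric("axisOrientation", function(x) standardGeneric("axisOrientation"))

#' @rdname HingeAxis-class
#' @export
setGeneric("axisAnchor", function(x) standardGeneric("axisAnchor"))

#' @rdname HingeAxis-class
#' @export
setGeneric("frameAngles", function(x) standardGeneric("frameAngles"))

#' @rdname MetaTrajectory-class
#' @param x a \linkS4class{MetaTrajectory}.
#' @export
setGeneric("frameProvenance", function(x) standardGeneric("frameProvenance"))
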