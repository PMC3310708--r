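#' @import methods
NULL

#' Calpha coordinate trajectory
#'
#' The universal data carrier: an array of Calpha positions of shape
#' frames x residues x 3, in Angstrom, together with a residue table
#' (protein tag, chain, residue number, residue name), optional frame
#' times in nanoseconds, and a free-form provenance string.
#'
#' @slot coords numeric array, frames x residues x 3 (Angstrom).
#' @slot residueIds data.frame with columns \code{proteinTag},
#'   \code{chain}, \code{resno}, \code{resname}; one row per residue.
#' @slot frameTimes numeric, length 0 (absent) or one entry per frame,
#'   strictly increasing (ns).
#' @slot source character provenance string.
#' @export
setClass("CalphaTrajectory",
  representation(coords = "array", residueIds = "data.frame",
                 frameTimes = "numeric", source = "character"),
  prototype(frameTimes = numeric(0), source = "constructed"))

setValidity("CalphaTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x residues x 3 array")
  if (d[1] < 1L) return("at least one frame required")
  if (d[2] < 2L) return("at least two residues required")
  if (!all(is.finite(object@coords)))
    return("coords contain non-finite values")
  ri <- object@residueIds
  need <- c("proteinTag", "chain", "resno", "resname")
  if (!all(need %in% names(ri)))
    return("residueIds needs columns proteinTag, chain, resno, resname")
  if (nrow(ri) != d[2])
    return("residueIds rows must match the residue axis")
  key <- paste(ri$proteinTag, ri$chain, ri$resno)
  if (anyDuplicated(key))
    return("(proteinTag, chain, resno) triples must be unique")
  ft <- object@frameTimes
  if (length(ft) && (length(ft) != d[1] || any(diff(ft) <= 0)))
    return("frameTimes must have one strictly increasing entry per frame")
  TRUE
})

#' Residue selection
#'
#' A set of residue indices resolved from a selection expression of the
#' form \code{tag:<proteinTag> chain:<id> resid:<a>-<b>} (terms joined by
#' whitespace are ANDed, alternatives joined by \code{|} are ORed).
#'
#' @slot expression the selection string.
#' @slot indices sorted unique 1-based residue indices into the
#'   trajectory's residue axis.
#' @export
setClass("AtomSelection",
  representation(expression = "character", indices = "integer"))

setValidity("AtomSelection", function(object) {
  idx <- object@indices
  if (length(idx) && (anyDuplicated(idx) || is.unsorted(idx) || any(idx < 1L)))
    return("indices must be unique, sorted and positive")
  TRUE
})

#' Distance-fluctuation matrix
#'
#' Symmetric residue x residue matrix of the time variance of the
#' inter-Calpha distance (Angstrom^2); superposition-free by construction.
#'
#' @slot values symmetric numeric matrix, zero diagonal, entries >= 0.
#' @slot meanDistances time-mean inter-Calpha distance matrix (Angstrom),
#'   kept because the strain profile weights fluctuations by it.
#' @slot residueIds residue table of the source trajectory.
#' @slot frameRange integer (first, last) frame indices used.
#' @export
setClass("DistanceFluctuationMatrix",
  representation(values = "matrix", meanDistances = "matrix",
                 residueIds = "data.frame", frameRange = "integer"))

setValidity("DistanceFluctuationMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (max(abs(v - t(v))) > 1e-10) return("values must be symmetric")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  if (any(v < -1e-12)) return("entries must be non-negative")
  if (length(object@frameRange) != 2L) return("frameRange must be (first, last)")
  TRUE
})

#' Minimum-distance time series between two selections
#'
#' Per frame, the distance between the closest pair of atoms across two
#' disjoint selections, with the final-frame and time-average values.
#'
#' @slot perFrameMin numeric, one entry per frame (Angstrom).
#' @slot selectionA,selectionB the two \linkS4class{AtomSelection}s.
#' @slot finalValue last entry of \code{perFrameMin}.
#' @slot averageValue mean of \code{perFrameMin}.
#' @export
setClass("DistanceSeries",
  representation(perFrameMin = "numeric", selectionA = "AtomSelection",
                 selectionB = "AtomSelection", finalValue = "numeric",
                 averageValue = "numeric"))

setValidity("DistanceSeries", function(object) {
  x <- object@perFrameMin
  if (any(x < 0)) return("distances must be non-negative")
  if (length(x) && abs(object@finalValue - x[length(x)]) > 1e-12)
    return("finalValue must equal the last entry")
  if (length(x) && abs(object@averageValue - mean(x)) > 1e-12)
    return("averageValue must equal the mean")
  TRUE
})

#' Per-residue geometric strain profile
#'
#' Strain of residue i is the fluctuation of its ~5 Angstrom contact
#' network: the sigmoid-weighted row sum of the distance-fluctuation
#' matrix. Optionally time-resolved over non-overlapping frame windows.
#'
#' @slot perResidue numeric strain per residue (Angstrom^2).
#' @slot perWindow window x residue matrix (0 rows when not windowed).
#' @slot windowLengthFrames window length (0 when not windowed).
#' @slot cutoff,width logistic weight midpoint and width (Angstrom).
#' @slot residueIds residue table of the source trajectory.
#' @export
setClass("StrainProfile",
  representation(perResidue = "numeric", perWindow = "matrix",
                 windowLengthFrames = "integer", cutoff = "numeric",
                 width = "numeric", residueIds = "data.frame"),
  prototype(perWindow = matrix(numeric(0), 0, 0), windowLengthFrames = 0L))

setValidity("StrainProfile", function(object) {
  if (any(object@perResidue < -1e-12)) return("strain must be non-negative")
  if (object@cutoff <= 0 || object@width <= 0)
    return("cutoff and width must be positive")
  if (nrow(object@perWindow) > 0 &&
      ncol(object@perWindow) != length(object@perResidue))
    return("perWindow columns must match residue count")
  TRUE
})

#' Residue-to-domain partition
#'
#' @slot assignment integer domain label in 1..q per residue.
#' @slot q number of domains.
#' @slot contiguityRequired whether domains were constrained to be
#'   contiguous in sequence (quasi-rigid domains are spatial; default FALSE).
#' @export
setClass("Partition",
  representation(assignment = "integer", q = "integer",
                 contiguityRequired = "logical"),
  prototype(contiguityRequired = FALSE))

setValidity("Partition", function(object) {
  a <- object@assignment; q <- object@q
  if (length(q) != 1L || q < 1L) return("q must be a positive integer")
  if (any(a < 1L) || any(a > q)) return("labels must lie in 1..q")
  sizes <- tabulate(a, nbins = q)
  if (any(sizes == 0L)) return("every domain must be non-empty")
  if (any(sizes < 3L)) return("every domain needs >= 3 residues")
  TRUE
})

#' Per-frame per-domain rigid-body fit of a partition
#'
#' For every frame and domain, the optimal (Kabsch) rigid placement of the
#' reference-frame domain onto the frame's coordinates. \code{residualMsf}
#' is the per-coordinate mean squared residual (Angstrom^2), so that for
#' planted rigid motion plus isotropic noise of standard deviation sigma it
#' approaches 2 sigma^2; \code{perFrameRmsd} is the conventional per-atom
#' RMSD, hence \code{mean(perFrameRmsd^2) == 3 * residualMsf}.
#'
#' @slot rotations 3 x 3 x (q*frames) array, domain index fastest.
#' @slot translations 3 x (q*frames) matrix (Angstrom).
#' @slot residualMsf per-coordinate mean squared residual (Angstrom^2).
#' @slot rawSse total residual sum of squares (Angstrom^2).
#' @slot totalMsf same measure under a single whole-molecule superposition
#'   per frame (the baseline).
#' @slot capturedFraction 1 - residualMsf / totalMsf, clamped to [0, 1];
#'   1 when the baseline itself is ~0.
#' @slot perFrameRmsd conventional per-atom RMSD per frame (Angstrom).
#' @slot referenceFrame index of the reference conformation.
#' @slot partition the fitted \linkS4class{Partition}.
#' @export
setClass("RigidFitResult",
  representation(rotations = "array", translations = "matrix",
                 residualMsf = "numeric", rawSse = "numeric",
                 totalMsf = "numeric", capturedFraction = "numeric",
                 perFrameRmsd = "numeric", referenceFrame = "integer",
                 partition = "Partition"))

setValidity("RigidFitResult", function(object) {
  if (object@residualMsf < 0) return("residualMsf must be non-negative")
  cf <- object@capturedFraction
  if (is.finite(cf) && (cf < -1e-9 || cf > 1 + 1e-9))
    return("capturedFraction must lie in [0, 1]")
  rot <- object@rotations
  if (length(dim(rot)) != 3L || any(dim(rot)[1:2] != 3L))
    return("rotations must be 3 x 3 x (q*frames)")
  for (k in seq_len(dim(rot)[3])) {
    R <- rot[, , k]
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
      return("rotations must be proper orthogonal")
  }
  if (abs(mean(object@perFrameRmsd^2) - 3 * object@residualMsf) >
      1e-8 * max(1, object@residualMsf))
    return("mean(perFrameRmsd^2) must equal 3 * residualMsf")
  TRUE
})

#' Fixed hinge axis of a moving domain
#'
#' A time-independent rotation axis, fixed in the core-domain frame and
#' passing through one Calpha, about which the moving domain's motion is
#' modelled as pure rotation; the per-frame angle is the only
#' time-dependent parameter.
#'
#' @slot anchorResidue 1-based residue index of the Calpha on the axis.
#' @slot orientation unit 3-vector in core-fixed reference coordinates,
#'   sign fixed so the mean angle is >= 0.
#' @slot perFrameAngle rotation angle per frame (degrees).
#' @slot movingDomain,coreDomain domain labels.
#' @slot residualMsf per-coordinate mean squared residual over the moving
#'   domain (Angstrom^2).
#' @slot capturedFraction share of the moving domain's mean-square
#'   displacement (in core-fixed coordinates, relative to the reference)
#'   explained by the fitted rotation; NA when the domain is static.
#' @slot discreteOrientation best orientation before continuous
#'   refinement (the raw anchor x sampled-orientation scan result).
#' @slot discreteResidualMsf residual of the discrete-scan axis.
#' @slot nOrientations,seed the orientation-sampling settings used.
#' @export
setClass("HingeAxis",
  representation(anchorResidue = "integer", orientation = "numeric",
                 perFrameAngle = "numeric", movingDomain = "integer",
                 coreDomain = "integer", residualMsf = "numeric",
                 capturedFraction = "numeric",
                 discreteOrientation = "numeric",
                 discreteResidualMsf = "numeric",
                 nOrientations = "integer", seed = "integer"))

setValidity("HingeAxis", function(object) {
  if (abs(sqrt(sum(object@orientation^2)) - 1) > 1e-10)
    return("orientation must be a unit vector")
  if (length(object@anchorResidue) != 1L || object@anchorResidue < 1L)
    return("anchorResidue must be a single positive index")
  TRUE
})

#' A set of hinge axes sharing one core domain
#'
#' Result of fitting every non-core domain of a partition with its own
#' fixed axis; carries the combined whole-molecule fit, comparable (same
#' baseline) with the unrestricted rigid-domain fit.
#'
#' @slot axes list of \linkS4class{HingeAxis}.
#' @slot coreDomain core domain label.
#' @slot combinedCapturedFraction whole-molecule mean-square fluctuation
#'   explained when side domains move only by their fitted rotations.
#' @slot residualMsf combined per-coordinate residual (Angstrom^2).
#' @slot perFrameRmsd whole-molecule per-atom RMSD per frame of the
#'   restricted model (Angstrom).
#' @export
setClass("HingeAxisSet",
  representation(axes = "list", coreDomain = "integer",
                 combinedCapturedFraction = "numeric",
                 residualMsf = "numeric", perFrameRmsd = "numeric"))

#' Residue-correspondence table across proteins
#'
#' Rows of (groupId, proteinTag, chain, resno): alignment columns mapping
#' equivalent residues across homologous proteins. Only complete columns
#' (covering every protein in the table) are retained.
#'
#' @slot table data.frame with columns \code{groupId}, \code{proteinTag},
#'   \code{chain}, \code{resno}.
#' @export
setClass("CorrespondenceTable", representation(table = "data.frame"))

setValidity("CorrespondenceTable", function(object) {
  tb <- object@table
  need <- c("groupId", "proteinTag", "chain", "resno")
  if (!all(need %in% names(tb)))
    return("table needs columns groupId, proteinTag, chain, resno")
  if (anyDuplicated(tb[, c("groupId", "proteinTag")]))
    return("a proteinTag may appear at most once per group")
  if (anyDuplicated(tb[, c("proteinTag", "chain", "resno")]))
    return("a residue may belong to at most one group")
  tags <- unique(tb$proteinTag)
  cover <- table(tb$groupId)
  if (length(cover) && any(cover != length(tags)))
    return("every group must cover all protein tags (complete columns only)")
  TRUE
})

#' Meta-trajectory of corresponding residues
#'
#' A \linkS4class{CalphaTrajectory} whose residue axis is the ordered
#' correspondence groups and whose frames are the concatenated source
#' frames, with per-frame provenance (protein tag, ligand state, original
#' frame index).
#'
#' @slot frameProvenance data.frame with columns \code{proteinTag},
#'   \code{ligandState}, \code{sourceFrame}; one row per frame.
#' @export
setClass("MetaTrajectory", contains = "CalphaTrajectory",
  representation(frameProvenance = "data.frame"))

setValidity("MetaTrajectory", function(object) {
  if (nrow(object@frameProvenance) != dim(object@coords)[1])
    return("frameProvenance must have one row per frame")
  need <- c("proteinTag", "ligandState", "sourceFrame")
  if (!all(need %in% names(object@frameProvenance)))
    return("frameProvenance needs proteinTag, ligandState, sourceFrame")
  TRUE
})

#' Specification of a planted-ground-truth synthetic trajectory
#'
#' Describes a multi-domain molecule built from compact random blobs that
#' move as rigid bodies about planted fixed hinge axes, with additive
#' isotropic Gaussian coordinate noise.
#'
#' @slot domainSizes residues per domain (each >= 3).
#' @slot hinges list of hinges; each a list with fields \code{moving}
#'   (domain label), \code{core} (domain label), \code{anchor} (global
#'   residue index in the core domain, or NA to pick one near the moving
#'   domain), \code{orientation} (3-vector, normalised at generation) and
#'   \code{angles} (degrees, one per frame, or NULL for a smooth default
#'   schedule).
#' @slot noiseSigma per-coordinate Gaussian noise s.d. (Angstrom).
#' @slot nFrames number of frames.
#' @slot seed RNG seed.
#' @slot scale blob packing scale factor (dimensionless, default 1).
#' @slot tag protein tag stamped on the residues.
#' @export
setClass("SyntheticSpec",
  representation(domainSizes = "integer", hinges = "list",
                 noiseSigma = "numeric", nFrames = "integer",
                 seed = "integer", scale = "numeric", tag = "character"),
  prototype(noiseSigma = 0, nFrames = 50L, seed = 1L, scale = 1,
            tag = "synth"))

setValidity("SyntheticSpec", function(object) {
  if (any(object@domainSizes < 3L)) return("domains need >= 3 residues")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  for (h in object@hinges) {
    if (!all(c("moving", "core") %in% names(h)))
      return("each hinge needs moving and core domain labels")
    if (!is.null(h$angles) && length(h$angles) != object@nFrames)
      return("angle schedules must have one entry per frame")
  }
  TRUE
})
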