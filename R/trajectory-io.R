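#' Construct a CalphaTrajectory from parts
#'
#' @param coords numeric array frames x residues x 3 (Angstrom).
#' @param residueIds data.frame with columns \code{proteinTag},
#'   \code{chain}, \code{resno}, \code{resname}; defaults to sequential
#'   numbering on chain A.
#' @param frameTimes optional strictly increasing frame times (ns).
#' @param source provenance string.
#' @return a \linkS4class{CalphaTrajectory}.
#' @export
CalphaTrajectory <- function(coords, residueIds = NULL,
                             frameTimes = numeric(0),
                             source = "constructed") {
  coords <- as.array(coords)
  if (is.null(residueIds)) {
    n <- dim(coords)[2]
    residueIds <- data.frame(proteinTag = "protein", chain = "A",
                             resno = seq_len(n), resname = "ALA",
                             stringsAsFactors = FALSE)
  }
  new("CalphaTrajectory", coords = coords, residueIds = residueIds,
      frameTimes = as.numeric(frameTimes), source = source)
}

# ---- structure/trajectory readers ------------------------------------

# minimal fixed-width GRO reader (single or concatenated multi-frame);
# GRO stores nm, converted to Angstrom here. Returns atom table + xyz
# (frames x 3*atoms) in Angstrom.
.readGro <- function(path) {
  lines <- readLines(path)
  frames <- list(); atomTab <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO file: ", path, call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + natoms)]
    resno <- as.integer(substr(block, 1, 5))
    resid <- trimws(substr(block, 6, 10))
    elety <- trimws(substr(block, 11, 15))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44))) * 10  # nm -> Angstrom
    if (is.null(atomTab))
      atomTab <- data.frame(elety = elety, resno = resno, resid = resid,
                            chain = "A", insert = NA_character_,
                            alt = NA_character_, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- as.vector(t(xyz))
    i <- i + 3L + natoms  # title, count, atoms, box line
  }
  if (!length(frames)) stop("zero frames in ", path, call. = FALSE)
  list(atom = atomTab, xyz = do.call(rbind, frames))
}

.readStructure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(.readGro(path))
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  list(atom = data.frame(elety = at$elety, resno = at$resno,
                         resid = at$resid, chain = at$chain,
                         insert = at$insert, alt = at$alt,
                         stringsAsFactors = FALSE),
       xyz = matrix(p$xyz, nrow = nrow(p$xyz), ncol = ncol(p$xyz)))
}

#' Load a Calpha trajectory from structure (and trajectory) files
#'
#' Reads a multi-model PDB or GRO structure file, reduces it to Calpha
#' atoms (one per residue), and optionally replaces its frames with a
#' binary trajectory (DCD or AMBER NetCDF, read through bio3d) whose atom
#' count must match the structure. All coordinates are returned in
#' Angstrom (GRO nm sources are converted); residues are ordered by
#' (chain, residue number).
#'
#' Residues lacking a Calpha are dropped with a warning. Only the first
#' alternate location of a Calpha is kept; insertion codes are folded
#' into the residue numbering by sequential renumbering of the affected
#' chain (logged).
#'
#' @param structurePath path to a PDB (multi-model allowed) or GRO file.
#' @param trajectoryPath optional path to a DCD/NetCDF trajectory.
#' @param selection optional selection expression (see
#'   \code{\link{selectResidues}}) applied after Calpha reduction.
#' @param proteinTag tag stamped on the residues; defaults to the
#'   structure file name without extension.
#' @return a \linkS4class{CalphaTrajectory}.
#' @export
loadTrajectory <- function(structurePath, trajectoryPath = NULL,
                           selection = NULL, proteinTag = NULL) {
  if (is.null(proteinTag))
    proteinTag <- tools::file_path_sans_ext(basename(structurePath))
  s <- .readStructure(structurePath)
  at <- s$atom
  at$chain[is.na(at$chain)] <- "A"
  at$insert[!is.na(at$insert) & at$insert == ""] <- NA_character_
  resKey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "",
                                             at$insert))
  isCa <- at$elety == "CA"
  # first altloc only
  if (any(isCa)) {
    caRows <- which(isCa)
    keep <- !duplicated(resKey[caRows])
    if (!all(keep))
      message("keeping first alternate location for ",
              sum(!keep), " Calpha atom(s)")
    caRows <- caRows[keep]
  } else caRows <- integer(0)
  missingRes <- setdiff(unique(resKey), resKey[caRows])
  if (length(missingRes))
    warning(length(missingRes),
            " residue(s) without a Calpha dropped", call. = FALSE)
  if (length(caRows) < 2L)
    stop("structure must contain at least two residues with Calpha atoms",
         call. = FALSE)

  ca <- at[caRows, , drop = FALSE]
  # fold insertion codes: renumber affected chains sequentially
  if (any(!is.na(ca$insert))) {
    message("insertion codes present; renumbering affected chain(s) ",
            "sequentially")
    for (ch in unique(ca$chain[!is.na(ca$insert)])) {
      rows <- ca$chain == ch
      ord <- order(ca$resno[rows], ifelse(is.na(ca$insert[rows]), "",
                                          ca$insert[rows]))
      ca$resno[rows][ord] <- seq_len(sum(rows))
    }
  }
  ord <- order(ca$chain, ca$resno)
  ca <- ca[ord, , drop = FALSE]
  caRows <- caRows[ord]

  if (is.null(trajectoryPath)) {
    xyz <- s$xyz
  } else {
    if (!file.exists(trajectoryPath))
      stop("trajectory file not found: ", trajectoryPath, call. = FALSE)
    ext <- tolower(tools::file_ext(trajectoryPath))
    xyz <- switch(ext,
      dcd = bio3d::read.dcd(trajectoryPath, verbose = FALSE),
      nc = ,
      ncdf = bio3d::read.ncdf(trajectoryPath),
      stop("unsupported trajectory format: .", ext, call. = FALSE))
    xyz <- matrix(xyz, nrow = nrow(xyz))
    if (ncol(xyz) != 3L * nrow(at))
      stop("trajectory atom count (", ncol(xyz) / 3,
           ") does not match structure (", nrow(at), ")", call. = FALSE)
  }
  if (nrow(xyz) < 1L) stop("zero frames in input", call. = FALSE)

  nf <- nrow(xyz); nres <- length(caRows)
  coords <- array(NA_real_, c(nf, nres, 3))
  for (k in seq_len(3))
    coords[, , k] <- xyz[, (caRows - 1L) * 3L + k, drop = FALSE]

  traj <- new("CalphaTrajectory", coords = coords,
              residueIds = data.frame(proteinTag = proteinTag,
                                      chain = ca$chain, resno = ca$resno,
                                      resname = ca$resid,
                                      stringsAsFactors = FALSE),
              frameTimes = numeric(0),
              source = paste0(structurePath,
                              if (!is.null(trajectoryPath))
                                paste0(" + ", trajectoryPath) else ""))
  if (!is.null(selection)) traj <- subsetResidues(traj, selection)
  traj
}

#' Write a Calpha trajectory as a multi-model PDB
#'
#' One MODEL per frame, Calpha ATOM records only; residue numbering and
#' chain identifiers are preserved.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param path output file path.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "CalphaTrajectory"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("cannot write to ", path, call. = FALSE)
  ri <- residueIds(traj)
  nf <- nFrames(traj); n <- nResidues(traj)
  xyz <- matrix(NA_real_, nf, 3L * n)
  for (k in seq_len(3)) xyz[, seq(k, 3L * n, by = 3L)] <- trajCoords(traj)[, , k]
  bio3d::write.pdb(file = path, xyz = xyz, resno = ri$resno,
                   resid = ri$resname, chain = ri$chain,
                   elety = rep("CA", n))
  if (nf == 1L) {
    # keep the one-MODEL-per-frame contract also for single frames
    lines <- readLines(path)
    atoms <- grepl("^(ATOM|HETATM|TER)", lines)
    writeLines(c("MODEL        1", lines[atoms], "ENDMDL", "END"), path)
  }
  invisible(path)
}

# ---- selections ------------------------------------------------------

#' Resolve a residue selection expression
#'
#' Grammar: whitespace-separated terms \code{tag:<proteinTag>},
#' \code{chain:<id>}, \code{resid:<a>-<b>} (or a single \code{resid:<a>})
#' are ANDed within a clause; clauses joined by \code{|} are ORed.
#' An empty or missing expression selects everything.
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param expression selection string.
#' @return an \linkS4class{AtomSelection} with sorted 1-based indices.
#' @export
selectResidues <- function(traj, expression = "") {
  ri <- residueIds(traj)
  n <- nrow(ri)
  if (is(expression, "AtomSelection")) return(expression)
  expr <- trimws(expression)
  if (!nzchar(expr))
    return(new("AtomSelection", expression = "", indices = seq_len(n)))
  hits <- rep(FALSE, n)
  for (clause in strsplit(expr, "|", fixed = TRUE)[[1]]) {
    keep <- rep(TRUE, n)
    terms <- strsplit(trimws(clause), "\\s+")[[1]]
    for (term in terms[nzchar(terms)]) {
      kv <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed selection term: ", term, call. = FALSE)
      val <- kv[2]
      keep <- keep & switch(kv[1],
        tag = ri$proteinTag == val,
        chain = ri$chain == val,
        resid = {
          ab <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
          if (anyNA(ab)) stop("bad resid range: ", val, call. = FALSE)
          if (length(ab) == 1L) ri$resno == ab
          else ri$resno >= ab[1] & ri$resno <= ab[2]
        },
        stop("unknown selection key: ", kv[1], call. = FALSE))
    }
    hits <- hits | keep
  }
  new("AtomSelection", expression = expression,
      indices = which(hits))
}

#' Subset a trajectory to a residue selection
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param selection an \linkS4class{AtomSelection}, selection expression,
#'   or integer index vector.
#' @return the reduced \linkS4class{CalphaTrajectory}.
#' @export
subsetResidues <- function(traj, selection) {
  idx <- if (is(selection, "AtomSelection")) selection@indices
         else if (is.character(selection))
           selectResidues(traj, selection)@indices
         else sort(unique(as.integer(selection)))
  if (!length(idx)) stop("empty selection", call. = FALSE)
  if (any(idx < 1L | idx > nResidues(traj)))
    stop("selection indices out of bounds", call. = FALSE)
  new("CalphaTrajectory",
      coords = trajCoords(traj)[, idx, , drop = FALSE],
      residueIds = residueIds(traj)[idx, , drop = FALSE],
      frameTimes = frameTimes(traj), source = traj@source)
}
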