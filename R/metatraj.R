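# Meta-trajectory construction: concatenate trajectories of homologous
# proteins restricted to corresponding residues, so one joint
# decomposition covers them all; per-source bookkeeping lets results be
# reported per protein.

#' Construct a CorrespondenceTable
#'
#' @param table data.frame with columns \code{groupId},
#'   \code{proteinTag}, \code{chain}, \code{resno}. Groups that do not
#'   cover every protein tag present are dropped with a message.
#' @return a \linkS4class{CorrespondenceTable}.
#' @export
CorrespondenceTable <- function(table) {
  table <- as.data.frame(table)
  dup <- duplicated(table[, c("proteinTag", "chain", "resno")])
  if (any(dup))
    stop("duplicate (protein, residue) assignment at row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  tags <- unique(table$proteinTag)
  cover <- tapply(table$proteinTag, table$groupId,
                  function(x) length(unique(x)))
  incomplete <- names(cover)[cover < length(tags)]
  if (length(incomplete)) {
    message("dropping ", length(incomplete),
            " incomplete correspondence group(s)")
    table <- table[!(as.character(table$groupId) %in% incomplete), ,
                   drop = FALSE]
  }
  table <- table[order(table$groupId, table$proteinTag), , drop = FALSE]
  rownames(table) <- NULL
  new("CorrespondenceTable", table = table)
}

#' Read a residue-correspondence table from TSV
#'
#' Expected header: \code{group_id}, \code{protein_tag}, \code{chain},
#' \code{resid}. Such tables map equivalent residues across homologous
#' proteins (e.g. produced externally by flexible structural alignment);
#' incomplete groups are dropped with a logged count.
#'
#' @param path TSV file path.
#' @return a \linkS4class{CorrespondenceTable}.
#' @export
loadCorrespondence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("group_id", "protein_tag", "chain", "resid")
  if (!all(need %in% names(tb)))
    stop("expected header: group_id protein_tag chain resid",
         call. = FALSE)
  CorrespondenceTable(data.frame(groupId = as.integer(tb$group_id),
                                 proteinTag = as.character(tb$protein_tag),
                                 chain = as.character(tb$chain),
                                 resno = as.integer(tb$resid),
                                 stringsAsFactors = FALSE))
}

#' Write a correspondence table as TSV
#'
#' @param table a \linkS4class{CorrespondenceTable}.
#' @param path output path.
#' @export
writeCorrespondence <- function(table, path) {
  tb <- table@table
  utils::write.table(
    data.frame(group_id = tb$groupId, protein_tag = tb$proteinTag,
               chain = tb$chain, resid = tb$resno),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a meta-trajectory of corresponding residues
#'
#' Each input trajectory is reduced to the residues listed for its
#' protein tag (ordered by group id) and the frames are concatenated in
#' input order; no re-superposition is performed, because downstream
#' analyses are either superposition-free or superpose internally.
#'
#' @param trajs list of entries; each either a
#'   \linkS4class{CalphaTrajectory} (tag taken from its residue table) or
#'   a list with fields \code{trajectory}, \code{proteinTag} (optional
#'   override) and \code{ligandState} (optional label, reporting only).
#' @param table a \linkS4class{CorrespondenceTable} covering every input
#'   protein tag.
#' @return a \linkS4class{MetaTrajectory}.
#' @export
buildMetaTrajectory <- function(trajs, table) {
  stopifnot(is(table, "CorrespondenceTable"), length(trajs) >= 1L)
  tb <- table@table
  groups <- sort(unique(tb$groupId))
  blocks <- list(); prov <- list()
  for (k in seq_along(trajs)) {
    entry <- trajs[[k]]
    if (is(entry, "CalphaTrajectory"))
      entry <- list(trajectory = entry)
    tr <- entry$trajectory
    tag <- if (!is.null(entry$proteinTag)) entry$proteinTag
           else unique(residueIds(tr)$proteinTag)[1]
    lig <- if (!is.null(entry$ligandState)) entry$ligandState else "none"
    sub <- tb[tb$proteinTag == tag, , drop = FALSE]
    if (!nrow(sub))
      stop("no correspondence rows for protein tag '", tag, "'",
           call. = FALSE)
    sub <- sub[match(groups, sub$groupId), , drop = FALSE]
    ri <- residueIds(tr)
    idx <- match(paste(sub$chain, sub$resno),
                 paste(ri$chain, ri$resno))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      stop("residue ", sub$chain[miss], ":", sub$resno[miss],
           " of protein '", tag, "' referenced in the table is absent ",
           "from its trajectory", call. = FALSE)
    }
    blocks[[k]] <- trajCoords(tr)[, idx, , drop = FALSE]
    prov[[k]] <- data.frame(proteinTag = tag, ligandState = lig,
                            sourceFrame = seq_len(nFrames(tr)),
                            stringsAsFactors = FALSE)
  }
  nfTotal <- sum(vapply(blocks, function(b) dim(b)[1], integer(1)))
  coords <- array(NA_real_, c(nfTotal, length(groups), 3))
  at <- 0L
  for (b in blocks) {
    coords[at + seq_len(dim(b)[1]), , ] <- b
    at <- at + dim(b)[1]
  }
  new("MetaTrajectory", coords = coords,
      residueIds = data.frame(proteinTag = "meta", chain = "A",
                              resno = groups,
                              resname = "GRP", stringsAsFactors = FALSE),
      frameTimes = numeric(0),
      source = paste("meta-trajectory of", length(trajs), "source(s)"),
      frameProvenance = do.call(rbind, prov))
}

#' Per-source fit quality report
#'
#' Groups the per-frame fit RMSD of a rigid-domain or fixed-axis fit on a
#' meta-trajectory by source (protein tag x ligand state) and reports
#' mean, max and the fraction of frames fitted within a threshold.
#'
#' @param meta the \linkS4class{MetaTrajectory} the fit was computed on.
#' @param fit a \linkS4class{RigidFitResult} or \linkS4class{HingeAxisSet}
#'   computed on \code{meta}.
#' @param threshold RMSD threshold (Angstrom, default 4).
#' @return data.frame with one row per source plus an \code{overall} row:
#'   columns \code{proteinTag}, \code{ligandState}, \code{nFrames},
#'   \code{meanRmsd}, \code{maxRmsd}, \code{fracWithin}.
#' @export
perSourceFitReport <- function(meta, fit, threshold = 4) {
  stopifnot(is(meta, "MetaTrajectory"))
  rmsd <- perFrameRmsd(fit)
  if (length(rmsd) != nFrames(meta))
    stop("fit does not match the meta-trajectory (frame count differs)",
         call. = FALSE)
  prov <- frameProvenance(meta)
  key <- paste(prov$proteinTag, prov$ligandState, sep = "/")
  rows <- lapply(unique(key), function(k) {
    r <- rmsd[key == k]
    p <- prov[match(k, key), ]
    data.frame(proteinTag = p$proteinTag, ligandState = p$ligandState,
               nFrames = length(r), meanRmsd = mean(r), maxRmsd = max(r),
               fracWithin = mean(r <= threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(proteinTag = "overall", ligandState = "",
                        nFrames = length(rmsd), meanRmsd = mean(rmsd),
                        maxRmsd = max(rmsd),
                        fracWithin = mean(rmsd <= threshold),
                        stringsAsFactors = FALSE))
}
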