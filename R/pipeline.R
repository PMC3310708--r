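# Pipeline orchestration and the command-line entry point. The pipeline
# runs the analysis stages in their natural order (fluctuation -> strain
# -> optional meta-trajectory -> quasi-rigid decomposition -> hinge
# axes) and writes plain-text/JSON artifacts plus a manifest with
# checksums, so a rerun with the same seeds is verifiably identical.

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(discardFrames = 0L, cutoff = 5, width = 0.5,
                   q = 3L, qScan = NULL, seed = 1L, nOrientations = 500L,
                   core = NULL, force = FALSE, outputDir = "hingescan-out",
                   trajectories = NULL, correspondence = NULL,
                   synth = NULL, windowFrames = NULL)
  utils::modifyList(defaults, config)
}

.specFromList <- function(s) {
  SyntheticSpec(domainSizes = unlist(s$domainSizes),
                hinges = if (is.null(s$hinges)) list() else s$hinges,
                noiseSigma = if (is.null(s$noiseSigma)) 0 else s$noiseSigma,
                nFrames = if (is.null(s$nFrames)) 50L else s$nFrames,
                seed = if (is.null(s$seed)) 1L else s$seed,
                tag = if (is.null(s$tag)) "synth" else s$tag)
}

#' Run the full analysis pipeline
#'
#' Loads or generates the input trajectory (several trajectories plus a
#' correspondence table become a meta-trajectory), discards equilibration
#' frames, computes the distance-fluctuation matrix and strain profile,
#' decomposes into quasi-rigid domains (single q or a q scan), fits fixed
#' hinge axes for every non-core domain, and writes all artifacts with a
#' JSON manifest listing their md5 checksums and the full configuration.
#'
#' @param config a named list or YAML file path. Recognised fields:
#'   \code{trajectories} (list of \code{structure}/\code{trajectory}/
#'   \code{tag}/\code{ligandState} entries), \code{correspondence} (TSV
#'   path), \code{synth} (a synthetic spec as a list, used when no
#'   trajectories are given), \code{discardFrames}, \code{cutoff},
#'   \code{width}, \code{windowFrames}, \code{q} or \code{qScan},
#'   \code{core} (core domain label for the axis fit; default: largest
#'   domain), \code{nOrientations}, \code{seed}, \code{outputDir},
#'   \code{force}.
#' @return (invisibly) the manifest as a list; artifacts are written
#'   under \code{outputDir}.
#' @export
runPipeline <- function(config) {
  cfg <- .readConfig(config)
  out <- cfg$outputDir
  manifestPath <- file.path(out, "manifest.json")
  if (file.exists(manifestPath) && !isTRUE(cfg$force))
    stop("output directory already holds a manifest; use force = TRUE",
         call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  addArtifact <- function(path) artifacts <<- c(artifacts, path)

  # --- input stage ---
  if (!is.null(cfg$trajectories)) {
    trajs <- lapply(cfg$trajectories, function(tr) {
      if (is.null(tr$structure) || !file.exists(tr$structure))
        stop("missing input structure: ",
             if (is.null(tr$structure)) "(unset)" else tr$structure,
             call. = FALSE)
      list(trajectory = loadTrajectory(tr$structure, tr$trajectory,
                                       proteinTag = tr$tag),
           proteinTag = tr$tag,
           ligandState = if (is.null(tr$ligandState)) "none"
                         else tr$ligandState)
    })
    if (length(trajs) > 1L || !is.null(cfg$correspondence)) {
      if (is.null(cfg$correspondence))
        stop("several trajectories need a correspondence table",
             call. = FALSE)
      tab <- loadCorrespondence(cfg$correspondence)
      traj <- buildMetaTrajectory(trajs, tab)
      utils::write.table(frameProvenance(traj),
                         file.path(out, "provenance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      addArtifact(file.path(out, "provenance.tsv"))
    } else {
      traj <- trajs[[1]]$trajectory
    }
  } else if (!is.null(cfg$synth)) {
    spec <- .specFromList(cfg$synth)
    gen <- generateTrajectory(spec)
    traj <- gen$trajectory
    writeTrajectory(traj, file.path(out, "synthetic.pdb"))
    jsonlite::write_json(gen$truth[c("assignment", "interface")],
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    addArtifact(file.path(out, "synthetic.pdb"))
    addArtifact(file.path(out, "ground_truth.json"))
  } else {
    stop("config must provide either trajectories or a synth spec",
         call. = FALSE)
  }

  if (cfg$discardFrames > 0) {
    if (cfg$discardFrames >= nFrames(traj) - 1L)
      stop("discardFrames leaves fewer than 2 frames", call. = FALSE)
    traj <- subsetFrames(traj, (cfg$discardFrames + 1L):nFrames(traj))
  }

  # --- fluctuation + strain ---
  dfm <- distanceFluctuationMatrix(traj)
  writeFluctuationTsv(dfm, file.path(out, "dfmat.tsv"))
  saveRDS(dfm, file.path(out, "dfmat.rds"))
  addArtifact(file.path(out, "dfmat.tsv"))
  addArtifact(file.path(out, "dfmat.rds"))
  strain <- if (is.null(cfg$windowFrames))
    strainProfile(traj, cfg$cutoff, cfg$width)
  else strainTimeResolved(traj, cfg$windowFrames, cfg$cutoff, cfg$width)
  writeStrainTsv(strain, file.path(out, "strain.tsv"))
  addArtifact(file.path(out, "strain.tsv"))

  # --- quasi-rigid decomposition ---
  if (!is.null(cfg$qScan)) {
    qv <- if (length(cfg$qScan) == 2L)
      seq.int(cfg$qScan[1], cfg$qScan[2]) else unlist(cfg$qScan)
    scan <- scanQ(traj, qv, seed = cfg$seed)
    utils::write.table(scan, file.path(out, "qscan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    addArtifact(file.path(out, "qscan.tsv"))
    sq <- attr(scan, "suggestedQ")
    pick <- if (!is.na(sq)) which(scan$q == sq)[1] else nrow(scan)
    best <- attr(scan, "partitions")[[pick]]
    sp <- list(partition = best, fit = fitRigidDomains(traj, best))
  } else {
    sp <- searchPartition(traj, cfg$q, seed = cfg$seed)
  }
  writePartitionJson(sp$fit, file.path(out, "partition.json"),
                     seed = cfg$seed)
  addArtifact(file.path(out, "partition.json"))

  # --- hinge axes ---
  axisInfo <- NULL
  if (sp$partition@q >= 2L) {
    core <- if (!is.null(cfg$core)) cfg$core
            else which.max(tabulate(sp$partition@assignment,
                                    sp$partition@q))
    axes <- fitAllHinges(traj, sp$partition, core,
                         nOrientations = cfg$nOrientations,
                         seed = cfg$seed)
    writeAxesJson(axes, file.path(out, "axes.json"), traj = traj,
                  pdbPath = file.path(out, "axes.pdb"))
    addArtifact(file.path(out, "axes.json"))
    addArtifact(file.path(out, "axes.pdb"))
    axisInfo <- list(core = core,
                     combined_captured_fraction =
                       axes@combinedCapturedFraction)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hingescan")),
    config = cfg[setdiff(names(cfg), "force")],
    summary = c(list(n_frames = nFrames(traj),
                     n_residues = nResidues(traj),
                     q = sp$partition@q,
                     captured_fraction = sp$fit@capturedFraction,
                     epsilon2 = sp$fit@residualMsf), axisInfo),
    artifacts = lapply(artifacts, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# ---- command-line interface -----------------------------------------

.cliUsage <- function() {
  cat("usage: hingescan <subcommand> [options]\n",
      "subcommands:\n",
      "  pipeline --config cfg.yaml [--out DIR] [--force]\n",
      "  synth    --spec spec.yaml --out-prefix PREFIX\n",
      "  dfmat    --structure S [--traj T] [--discard-frames N] --out F\n",
      "  strain   --structure S [--traj T] [--cutoff X] [--width W]\n",
      "           [--window-frames N] --out F\n",
      "  qrd      --structure S [--traj T] --q Q [--seed S] --out F\n",
      "  axisfit  --structure S [--traj T] --partition P.json --core L\n",
      "           [--n-orient N] [--seed S] --out F\n",
      "  metatraj --map corr.tsv --traj S:TAG:LIG [--traj ...] --out F\n",
      sep = "")
}

.cliArgs <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        val <- args[i + 1L]
        if (key %in% names(out)) out[[key]] <- c(out[[key]], val)
        else out[[key]] <- val
        i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else { out[["_positional"]] <- c(out[["_positional"]], a); i <- i + 1L }
  }
  out
}

.cliLoad <- function(opt) {
  if (is.null(opt$structure) || !file.exists(opt$structure))
    stop("missing --structure input", call. = FALSE)
  traj <- loadTrajectory(opt$structure, opt$traj)
  n <- as.integer(opt$`discard-frames` %||% 0)
  if (n > 0) subsetFrames(traj, (n + 1L):nFrames(traj)) else traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches the \code{hingescan} subcommands (see the \code{exec}
#' script shipped with the package). Returns an exit status instead of
#' quitting so it can be tested in-process: 0 on success, 2 on bad
#' arguments or missing input.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { .cliUsage(); return(2L) }
  sub <- args[1]
  opt <- .cliArgs(args[-1])
  status <- tryCatch({
    switch(sub,
      pipeline = {
        cfg <- .readConfig(opt$config %||% stop("--config required",
                                                call. = FALSE))
        if (!is.null(opt$out)) cfg$outputDir <- opt$out
        if (isTRUE(opt$force)) cfg$force <- TRUE
        runPipeline(cfg)
        0L
      },
      synth = {
        spec <- .specFromList(yaml::read_yaml(
          opt$spec %||% stop("--spec required", call. = FALSE)))
        gen <- generateTrajectory(spec)
        prefix <- opt$`out-prefix` %||% "toy"
        writeTrajectory(gen$trajectory, paste0(prefix, ".pdb"))
        jsonlite::write_json(gen$truth[c("assignment", "interface")],
                             paste0(prefix, "_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      dfmat = {
        traj <- .cliLoad(opt)
        writeFluctuationTsv(distanceFluctuationMatrix(traj),
                            opt$out %||% "dfmat.tsv")
        0L
      },
      strain = {
        traj <- .cliLoad(opt)
        prof <- if (is.null(opt$`window-frames`))
          strainProfile(traj, as.numeric(opt$cutoff %||% 5),
                        as.numeric(opt$width %||% 0.5))
        else strainTimeResolved(traj, as.integer(opt$`window-frames`),
                                as.numeric(opt$cutoff %||% 5),
                                as.numeric(opt$width %||% 0.5))
        writeStrainTsv(prof, opt$out %||% "strain.tsv")
        0L
      },
      qrd = {
        traj <- .cliLoad(opt)
        sp <- searchPartition(traj, as.integer(opt$q %||% 3),
                              seed = as.integer(opt$seed %||% 1))
        writePartitionJson(sp$fit, opt$out %||% "partition.json",
                           seed = as.integer(opt$seed %||% 1))
        0L
      },
      axisfit = {
        traj <- .cliLoad(opt)
        pj <- jsonlite::read_json(
          opt$partition %||% stop("--partition required", call. = FALSE),
          simplifyVector = TRUE)
        part <- Partition(pj$assignment, pj$q)
        axes <- fitAllHinges(traj, part,
                             as.integer(opt$core %||% 1),
                             nOrientations =
                               as.integer(opt$`n-orient` %||% 500),
                             seed = as.integer(opt$seed %||% 1))
        writeAxesJson(axes, opt$out %||% "axes.json", traj = traj)
        0L
      },
      metatraj = {
        tab <- loadCorrespondence(
          opt$map %||% stop("--map required", call. = FALSE))
        entries <- lapply(opt$traj, function(s) {
          parts <- strsplit(s, ":", fixed = TRUE)[[1]]
          if (!file.exists(parts[1]))
            stop("missing input: ", parts[1], call. = FALSE)
          list(trajectory = loadTrajectory(parts[1],
                                           proteinTag = parts[2]),
               proteinTag = parts[2],
               ligandState = if (length(parts) >= 3) parts[3] else "none")
        })
        meta <- buildMetaTrajectory(entries, tab)
        writeTrajectory(meta, opt$out %||% "metatraj.pdb")
        0L
      },
      { .cliUsage(); 2L })
  }, error = function(e) {
    message("hingescan: ", conditionMessage(e))
    2L
  })
  status
}

#' Keep a subset of frames
#'
#' @param traj a \linkS4class{CalphaTrajectory}.
#' @param frames integer frame indices to keep (in order).
#' @return the reduced trajectory (frame times are preserved when
#'   present).
#' @export
subsetFrames <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nFrames(traj)))
    stop("frame indices out of bounds", call. = FALSE)
  ft <- frameTimes(traj)
  coords <- trajCoords(traj)[frames, , , drop = FALSE]
  times <- if (length(ft)) ft[frames] else numeric(0)
  if (is(traj, "MetaTrajectory"))
    new("MetaTrajectory", coords = coords, residueIds = residueIds(traj),
        frameTimes = times, source = traj@source,
        frameProvenance = frameProvenance(traj)[frames, , drop = FALSE])
  else
    new("CalphaTrajectory", coords = coords,
        residueIds = residueIds(traj), frameTimes = times,
        source = traj@source)
}
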