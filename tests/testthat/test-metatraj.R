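makeTable <- function(nGroups, tags) {
  do.call(rbind, lapply(tags, function(t)
    data.frame(groupId = seq_len(nGroups), proteinTag = t, chain = "A",
               resno = seq_len(nGroups), stringsAsFactors = FALSE)))
}

test_that("correspondence tables validate, drop incomplete groups and round-trip", {
  tb <- makeTable(10, c("p1", "p2", "p3"))
  ct <- CorrespondenceTable(tb)
  expect_equal(length(unique(ct@table$groupId)), 10L)

  # one group missing one protein: dropped with a message
  expect_message(ct2 <- CorrespondenceTable(
    tb[!(tb$groupId == 4 & tb$proteinTag == "p2"), ]), "incomplete")
  expect_equal(sort(unique(ct2@table$groupId)), setdiff(1:10, 4))

  # duplicate residue assignment is a hard error with row numbers
  bad <- rbind(tb, data.frame(groupId = 99, proteinTag = "p1",
                              chain = "A", resno = 3))
  expect_error(CorrespondenceTable(bad), "row")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeCorrespondence(ct, path)
  back <- loadCorrespondence(path)
  expect_equal(back@table, ct@table)
})

test_that("meta-trajectory assembles blocks with provenance and exact coordinates", {
  t1 <- randomTrajectory(5, 20, seed = 85)
  t2 <- randomTrajectory(5, 20, seed = 87)
  t1@residueIds$proteinTag <- "p1"
  t2@residueIds$proteinTag <- "p2"
  ct <- CorrespondenceTable(makeTable(20, c("p1", "p2")))
  meta <- buildMetaTrajectory(list(
    list(trajectory = t1, proteinTag = "p1", ligandState = "ATP"),
    list(trajectory = t2, proteinTag = "p2", ligandState = "ADP")), ct)
  expect_equal(nFrames(meta), 10L)
  expect_equal(nResidues(meta), 20L)
  expect_equal(trajCoords(meta)[1:5, , ], trajCoords(t1))
  expect_equal(trajCoords(meta)[6:10, , ], trajCoords(t2))
  expect_equal(frameProvenance(meta)$proteinTag,
               rep(c("p1", "p2"), each = 5))

  # single source + identity table: bit-identical coordinates
  meta1 <- buildMetaTrajectory(list(list(trajectory = t1,
                                         proteinTag = "p1")),
                               CorrespondenceTable(makeTable(20, "p1")))
  expect_identical(trajCoords(meta1), trajCoords(t1))

  # residues referenced but absent are a hard error
  ct25 <- CorrespondenceTable(makeTable(25, c("p1", "p2")))
  expect_error(buildMetaTrajectory(list(
    list(trajectory = t1, proteinTag = "p1"),
    list(trajectory = t2, proteinTag = "p2")), ct25), "absent")
})

test_that("pooled fluctuations on a meta-trajectory match brute-force pooled variance", {
  t1 <- randomTrajectory(6, 12, seed = 89)
  t2 <- randomTrajectory(4, 12, seed = 91)
  t1@residueIds$proteinTag <- "p1"
  t2@residueIds$proteinTag <- "p2"
  ct <- CorrespondenceTable(makeTable(12, c("p1", "p2")))
  meta <- buildMetaTrajectory(list(
    list(trajectory = t1, proteinTag = "p1"),
    list(trajectory = t2, proteinTag = "p2")), ct)
  A <- fluctuationValues(distanceFluctuationMatrix(meta))
  pooledCoords <- array(NA_real_, c(10, 12, 3))
  pooledCoords[1:6, , ] <- trajCoords(t1)
  pooledCoords[7:10, , ] <- trajCoords(t2)
  expect_lt(max(abs(A - oracleDfm(pooledCoords))), 1e-12)
})

test_that("input order permutes frame blocks but not per-source results", {
  t1 <- randomTrajectory(5, 10, seed = 93)
  t2 <- randomTrajectory(7, 10, seed = 95)
  t1@residueIds$proteinTag <- "p1"
  t2@residueIds$proteinTag <- "p2"
  ct <- CorrespondenceTable(makeTable(10, c("p1", "p2")))
  m12 <- buildMetaTrajectory(list(list(trajectory = t1, proteinTag = "p1"),
                                  list(trajectory = t2, proteinTag = "p2")),
                             ct)
  m21 <- buildMetaTrajectory(list(list(trajectory = t2, proteinTag = "p2"),
                                  list(trajectory = t1, proteinTag = "p1")),
                             ct)
  A12 <- fluctuationValues(distanceFluctuationMatrix(m12))
  A21 <- fluctuationValues(distanceFluctuationMatrix(m21))
  expect_equal(A12, A21, tolerance = 1e-12)
  p1Frames12 <- which(frameProvenance(m12)$proteinTag == "p1")
  p1Frames21 <- which(frameProvenance(m21)$proteinTag == "p1")
  expect_equal(trajCoords(m12)[p1Frames12, , ],
               trajCoords(m21)[p1Frames21, , ])
})

test_that("per-source fit reports group rmsd correctly and recombine", {
  t1 <- randomTrajectory(4, 10, seed = 97)
  t2 <- randomTrajectory(4, 10, seed = 99)
  t1@residueIds$proteinTag <- "p1"
  t2@residueIds$proteinTag <- "p2"
  ct <- CorrespondenceTable(makeTable(10, c("p1", "p2")))
  meta <- buildMetaTrajectory(list(
    list(trajectory = t1, proteinTag = "p1", ligandState = "ATP"),
    list(trajectory = t2, proteinTag = "p2", ligandState = "ADP")), ct)
  fake <- new("HingeAxisSet", axes = list(), coreDomain = 1L,
              combinedCapturedFraction = 0.5, residualMsf = 1,
              perFrameRmsd = c(3, 5, 3, 5, 2, 2, 2, 2))
  rep1 <- perSourceFitReport(meta, fake, threshold = 4)
  expect_equal(rep1$fracWithin[rep1$proteinTag == "p1"], 0.5)
  expect_equal(rep1$meanRmsd[rep1$proteinTag == "p2"], 2)
  expect_equal(rep1$maxRmsd[rep1$proteinTag == "overall"], 5)
  # group-weighted means recombine to the overall mean
  bySource <- rep1[rep1$proteinTag != "overall", ]
  expect_equal(sum(bySource$meanRmsd * bySource$nFrames) /
                 sum(bySource$nFrames),
               rep1$meanRmsd[rep1$proteinTag == "overall"])
  # frame-count mismatch is a hard error
  short <- new("HingeAxisSet", axes = list(), coreDomain = 1L,
               combinedCapturedFraction = 0.5, residualMsf = 1,
               perFrameRmsd = c(3, 5))
  expect_error(perSourceFitReport(meta, short), "frame count")
})
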