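test_that("zero noise and zero angles give identical frames", {
  gen <- generateTrajectory(SyntheticSpec(c(10, 10),
    hinges = list(list(moving = 2, core = 1,
                       angles = rep(0, 5))), nFrames = 5, seed = 117))
  coords <- trajCoords(gen$trajectory)
  for (f in 2:5) expect_identical(coords[f, , ], coords[1, , ])
  expect_identical(coords[1, , ], gen$truth$reference)
})

test_that("generation is deterministic given the spec", {
  spec <- SyntheticSpec(c(15, 15),
    hinges = list(list(moving = 2, core = 1)), nFrames = 6, seed = 119)
  g1 <- generateTrajectory(spec)
  g2 <- generateTrajectory(spec)
  expect_identical(trajCoords(g1$trajectory), trajCoords(g2$trajectory))
  expect_identical(g1$truth$assignment, g2$truth$assignment)
})

test_that("planted angles close the loop with the fixed-axis angle solver", {
  angles <- c(0, 10, 20)
  gen <- generateTrajectory(SyntheticSpec(c(12, 12),
    hinges = list(list(moving = 2, core = 1, angles = angles)),
    nFrames = 3, seed = 121))
  truth <- gen$truth$hinges[[1]]
  movIdx <- which(gen$truth$assignment == 2)
  ref <- gen$truth$reference
  for (f in 1:3) {
    th <- optimalAngle(ref[movIdx, ],
                       trajCoords(gen$trajectory)[f, movIdx, ],
                       truth$axisPoint, truth$orientation)
    expect_equal(th, angles[f], tolerance = 1e-6)
  }
})

test_that("reference packing and interface structure are as declared", {
  gen <- generateTrajectory(SyntheticSpec(c(25, 20, 25),
    hinges = list(list(moving = 1, core = 2),
                  list(moving = 3, core = 2)), nFrames = 4, seed = 123))
  ref <- gen$truth$reference
  a <- gen$truth$assignment
  dm <- as.matrix(dist(ref))
  diag(dm) <- Inf
  expect_gte(min(dm), 3.5)
  cross <- outer(a, a, "!=")
  # declared interface = exactly the residues with a cross neighbour < 5
  expect_identical(gen$truth$interface,
                   which(apply(dm < 5 & cross, 1, any)))
  # contact-gap: non-interface residues have no cross pair below 7.5 A
  nonIf <- setdiff(seq_along(a), gen$truth$interface)
  expect_gte(min(dm[nonIf, ][cross[nonIf, ]]), 7.5)
  # block structure: intra-domain fluctuations ~0, cross-domain > 0
  A <- fluctuationValues(distanceFluctuationMatrix(gen$trajectory))
  expect_lt(max(A[!cross]), 1e-10)
  expect_gt(max(A[cross]), 0.1)
})

test_that("coordinate noise has the requested variance", {
  gen <- generateTrajectory(SyntheticSpec(c(10, 10), noiseSigma = 0.5,
                                          nFrames = 2000, seed = 125))
  coords <- trajCoords(gen$trajectory)
  v <- mean(apply(coords, c(2, 3), var))
  expect_equal(v, 0.25, tolerance = 0.05 * 0.25)
})

test_that("impossible geometry and undersized specs fail hard", {
  expect_error(SyntheticSpec(c(2, 10)), ">= 3")
  expect_error(generateTrajectory(
    SyntheticSpec(c(40, 40), scale = 0.3, nFrames = 2, seed = 1)),
    "placement attempts")
  expect_error(generateTrajectory(SyntheticSpec(c(3, 3, 3),
    nFrames = 2, seed = 1)), "too small")
})

test_that("synthetic correspondence tables map shared residues and validate", {
  specs <- list(SyntheticSpec(c(20, 20), seed = 1, tag = "a"),
                SyntheticSpec(c(20, 20), seed = 2, tag = "b"))
  ct <- makeCorrespondence(specs, overlapFraction = 1)
  expect_equal(length(unique(ct@table$groupId)), 40L)
  ct8 <- makeCorrespondence(specs, overlapFraction = 0.8)
  expect_equal(length(unique(ct8@table$groupId)), 32L)
  # the table passes the loader round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCorrespondence(ct8, path)
  expect_equal(loadCorrespondence(path)@table, ct8@table)
  expect_error(makeCorrespondence(
    list(SyntheticSpec(c(20, 20)), SyntheticSpec(c(20, 21)))),
    "share domain counts")
  expect_error(makeCorrespondence(specs, overlapFraction = 0.05),
               "fewer than 3")
})
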