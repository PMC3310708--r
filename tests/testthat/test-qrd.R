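# shared planted fixtures (built once per test file run)
threeBody <- generateTrajectory(SyntheticSpec(c(25, 20, 25),
  hinges = list(list(moving = 1, core = 2), list(moving = 3, core = 2)),
  nFrames = 40, seed = 101))

test_that("the reference frame is the conformation closest to the mean", {
  # constructed case: the mean structure itself is one of the frames
  set.seed(61)
  base <- matrix(rnorm(12 * 3, sd = 6), 12, 3)
  delta <- matrix(rnorm(12 * 3, sd = 1), 12, 3)
  coords <- array(NA_real_, c(3, 12, 3))
  coords[1, , ] <- base + delta
  coords[2, , ] <- base
  coords[3, , ] <- base - delta
  expect_equal(selectReference(CalphaTrajectory(coords)), 2L)

  # brute-force scan on a random trajectory
  traj <- randomTrajectory(10, 15, seed = 63, spread = 6)
  ref <- selectReference(traj)
  # independent check: superpose all frames onto frame `ref`, compute the
  # mean, and confirm `ref` has the smallest rmsd to an iterated mean
  cube <- aperm(trajCoords(traj), c(2, 3, 1))
  m <- cube[, , 1]
  for (it in 1:50) {
    sup <- lapply(1:10, function(f) {
      k <- kabschFit(cube[, , f], m)
      sweep(cube[, , f] %*% t(k$rotation), 2, as.numeric(k$translation),
            "+")
    })
    m <- Reduce(`+`, sup) / 10
  }
  rmsd <- vapply(sup, function(x) sqrt(mean(rowSums((x - m)^2))),
                 numeric(1))
  expect_equal(ref, which.min(rmsd))

  # duplicating frames does not change the selected structure
  doubled <- CalphaTrajectory(trajCoords(traj)[rep(1:10, 2), , ],
                              residueIds(traj))
  refD <- selectReference(doubled)
  expect_equal((refD - 1L) %% 10L + 1L, ref)
})

test_that("rigid fit is exact on planted rigid bodies and pins degenerate cases", {
  # single-domain partition of a globally rigid trajectory
  base <- randomTrajectory(1, 12, seed = 67)
  rigid <- randomlyRotateFrames(CalphaTrajectory(
    array(rep(trajCoords(base)[1, , ], each = 6), c(6, 12, 3))),
    seed = 7)
  fit <- fitRigidDomains(rigid, Partition(rep(1L, 12)), 1L)
  expect_lt(residualMsf(fit), 1e-12)
  expect_equal(capturedFraction(fit), 1)

  # planted three-body trajectory: true partition fits exactly
  fitT <- fitRigidDomains(threeBody$trajectory,
                          Partition(threeBody$truth$assignment))
  expect_lt(residualMsf(fitT), 1e-10)
  expect_gte(capturedFraction(fitT), 0.999)

  # a deliberately wrong partition (splitting a planted body) fits worse
  wrong <- threeBody$truth$assignment
  wrong[which(wrong == 1L)[1:8]] <- 2L
  fitW <- fitRigidDomains(threeBody$trajectory, Partition(wrong),
                          fitT@referenceFrame)
  expect_gt(residualMsf(fitW), residualMsf(fitT))

  # all rotations proper orthogonal; rmsd consistent with the residual
  rots <- fitT@rotations
  for (k in seq_len(dim(rots)[3])) {
    expect_lt(max(abs(crossprod(rots[, , k]) - diag(3))), 1e-8)
    expect_gt(det(rots[, , k]), 0)
  }
  expect_equal(mean(perFrameRmsd(fitT)^2), 3 * residualMsf(fitT),
               tolerance = 1e-10)
})

test_that("rigid fit rejects undersized or collinear domains", {
  traj <- randomTrajectory(6, 10, seed = 71)
  expect_error(Partition(c(rep(1L, 8), 2L, 2L)), ">= 3")
  coords <- trajCoords(traj)
  coords[, 8:10, 2:3] <- 0  # residues 8-10 collinear along x
  collinear <- CalphaTrajectory(coords)
  expect_error(
    fitRigidDomains(collinear, Partition(c(rep(1L, 7), rep(2L, 3))), 1L),
    "collinear")
})

test_that("fit residual matches the independent Kabsch oracle", {
  traj <- randomTrajectory(7, 14, seed = 73)
  assign <- rep(c(1L, 2L), each = 7)
  fit <- fitRigidDomains(traj, Partition(assign), 2L)
  expect_equal(fit@rawSse,
               oraclePartitionSse(trajCoords(traj), assign, 2L),
               tolerance = 1e-9)
})

test_that("essential-dynamics seeding recovers planted splits", {
  gen <- generateTrajectory(SyntheticSpec(c(30, 30),
    hinges = list(list(moving = 2, core = 1)), nFrames = 25, seed = 103))
  init <- initialPartition(gen$trajectory, 2)
  expect_gte(randIndex(domainAssignment(init), gen$truth$assignment), 0.9)
  # deterministic
  init2 <- initialPartition(gen$trajectory, 2)
  expect_identical(domainAssignment(init), domainAssignment(init2))
  # rigid input has no essential space
  rigidBase <- randomTrajectory(1, 15, seed = 77)
  rigid <- CalphaTrajectory(array(rep(trajCoords(rigidBase)[1, , ],
                                      each = 8), c(8, 15, 3)))
  expect_error(initialPartition(rigid, 2), "rigid")
})

test_that("oversplitting does not straddle planted bodies (noiseless)", {
  init <- initialPartition(threeBody$trajectory, 4)
  truth <- threeBody$truth$assignment
  fit <- fitRigidDomains(threeBody$trajectory, init)
  # every returned domain must lie within one planted body, which is
  # equivalent to an (almost) exact fit surviving the split
  purity <- vapply(1:4, function(l) {
    members <- truth[domainAssignment(init) == l]
    max(table(members)) / length(members)
  }, numeric(1))
  expect_true(all(purity == 1))
})

test_that("stochastic search recovers the planted three-body partition", {
  sp <- searchPartition(threeBody$trajectory, 3, seed = 5)
  expect_equal(randIndex(domainAssignment(sp$partition),
                         threeBody$truth$assignment), 1.0)
  expect_lt(residualMsf(sp$fit), 1e-10)
  # determinism given the seed
  sp2 <- searchPartition(threeBody$trajectory, 3, seed = 5)
  expect_identical(domainAssignment(sp$partition),
                   domainAssignment(sp2$partition))
})

test_that("q = 1 short-circuits to the trivial partition", {
  sp <- searchPartition(threeBody$trajectory, 1)
  expect_equal(nDomains(sp$partition), 1L)
  expect_equal(capturedFraction(sp$fit), 0)
})

test_that("search matches exhaustive enumeration on a small instance", {
  gen <- generateTrajectory(SyntheticSpec(c(6, 6),
    hinges = list(list(moving = 2, core = 1)), nFrames = 8, seed = 105))
  coords <- trajCoords(gen$trajectory)
  refFrame <- selectReference(gen$trajectory)
  best <- Inf
  for (a in allTwoPartitions(12)) {
    s <- oraclePartitionSse(coords, a, refFrame)
    if (s < best) best <- s
  }
  sp <- searchPartition(gen$trajectory, 2, seed = 3)
  expect_lt(abs(sp$fit@rawSse - best), 1e-9)
})

test_that("captured fraction is non-decreasing over a warm-started q scan", {
  scan <- scanQ(threeBody$trajectory, 1:4, seed = 9)
  expect_true(all(diff(scan$capturedFraction) >= -1e-12))
  # three planted bodies: the gain collapses beyond q = 3
  expect_gt(scan$capturedFraction[3] - scan$capturedFraction[2], 0.05)
  expect_lt(scan$capturedFraction[4] - scan$capturedFraction[3], 0.05)
  expect_equal(attr(scan, "suggestedQ"), 3L)
})
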