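test_that("hand-computed pair variance is reproduced", {
  # two residues, distances 3 A then 5 A: population variance 1.0
  coords <- array(0, c(2, 2, 3))
  coords[1, 2, 1] <- 3
  coords[2, 2, 1] <- 5
  A <- fluctuationValues(distanceFluctuationMatrix(
    CalphaTrajectory(coords)))
  expect_equal(A[1, 2], 1.0, tolerance = 1e-12)
  expect_equal(A[2, 1], 1.0, tolerance = 1e-12)
  expect_equal(diag(A), c(0, 0))
})

test_that("fluctuation matrix matches the brute-force double loop", {
  traj <- randomTrajectory(20, 50, seed = 7)
  A <- fluctuationValues(distanceFluctuationMatrix(traj))
  expect_lt(max(abs(A - oracleDfm(trajCoords(traj)))), 1e-12)
})

test_that("rigid global motion yields a zero matrix", {
  base <- randomTrajectory(1, 25, seed = 9)
  rigid <- randomlyRotateFrames(CalphaTrajectory(
    array(rep(trajCoords(base)[1, , ], each = 12), c(12, 25, 3))),
    seed = 2)
  A <- fluctuationValues(distanceFluctuationMatrix(rigid))
  expect_lt(max(abs(A)), 1e-10)
})

test_that("matrix is invariant under per-frame roto-translations", {
  traj <- randomTrajectory(15, 30, seed = 11)
  moved <- randomlyRotateFrames(traj, seed = 13)
  A1 <- fluctuationValues(distanceFluctuationMatrix(traj))
  A2 <- fluctuationValues(distanceFluctuationMatrix(moved))
  expect_lt(max(abs(A1 - A2)), 1e-10)
})

test_that("duplicating all frames leaves the matrix unchanged", {
  traj <- randomTrajectory(8, 15, seed = 17)
  doubled <- CalphaTrajectory(trajCoords(traj)[rep(1:8, 2), , ],
                              residueIds(traj))
  A1 <- fluctuationValues(distanceFluctuationMatrix(traj))
  A2 <- fluctuationValues(distanceFluctuationMatrix(doubled))
  expect_lt(max(abs(A1 - A2)), 1e-12)
})

test_that("frame ranges are honoured and validated", {
  traj <- randomTrajectory(10, 12, seed = 19)
  sub <- CalphaTrajectory(trajCoords(traj)[3:7, , ], residueIds(traj))
  A1 <- fluctuationValues(distanceFluctuationMatrix(traj, c(3, 7)))
  A2 <- fluctuationValues(distanceFluctuationMatrix(sub))
  expect_equal(A1, A2, tolerance = 1e-14)
  expect_error(distanceFluctuationMatrix(traj, c(5, 11)), "outside")
  expect_error(distanceFluctuationMatrix(traj, c(4, 4)), "at least 2")
})

test_that("block summaries equal explicit double-loop means", {
  # hand case: 3x3 with off-diagonal entries 1, 2, 3
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 1; v[1, 3] <- v[3, 1] <- 2
  v[2, 3] <- v[3, 2] <- 3
  dfm <- new("DistanceFluctuationMatrix", values = v,
             meanDistances = matrix(5, 3, 3),
             residueIds = data.frame(proteinTag = "p", chain = "A",
                                     resno = 1:3, resname = "ALA"),
             frameRange = c(1L, 2L))
  expect_equal(blockSummary(dfm, c(1, 3), c(1, 3)), 2.0)
  expect_equal(blockSummary(dfm, 1, c(2, 3)), 1.5)

  traj <- randomTrajectory(12, 20, seed = 23)
  dfm2 <- distanceFluctuationMatrix(traj)
  a <- 4:11; b <- 9:17
  acc <- c()
  for (i in a) for (j in b)
    if (i != j) acc <- c(acc, fluctuationValues(dfm2)[i, j])
  expect_equal(blockSummary(dfm2, range(a), range(b)), mean(acc),
               tolerance = 1e-12)
  expect_error(blockSummary(dfm2, c(25, 30), c(1, 2)), "out-of-bounds")
})

test_that("minimum-distance series matches exhaustive enumeration", {
  # constant 4 A pair
  coords <- array(0, c(3, 2, 3)); coords[, 2, 2] <- 4
  ds <- minDistanceSeries(CalphaTrajectory(coords), "resid:1", "resid:2")
  expect_equal(ds@perFrameMin, rep(4, 3))
  expect_equal(ds@averageValue, 4)
  expect_equal(ds@finalValue, 4)

  # hand-enumerated two-frame case: pairs {2,5} then {7,3}
  coords <- array(0, c(2, 3, 3))
  coords[1, 2, 1] <- 2; coords[1, 3, 1] <- 5
  coords[2, 2, 1] <- 7; coords[2, 3, 1] <- 3
  ds2 <- minDistanceSeries(CalphaTrajectory(coords), "resid:1",
                           "resid:2-3")
  expect_equal(ds2@perFrameMin, c(2, 3))
  expect_equal(ds2@averageValue, 2.5)

  traj <- randomTrajectory(10, 13, seed = 29)
  ds3 <- minDistanceSeries(traj, "resid:1-5", "resid:6-13")
  expect_equal(ds3@perFrameMin,
               oracleMinDist(trajCoords(traj), 1:5, 6:13),
               tolerance = 1e-12)
  # permutation invariance within selections
  sel <- new("AtomSelection", expression = "", indices = 1:5)
  expect_equal(minDistanceSeries(traj, sel, "resid:6-13")@perFrameMin,
               ds3@perFrameMin)
  expect_error(minDistanceSeries(traj, "resid:1-6", "resid:6-13"),
               "overlap")
})
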