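test_that("logistic weight has the pinned midpoint, limits and monotonicity", {
  expect_equal(sigmoidWeight(5), 0.5)
  expect_equal(sigmoidWeight(0), 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_gt(sigmoidWeight(0), 0.99)
  grid <- sigmoidWeight(seq(0, 20, by = 0.05))
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 0 & grid < 1))
  expect_equal(sigmoidWeight(7, cutoff = 7, width = 2), 0.5)
  expect_error(sigmoidWeight(-1), "x >= 0")
})

test_that("strain matches the brute-force double loop", {
  traj <- randomTrajectory(12, 30, seed = 31)
  p <- strainValues(strainProfile(traj))
  expect_lt(max(abs(p - oracleStrain(trajCoords(traj)))), 1e-12)
})

test_that("pure rigid motion carries zero strain", {
  base <- randomTrajectory(1, 20, seed = 33)
  rigid <- randomlyRotateFrames(CalphaTrajectory(
    array(rep(trajCoords(base)[1, , ], each = 10), c(10, 20, 3))),
    seed = 4)
  expect_lt(max(strainValues(strainProfile(rigid))), 1e-10)
})

test_that("strain is invariant under per-frame roto-translations", {
  traj <- randomTrajectory(10, 25, seed = 37)
  moved <- randomlyRotateFrames(traj, seed = 5)
  expect_lt(max(abs(strainValues(strainProfile(traj)) -
                    strainValues(strainProfile(moved)))), 1e-10)
})

test_that("narrow width approaches a hard distance cutoff", {
  traj <- randomTrajectory(10, 20, seed = 41)
  p <- strainValues(strainProfile(traj, width = 1e-3))
  # hard-cutoff oracle on the mean-distance matrix
  A <- oracleDfm(trajCoords(traj))
  nf <- 10; n <- 20
  meanD <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- vapply(1:nf, function(f)
      sqrt(sum((trajCoords(traj)[f, i, ] - trajCoords(traj)[f, j, ])^2)),
      numeric(1))
    meanD[i, j] <- meanD[j, i] <- mean(d)
  }
  hard <- vapply(1:n, function(i)
    sum(A[i, meanD[i, ] < 5 & seq_len(n) != i]), numeric(1))
  expect_equal(p, hard, tolerance = 1e-6)
})

test_that("strain localizes at the planted domain interface", {
  gen <- generateTrajectory(SyntheticSpec(c(40, 40),
    hinges = list(list(moving = 2, core = 1)), nFrames = 30, seed = 8))
  p <- strainValues(strainProfile(gen$trajectory))
  top5 <- order(p, decreasing = TRUE)[1:5]
  expect_true(all(top5 %in% gen$truth$interface))
  expect_gt(mean(p[gen$truth$interface]),
            3 * mean(p[-gen$truth$interface]))
})

test_that("a single window spanning all frames reproduces the plain profile", {
  traj <- randomTrajectory(12, 15, seed = 43)
  win <- strainTimeResolved(traj, windowFrames = 12)
  expect_equal(nrow(win@perWindow), 1L)
  expect_equal(as.numeric(win@perWindow[1, ]),
               strainValues(strainProfile(traj)), tolerance = 1e-14)
})

test_that("windows on a rigid trajectory are all zero", {
  base <- randomTrajectory(1, 15, seed = 47)
  rigid <- randomlyRotateFrames(CalphaTrajectory(
    array(rep(trajCoords(base)[1, , ], each = 12), c(12, 15, 3))),
    seed = 6)
  win <- strainTimeResolved(rigid, windowFrames = 3)
  expect_equal(nrow(win@perWindow), 4L)
  expect_lt(max(win@perWindow), 1e-10)
})

test_that("windows of a stationary trajectory agree with each other", {
  # stationary fluctuation: fixed structure plus i.i.d. noise
  set.seed(51)
  base <- matrix(rnorm(20 * 3, sd = 8), 20, 3)
  coords <- array(NA_real_, c(80, 20, 3))
  for (f in 1:80) coords[f, , ] <- base + matrix(rnorm(60, sd = 0.4), 20, 3)
  win <- strainTimeResolved(CalphaTrajectory(coords), windowFrames = 20)
  expect_equal(nrow(win@perWindow), 4L)
  m <- colMeans(win@perWindow)
  se <- apply(win@perWindow, 2, sd) / sqrt(4)
  expect_true(all(abs(sweep(win@perWindow, 2, m)) <= 3.5 * rep(se,
              each = 4) + 1e-12))
  expect_error(strainTimeResolved(CalphaTrajectory(coords),
                                  windowFrames = 81), "windowFrames")
})
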