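singleHinge <- generateTrajectory(SyntheticSpec(c(30, 35),
  hinges = list(list(moving = 2, core = 1,
                     orientation = c(0.3, -0.5, 0.81))),
  nFrames = 40, seed = 107))

# sign- and offset-aligned maximum angle discrepancy: fitted angles are
# relative to the reference conformation, planted schedules to the
# generation reference
angleError <- function(ax, truth, refFrame) {
  expected <- truth$angles - truth$angles[refFrame]
  min(max(abs(frameAngles(ax) - expected)),
      max(abs(frameAngles(ax) + expected)))
}

test_that("sampled orientations are unit, reproducible and balanced", {
  u <- sampleOrientations(200, seed = 13)
  expect_equal(sqrt(rowSums(u^2)), rep(1, 200), tolerance = 1e-12)
  expect_identical(u, sampleOrientations(200, seed = 13))
  big <- sampleOrientations(10000, seed = 17)
  expect_lt(sqrt(sum(colMeans(big)^2)), 0.05)
})

test_that("closed-form optimal angle matches planted rotations and the grid oracle", {
  set.seed(83)
  P <- matrix(rnorm(30, sd = 6), 10, 3)
  anchor <- c(1, -2, 0.5)
  u <- c(2, -1, 0.3); u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  rot <- function(th) diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  planted <- sweep(sweep(P, 2, anchor) %*% t(rot(25 * pi / 180)), 2,
                   anchor, "+")
  expect_equal(optimalAngle(P, planted, anchor, u), 25, tolerance = 1e-6)
  expect_equal(optimalAngle(P, P, anchor, u), 0)

  # randomly perturbed targets against the 0.01-degree grid search
  for (case in 1:3) {
    Q <- planted + matrix(rnorm(30, sd = 0.8), 10, 3)
    expect_equal(optimalAngle(P, Q, anchor, u),
                 oracleAngleGrid(P, Q, anchor, u), tolerance = 0.011)
  }

  # all points on the axis: angle undefined
  onAxis <- outer(seq(-2, 2, length.out = 5), u) +
    matrix(anchor, 5, 3, byrow = TRUE)
  expect_error(optimalAngle(onAxis, onAxis, anchor, u), "undefined")
})

test_that("exhaustive small-instance scan equals an independent reimplementation", {
  gen <- generateTrajectory(SyntheticSpec(c(4, 4),
    hinges = list(list(moving = 2, core = 1)), nFrames = 6, seed = 109))
  traj <- gen$trajectory
  part <- Partition(gen$truth$assignment)
  refFrame <- selectReference(traj)
  ref <- trajCoords(traj)[refFrame, , ]
  coreIdx <- which(gen$truth$assignment == 1)
  movIdx <- which(gen$truth$assignment == 2)
  # core-fixed frames via the public Kabsch helper
  sup <- lapply(1:6, function(f) {
    X <- trajCoords(traj)[f, , ]
    k <- kabschFit(X[coreIdx, ], ref[coreIdx, ])
    sweep(X %*% t(k$rotation), 2, as.numeric(k$translation), "+")
  })
  orients <- sampleOrientations(50, seed = 19)
  anchors <- 1:5
  best <- Inf
  for (a in anchors) for (o in seq_len(nrow(orients))) {
    sse <- 0
    for (f in 1:6) {
      th <- tryCatch(optimalAngle(ref[movIdx, ], sup[[f]][movIdx, ],
                                  ref[a, ], orients[o, ]),
                     error = function(e) 0)
      K <- orients[o, ]
      Km <- matrix(c(0, K[3], -K[2], -K[3], 0, K[1], K[2], -K[1], 0),
                   3, 3)
      R <- diag(3) + sin(th * pi / 180) * Km +
        (1 - cos(th * pi / 180)) * (Km %*% Km)
      pred <- sweep(sweep(ref[movIdx, ], 2, ref[a, ]) %*% t(R), 2,
                    ref[a, ], "+")
      sse <- sse + sum((pred - sup[[f]][movIdx, ])^2)
    }
    if (sse < best) best <- sse
  }
  scan <- hingescan:::.cpp_axis_scan(ref[movIdx, ],
    aperm(array(unlist(lapply(sup, function(x) x[movIdx, ])),
                c(4, 3, 6)), c(1, 2, 3)),
    ref[anchors, ], orients)
  expect_equal(scan$sse, best, tolerance = 1e-8)
})

test_that("a planted fixed-axis hinge is recovered accurately", {
  part <- Partition(singleHinge$truth$assignment)
  ax <- fitFixedAxis(singleHinge$trajectory, part, core = 1, moving = 2,
                     nOrientations = 500, seed = 21)
  truth <- singleHinge$truth$hinges[[1]]
  expect_lt(orientationError(axisOrientation(ax), truth$orientation), 2)
  refFrame <- selectReference(singleHinge$trajectory)
  expect_lt(angleError(ax, truth, refFrame), 0.5)
  expect_gte(capturedFraction(ax), 0.99)
  # the discrete-scan result is also reported and is no better
  expect_gte(ax@discreteResidualMsf, residualMsf(ax) - 1e-12)
})

test_that("axis recovery improves with the orientation budget", {
  part <- Partition(singleHinge$truth$assignment)
  truth <- singleHinge$truth$hinges[[1]]
  errs <- vapply(c(50, 500, 5000), function(n) {
    ax <- fitFixedAxis(singleHinge$trajectory, part, 1, 2,
                       nOrientations = n, seed = 23, refine = FALSE)
    orientationError(ax@discreteOrientation, truth$orientation)
  }, numeric(1))
  expect_true(errs[3] <= errs[1] + 1e-9)
  expect_true(errs[2] <= errs[1] + 1e-9)
})

test_that("a static moving domain is flagged degenerate", {
  gen <- generateTrajectory(SyntheticSpec(c(20, 20), nFrames = 10,
                                          seed = 111))
  part <- Partition(gen$truth$assignment)
  expect_warning(ax <- fitFixedAxis(gen$trajectory, part, 1, 2,
                                    nOrientations = 50, seed = 25),
                 "static")
  expect_true(is.na(capturedFraction(ax)))
  expect_lt(max(abs(frameAngles(ax))), 1e-8)
})

test_that("the fit is invariant under a global rigid motion of all frames", {
  part <- Partition(singleHinge$truth$assignment)
  ax1 <- fitFixedAxis(singleHinge$trajectory, part, 1, 2,
                      nOrientations = 100, seed = 27)
  moved <- randomlyRotateFrames(singleHinge$trajectory, seed = 29)
  ax2 <- fitFixedAxis(moved, part, 1, 2, nOrientations = 100, seed = 27)
  expect_equal(axisAnchor(ax1), axisAnchor(ax2))
  expect_equal(frameAngles(ax1), frameAngles(ax2), tolerance = 1e-5)
  expect_equal(residualMsf(ax1), residualMsf(ax2), tolerance = 1e-7)
})

test_that("two planted hinges are recovered and restriction never helps", {
  gen <- generateTrajectory(SyntheticSpec(c(25, 22, 25),
    hinges = list(list(moving = 1, core = 2), list(moving = 3, core = 2)),
    nFrames = 30, seed = 113))
  part <- Partition(gen$truth$assignment)
  hs <- fitAllHinges(gen$trajectory, part, core = 2,
                     nOrientations = 300, seed = 31)
  expect_length(hs@axes, 2L)
  refFrame <- selectReference(gen$trajectory)
  for (k in 1:2) {
    truth <- gen$truth$hinges[[k]]
    ax <- hs@axes[[paste0("domain", truth$moving)]]
    expect_lt(orientationError(axisOrientation(ax), truth$orientation), 2)
  }
  expect_gte(capturedFraction(hs), 0.99)
  free <- fitRigidDomains(gen$trajectory, part)
  expect_lte(capturedFraction(hs), capturedFraction(free) + 1e-9)

  # one planted hinge + one static side domain
  gen2 <- generateTrajectory(SyntheticSpec(c(25, 22, 25),
    hinges = list(list(moving = 1, core = 2)), nFrames = 20, seed = 115))
  expect_warning(hs2 <- fitAllHinges(gen2$trajectory,
    Partition(gen2$truth$assignment), core = 2, nOrientations = 100,
    seed = 33), "static")
  moving <- gen2$truth$hinges[[1]]$moving
  ax <- hs2@axes[[paste0("domain", moving)]]
  expect_lt(orientationError(axisOrientation(ax),
                             gen2$truth$hinges[[1]]$orientation), 3)
  expect_true(is.na(capturedFraction(hs2@axes[["domain3"]])))
})
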