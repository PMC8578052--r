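# Kinetic core: system matrix assembly, RK4 integration, coarse sampling.

test_that("system matrix encodes edges with zero column sums", {
  # no flow at all
  expect_equal(unname(buildSystemMatrix(rep(0, 8), known = c("Others->Blood" = 0))),
               matrix(0, 11, 11))

  # single hepatic-retention edge
  K <- stats::setNames(rep(0, 8), paramNames())
  K["kLiver"] <- 0.01
  A1 <- buildSystemMatrix(K, known = c("Others->Blood" = 0))
  expect_equal(A1["LiverRet", "Blood"], 0.01)
  expect_equal(A1["Blood", "Blood"], -0.01)
  expect_equal(sum(A1 != 0), 2)
  expect_equal(max(abs(colSums(A1))), 0)

  # random rates against an independent edge-by-edge oracle
  set.seed(101)
  for (rep in 1:5) {
    K <- randomParams()
    A <- buildSystemMatrix(K)
    expect_equal(A, oracleSystemMatrix(K), tolerance = 1e-14)
    expect_lt(max(abs(colSums(A))), 1e-15)
  }
})

test_that("system matrix rejects bad input", {
  expect_error(buildSystemMatrix(rep(-0.01, 8)), "nonnegative")
  expect_error(buildSystemMatrix(rep(0.01, 8), known = c("Hepar->Blood" = 0.1)),
               "unknown compartment")
  expect_error(kineticParameters(rep(0.05, 8)), "lie in")
})

test_that("RK4 reproduces the closed-form exponential and conserves mass", {
  # zero matrix: trajectory frozen at the initial state
  tr0 <- rk4Integrate(matrix(0, 11, 11), initialState(), stepMin = 1,
                      endMin = 100)
  expect_true(all(compartmentStates(tr0) == initialState()))

  # 1-compartment reduction dI/dt = -kI embedded as Blood -> Bladder
  A <- matrix(0, 11, 11)
  A[2, 2] <- -0.01
  A[10, 2] <- 0.01
  tr <- rk4Integrate(A, initialState(100), stepMin = 1, endMin = 4320)
  blood <- compartmentStates(tr)["Blood", ]
  expect_equal(blood[length(blood)], 100 * exp(-0.01 * 4320),
               tolerance = 1e-8)

  # mass conservation at every step for a random valid system
  set.seed(7)
  trr <- rk4Integrate(buildSystemMatrix(randomParams()))
  tot <- colSums(compartmentStates(trr))
  expect_lt(max(abs(tot - 100)) / 100, 1e-8)
  # nonnegativity throughout
  expect_gt(min(compartmentStates(trr)), -1e-9)
})

test_that("RK4 agrees with a matrix-exponential oracle and is step-stable", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  sc <- makeScheme("7")
  for (rep in 1:3) {
    A <- buildSystemMatrix(randomParams())
    tr <- rk4Integrate(A)
    cs <- sampleCoarse(tr, sc)
    for (j in seq_along(sc)) {
      ex <- as.numeric(Matrix::expm(A * sc[j] * 60) %*% initialState())
      expect_lt(max(abs(cs[, j] - ex)) / max(abs(ex)), 1e-6)
    }
  }
  # halving the step changes the solution by < 1e-7 of its scale
  A <- buildSystemMatrix(randomParams())
  y1 <- compartmentStates(rk4Integrate(A, stepMin = 0.5))
  y2 <- compartmentStates(rk4Integrate(A, stepMin = 0.25))
  expect_lt(max(abs(y2[, seq(1, ncol(y2), 2)] - y1)) / max(abs(y1)), 1e-7)
})

test_that("stage-wise RK4 and the one-step transition map coincide", {
  set.seed(12)
  A <- buildSystemMatrix(randomParams())
  y0 <- as.numeric(initialState())
  Ys <- fmtpk:::.rk4ForwardCpp(A, y0, 0.5, 2000)
  Yp <- fmtpk:::.phiForwardCpp(A, y0, 0.5, 2000)
  expect_lt(max(abs(Ys - Yp)), 1e-10)
})

test_that("named sampling schemes match their definitions", {
  expect_equal(as.numeric(makeScheme("7")), c(0.25, 2, 4, 8, 24, 48, 72))
  expect_equal(as.numeric(makeScheme("7-early")),
               c(0, 0.25, 0.5, 2, 12, 24, 48))
  for (nm in c("20", "50", "20-early", "50-early")) {
    sc <- makeScheme(nm)
    expect_length(sc, as.integer(sub("-early", "", nm)))
    expect_true(all(diff(sc) > 0))
  }
  expect_equal(makeScheme("20")[c(1, 20)], c(0.25, 72))
  expect_equal(makeScheme("50-early")[1], 0)
  expect_error(makeScheme("13"), "unknown")
})

test_that("coarse sampling extracts and interpolates correctly", {
  # constant trajectory: any scheme returns the constant
  tr0 <- rk4Integrate(matrix(0, 11, 11), initialState(), stepMin = 1,
                      endMin = 4320)
  cs0 <- sampleCoarse(tr0, "7")
  expect_true(all(cs0 == initialState()))

  # on-grid times are exact column extraction
  set.seed(21)
  tr <- rk4Integrate(buildSystemMatrix(randomParams()), stepMin = 0.5)
  cs <- sampleCoarse(tr, "7")
  expect_identical(cs[, 3], compartmentStates(tr)[, 1 + 4 * 60 * 2])

  # off-grid times: linear interpolation tracks an exponential closed form
  # (on a 0.25 min grid the interpolation curvature error is < 1e-6)
  A <- matrix(0, 11, 11); A[2, 2] <- -0.01; A[10, 2] <- 0.01
  tre <- rk4Integrate(A, initialState(100), stepMin = 0.25, endMin = 4320)
  odd <- c(0.3071, 5.77, 41.003)   # deliberately between grid nodes
  cse <- sampleCoarse(tre, odd)
  expect_equal(as.numeric(cse["Blood", ]), 100 * exp(-0.01 * odd * 60),
               tolerance = 1e-6)

  expect_error(sampleCoarse(tre, c(1, 80)), "beyond")
})

test_that("trajectory validity catches malformed grids", {
  expect_error(new("Trajectory", timesMin = c(0, 1, 1.5),
                   states = matrix(0, 11, 3)), "uniform")
  expect_error(new("Trajectory", timesMin = c(1, 2), states = matrix(0, 11, 2)),
               "start at 0")
})
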