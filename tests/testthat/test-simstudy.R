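# Recovery-study machinery: draws, noise, error metrics, regression, study
# orchestration. Full-size study behavior is exercised in test-acceptance.R;
# here the studies are tiny.

test_that("parameter draws are uniform, bounded and reproducible", {
  d1 <- drawParameters(5, seed = 9)
  d2 <- drawParameters(5, seed = 9)
  expect_identical(d1, d2)
  # degenerate interval
  dd <- drawParameters(4, lo = 0.01, hi = 0.010001, seed = 1)
  expect_true(all(abs(unlist(dd) - 0.01) < 1e-4))
  # uniform moments at scale
  big <- do.call(rbind, drawParameters(10000, seed = 2))
  se <- (0.02 - 0.001) / sqrt(12) / sqrt(nrow(big))
  expect_true(all(abs(colMeans(big) - 0.0105) < 3 * se))
})

test_that("measurement noise has the configured relative spread", {
  K <- stats::setNames(rep(0.01, 8), paramNames())
  clean <- simulateMeasurements(K, c(0.1, 0.2), noiseLevel = 0, endMin = 15)
  expect_equal(provenance(clean), "simulated")
  # noise-free equals the forward prediction exactly
  expect_equal(measurements(clean),
               predictMeasurements(K, c(0.1, 0.2), endMin = 15),
               ignore_attr = TRUE)
  # replicate one value many times: sample relative SD ~ 0.10
  set.seed(3)
  v <- measurements(clean)["blood", 1]
  reps <- vapply(1:2000, function(i) {
    m <- simulateMeasurements(K, c(0.1, 0.2), noiseLevel = 0.1, endMin = 15)
    measurements(m)["blood", 1]
  }, 0)
  relSd <- stats::sd(reps) / v
  seSd <- 0.1 / sqrt(2 * length(reps))
  expect_lt(abs(relSd - 0.1), 3 * seSd)
  # a zero measurement stays zero under noise (clipping): with no efflux
  # and collapse-only mixing all non-blood channels are exactly zero
  z <- simulateMeasurements(rep(0, 8), c(0, 0.1), mix = collapseMixing(),
                            noiseLevel = 0.5, seed = 4, endMin = 10)
  expect_equal(unname(measurements(z)[-2, ]), matrix(0, 8, 2))
})

test_that("relative error arithmetic is exact", {
  K <- stats::setNames(rep(0.01, 8), paramNames())
  expect_equal(unname(relativeError(K, K)), rep(0, 8))
  expect_equal(unname(relativeError(2 * K, K)), rep(1, 8))
  expect_equal(unname(relativeError(K + 0.001, K)), rep(0.1, 8))
  expect_error(relativeError(K, K * 0), "non-positive")
})

test_that("recovery regression matches the closed-form OLS oracle", {
  set.seed(51)
  x <- runif(100, 0.001, 0.02)
  y <- x + rnorm(100, sd = 0.001)
  got <- regressRecovery(y, x)
  want <- oracleOls(y, x)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$se, want$se, tolerance = 1e-12)
  expect_equal(got$r2, want$r2, tolerance = 1e-12)
  # consistency: generative slope 1 within 3 SEs
  expect_lt(abs(got$slope - 1), 3 * got$se)
  # degenerate cases
  expect_equal(regressRecovery(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(regressRecovery(x, x)$r2, 1, tolerance = 1e-12)
  cst <- regressRecovery(rep(0.5, 10), runif(10))
  expect_equal(cst$slope, 0, tolerance = 1e-12)
  expect_equal(cst$r2, 0, tolerance = 1e-12)
  expect_error(regressRecovery(y, rep(1, 100)), "degenerate")
})

test_that("tiny studies are deterministic, paired across arms, and accurate when noise-free", {
  cfgA <- studyConfig(n = 3, schemes = "7", seed = 5)
  r1 <- runStudy(cfgA)
  r2 <- runStudy(cfgA)
  expect_identical(studyRecords(r1), studyRecords(r2))

  # both arms saw the same truths and the same simulated data
  rec <- studyRecords(r1)
  byArm <- split(rec, rec$arm)
  expect_identical(byArm$corrected$true, byArm$uncorrected$true)

  # uncorrected-only runs pair with corrected-only runs via the master seed
  rc <- runStudy(studyConfig(n = 3, schemes = "7", arms = "corrected",
                             seed = 5))
  expect_identical(studyRecords(rc)$est,
                   rec$est[rec$arm == "corrected"])

  # noise-free corrected recovery is essentially exact
  r0 <- runStudy(studyConfig(n = 2, schemes = "7", arms = "corrected",
                             noiseLevel = 0, seed = 6))
  expect_lt(grandMeanError(r0, "7", "corrected"), 0.01)
})

test_that("study outputs round-trip to disk with a complete manifest", {
  r <- runStudy(studyConfig(n = 2, schemes = "7", seed = 8))
  dir <- file.path(tempdir(), "fmtpk-study-out")
  paths <- writeStudyOutputs(r, dir)
  expect_true(all(file.exists(paths)))
  t1 <- utils::read.csv(file.path(dir, "table1.csv"), check.names = FALSE)
  expect_equal(t1$param, c(paramNames(), "Average relative error"))
  expect_equal(t1[["7"]][9], mean(t1[["7"]][1:8]))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$n, 2)
  expect_equal(man$rbv$liver, 0.30)
  expect_equal(man$fit$constraint, "sigmoid")
})
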