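# Mixing-matrix construction and application.

test_that("reference intensity-diffusion matrix has the documented structure", {
  idv <- printedIdv()
  expect_equal(idv["lung", "lung"], 0.717)
  expect_equal(idv["lung", "bone"], 0.122)
  expect_equal(sum(idv["lung", ]),
               0.717 + 0.022 + 0.023 + 0.122 + 0.115)
  expect_true(all(idv >= 0 & idv <= 1))
  rs <- rowSums(idv)
  expect_true(all(rs >= 0.90 & rs <= 1.001))
  # each diagonal entry is the maximum of its row
  expect_true(all(diag(idv) == apply(idv, 1, max)))
})

test_that("packaged intensity-diffusion CSV matches the in-code matrix", {
  path <- system.file("extdata", "idv_reference.csv", package = "fmtpk")
  expect_true(nzchar(path))
  expect_identical(readIdv(path), printedIdv())
})

test_that("collapse map sums sub-compartments one-to-one", {
  Cm <- collapseMap()
  expect_equal(unname(colSums(Cm)), rep(1, 11))
  expect_equal(sum(Cm != 0), 11)
  expect_equal(Cm["liver", c("LiverRet", "LiverElim")], c(LiverRet = 1, LiverElim = 1))
  expect_equal(Cm["kidneys", c("KidneyRet", "KidneyElim")],
               c(KidneyRet = 1, KidneyElim = 1))
})

test_that("neutral components reduce the mixing matrix to the collapse map", {
  rbv0 <- stats::setNames(numeric(9), channelNames())
  rbv0["blood"] <- 1
  mix <- assembleMixing(idv = diag(9), rbv = rbv0, mode = "blend")
  expect_equal(unname(mixingOperator(mix)), unname(collapseMap()))
  expect_equal(unname(mixingOperator(collapseMixing())), unname(collapseMap()))
})

test_that("a pure-lung state is spread according to the lung source row", {
  rbv0 <- stats::setNames(numeric(9), channelNames())
  rbv0["blood"] <- 1
  mix <- assembleMixing(idv = printedIdv(), rbv = rbv0)
  state <- stats::setNames(numeric(11), stateNames())
  state["Lung"] <- 1
  got <- applyMixing(mix, matrix(state))
  want <- c(lung = 0.717, blood = 0.022, liver = 0.023, bone = 0.122,
            spleen = 0, intestine = 0, kidneys = 0, bladder = 0,
            others = 0.115)
  expect_equal(got[, 1], want)
})

test_that("blend mode forms the documented convex combination", {
  rbv <- stats::setNames(numeric(9), channelNames())
  rbv["blood"] <- 1
  rbv["liver"] <- 0.3
  mix <- assembleMixing(idv = diag(9), rbv = rbv, mode = "blend")
  set.seed(31)
  state <- matrix(runif(11, 0, 10))
  rownames(state) <- stateNames()
  got <- applyMixing(mix, state)
  expect_equal(unname(got["liver", 1]),
               unname(0.7 * (state["LiverRet", 1] + state["LiverElim", 1]) +
                        0.3 * state["Blood", 1]))
  # additive mode adds the vascular term without attenuating tissue
  mixA <- assembleMixing(idv = diag(9), rbv = rbv, mode = "additive")
  gotA <- applyMixing(mixA, state)
  expect_equal(unname(gotA["liver", 1]),
               unname(state["LiverRet", 1] + state["LiverElim", 1] +
                        0.3 * state["Blood", 1]))
})

test_that("mixing application matches a naive product oracle and is linear", {
  set.seed(32)
  mix <- assembleMixing()
  states <- matrix(runif(33, 0, 50), 11, 3)
  got <- applyMixing(mix, states)
  expect_equal(unname(got), oracleMatProd(mixingOperator(mix), states),
               tolerance = 1e-12)
  # linearity
  s1 <- matrix(runif(11, 0, 50)); s2 <- matrix(runif(11, 0, 50))
  expect_equal(applyMixing(mix, s1 + s2),
               applyMixing(mix, s1) + applyMixing(mix, s2), tolerance = 1e-12)
  # zero in, zero out; nonnegative in, nonnegative out
  expect_true(all(applyMixing(mix, matrix(0, 11, 2)) == 0))
  expect_true(all(got >= 0))
  expect_error(applyMixing(mix, matrix(0, 10, 2)), "dimension mismatch")
})

test_that("channel signals invert from mixed measurements by least squares", {
  # M is well-conditioned on the 9 collapsed channels: the 9 channel sums
  # are recoverable from one time point even though the retention/elimination
  # split within liver and kidneys is not
  set.seed(33)
  mix <- assembleMixing()
  state <- runif(11, 0, 30)
  mixed <- applyMixing(mix, matrix(state))
  # solve for the 9 channel signals under the blend parameterization
  rbv <- defaultRbv()
  S9 <- t(printedIdv())          # 9x9 operator on pre-blur channel signals
  pre <- qr.solve(S9, mixed[, 1])
  chan <- collapseMap() %*% state
  blend <- (1 - rbv) * chan[, 1] + rbv * chan["blood", 1]
  blend["blood"] <- chan["blood", 1]
  expect_equal(pre, blend, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("malformed mixing components are rejected", {
  expect_error(assembleMixing(idv = matrix(0.1, 3, 3)), "9 x 9")
  bad <- printedIdv(); bad[1, 1] <- 1.5
  expect_error(assembleMixing(idv = bad), "lie in")
  low <- diag(9) * 0.5
  expect_warning(assembleMixing(idv = low), "row sums")
  expect_error(assembleMixing(rbv = rep(2, 9)), "rbv")
  expect_error(assembleMixing(mode = "fancy"))
})
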