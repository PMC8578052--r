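# The full-size recovery study used by the acceptance tests. Computed once
# per test run and cached: several criteria read different slices of the
# same study. Conditions: 100 uniform truths on [0.001, 0.02] per minute,
# 10 % multiplicative Gaussian noise, reference intensity-diffusion matrix
# with default rBV, default known rates.

.acceptanceCache <- new.env(parent = emptyenv())

acceptanceStudy <- function() {
  if (is.null(.acceptanceCache$res)) {
    corrected <- runStudy(studyConfig(
      n = 100, schemes = c("7", "20", "50", "7-early", "20-early", "50-early"),
      arms = "corrected", seed = 1))
    uncorrected <- runStudy(studyConfig(
      n = 100, schemes = "7", arms = "uncorrected", seed = 1))
    .acceptanceCache$res <- list(corrected = corrected,
                                 uncorrected = uncorrected)
  }
  .acceptanceCache$res
}
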