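#' The reference intensity-diffusion matrix
#'
#' The 9 x 9 intensity-diffusion matrix estimated from hybrid uCT-FMT scans:
#' entry `[i, j]` is the fraction of source channel i's fluorescence that is
#' measured in organ j, after blurring by the limited optical resolution.
#' Rows are sources and columns are measured organs, both in
#' [channelNames()] order. Row sums fall in `[0.90, 1.001]` (a little signal
#' is lost outside all organ masks) and each diagonal entry is the maximum
#' of its row. The same matrix ships as
#' `system.file("extdata", "idv_reference.csv", package = "fmtpk")`.
#'
#' @return 9 x 9 numeric matrix with channel dimnames.
#' @examples
#' idv <- printedIdv()
#' idv["lung", "lung"]    # 0.717
#' rowSums(idv)
#' @export
printedIdv <- function() {
  ch <- channelNames()
  matrix(c(
    # lung   blood  liver  bone   spleen intest kidney bladdr others
    0.717, 0.022, 0.023, 0.122, 0.000, 0.000, 0.000, 0.000, 0.115,  # lung
    0.039, 0.818, 0.013, 0.043, 0.000, 0.000, 0.000, 0.000, 0.086,  # blood
    0.007, 0.002, 0.872, 0.022, 0.000, 0.013, 0.002, 0.000, 0.071,  # liver
    0.019, 0.004, 0.012, 0.682, 0.001, 0.004, 0.000, 0.000, 0.248,  # bone
    0.000, 0.000, 0.002, 0.044, 0.650, 0.000, 0.044, 0.000, 0.252,  # spleen
    0.000, 0.000, 0.008, 0.004, 0.000, 0.898, 0.007, 0.000, 0.067,  # intestine
    0.000, 0.000, 0.009, 0.002, 0.005, 0.046, 0.806, 0.000, 0.129,  # kidneys
    0.000, 0.000, 0.000, 0.005, 0.000, 0.001, 0.000, 0.742, 0.249,  # bladder
    0.005, 0.002, 0.011, 0.074, 0.001, 0.018, 0.005, 0.002, 0.785), # others
    nrow = 9, byrow = TRUE, dimnames = list(ch, ch))
}

#' Default relative blood volume per measured channel
#'
#' Fraction of each organ's measured signal attributable to blood within the
#' organ's vasculature. The heart/blood channel is pure blood by convention
#' (rBV = 1). These literature-informed defaults are configuration, not
#' measured constants of this package; override per study via
#' [assembleMixing()] or the `rbv.*` config keys.
#'
#' @return Named numeric vector over [channelNames()].
#' @export
defaultRbv <- function() {
  c(lung = 0.50, blood = 1.00, liver = 0.30, bone = 0.11, spleen = 0.35,
    intestine = 0.10, kidneys = 0.24, bladder = 0.05, others = 0.05)
}

#' Sub-compartment collapse map
#'
#' The 9 x 11 0/1 matrix summing model compartments into measured channels:
#' liver retention + liver elimination -> liver, kidney retention + kidney
#' elimination -> kidneys, all other compartments one-to-one. Each state
#' column contributes to exactly one channel.
#'
#' @return 9 x 11 matrix with channel/state dimnames.
#' @export
collapseMap <- function() {
  Cm <- matrix(0, 9, 11, dimnames = list(channelNames(), stateNames()))
  Cm["lung", "Lung"] <- 1
  Cm["blood", "Blood"] <- 1
  Cm["liver", c("LiverRet", "LiverElim")] <- 1
  Cm["bone", "Bone"] <- 1
  Cm["spleen", "Spleen"] <- 1
  Cm["intestine", "Intestine"] <- 1
  Cm["kidneys", c("KidneyRet", "KidneyElim")] <- 1
  Cm["bladder", "Bladder"] <- 1
  Cm["others", "Others"] <- 1
  Cm
}

.checkIdv <- function(idv) {
  ch <- channelNames()
  if (!is.matrix(idv) || !identical(dim(idv), c(9L, 9L)))
    stop("the intensity-diffusion matrix must be 9 x 9")
  if (is.null(dimnames(idv))) dimnames(idv) <- list(ch, ch)
  if (!identical(rownames(idv), ch) || !identical(colnames(idv), ch))
    idv <- idv[ch, ch]
  if (any(idv < 0) || any(idv > 1))
    stop("intensity-diffusion entries must lie in [0, 1]")
  rs <- rowSums(idv)
  if (any(rs < 0.90 - 1e-9) || any(rs > 1.001 + 1e-9))
    warning("intensity-diffusion row sums outside [0.90, 1.001]: ",
            paste(sprintf("%s=%.3f", rownames(idv)[rs < 0.90 | rs > 1.001],
                          rs[rs < 0.90 | rs > 1.001]), collapse = ", "))
  idv
}

#' Assemble the measurement mixing matrix
#'
#' Combines the three signal-mixing effects into the 9 x 11 operator M of
#' the measurement model I_m = M I:
#' \enumerate{
#'   \item sub-compartment fusion (the collapse map),
#'   \item vascular signal: in the default `"blend"` mode, channel j's
#'     pre-blur signal is `(1 - rbv_j)` times its tissue compartments plus
#'     `rbv_j` times blood (a convex combination preserving signal scale);
#'     in `"additive"` mode the blood term is added on top. The blood
#'     channel is pure blood in both modes.
#'   \item inter-organ blur: the transposed intensity-diffusion matrix is
#'     applied to the 9 channel signals (the matrix's rows are sources, so
#'     measurement assembly uses its transpose).
#' }
#' With an identity intensity-diffusion matrix and zero rBV (blood channel
#' excepted), M reduces to the collapse map exactly.
#'
#' @param idv 9 x 9 intensity-diffusion matrix; [printedIdv()] by default.
#' @param rbv Relative blood volumes per channel; [defaultRbv()] by default.
#' @param collapse The sub-compartment collapse map.
#' @param mode `"blend"` (default) or `"additive"`.
#' @return A [MixingMatrix-class] object.
#' @examples
#' mix <- assembleMixing()
#' round(mixingOperator(mix)["liver", ], 3)
#' @export
assembleMixing <- function(idv = printedIdv(), rbv = defaultRbv(),
                           collapse = collapseMap(),
                           mode = c("blend", "additive")) {
  mode <- match.arg(mode)
  idv <- .checkIdv(idv)
  ch <- channelNames()
  if (is.null(names(rbv))) names(rbv) <- ch
  if (!setequal(names(rbv), ch)) stop("rbv must cover the 9 channels")
  rbv <- rbv[ch]
  if (any(rbv < 0) || any(rbv > 1)) stop("rbv values must lie in [0, 1]")
  eBlood <- as.numeric(stateNames() == "Blood")
  S <- collapse
  for (j in ch) {
    if (j == "blood") {
      S[j, ] <- eBlood
    } else if (mode == "blend") {
      S[j, ] <- (1 - rbv[[j]]) * collapse[j, ] + rbv[[j]] * eBlood
    } else {
      S[j, ] <- collapse[j, ] + rbv[[j]] * eBlood
    }
  }
  M <- t(idv) %*% S
  dimnames(M) <- list(ch, stateNames())
  new("MixingMatrix", M = M, idv = idv, rbv = rbv, collapse = collapse,
      mode = mode)
}

#' Collapse-only (uncorrected) mixing
#'
#' The measurement operator of the uncorrected model: sub-compartments are
#' still summed into their measured organs, but there is no blur and no
#' vascular term.
#'
#' @return A [MixingMatrix-class] whose operator equals [collapseMap()].
#' @export
collapseMixing <- function() {
  rbv <- stats::setNames(numeric(9), channelNames())
  rbv["blood"] <- 1
  assembleMixing(idv = diag(9), rbv = rbv, mode = "blend")
}

#' Apply a mixing matrix to compartment states
#'
#' Plain matrix product per time column: the mixed prediction
#' `I_m = M I_c`.
#'
#' @param mix A [MixingMatrix-class] or a 9 x 11 matrix.
#' @param coarse 11 x n matrix of compartment amounts.
#' @return 9 x n matrix of predicted channel measurements.
#' @export
applyMixing <- function(mix, coarse) {
  M <- if (is(mix, "MixingMatrix")) mix@M else mix
  coarse <- as.matrix(coarse)
  if (nrow(coarse) != ncol(M))
    stop(sprintf("dimension mismatch: mixing is %d x %d but states have %d rows",
                 nrow(M), ncol(M), nrow(coarse)))
  out <- M %*% coarse
  rownames(out) <- rownames(M)
  out
}

#' @rdname accessors
#' @export
setMethod("mixingOperator", "MixingMatrix", function(x, ...) x@M)

setMethod("show", "MixingMatrix", function(object) {
  cat(sprintf("MixingMatrix (9 channels x 11 compartments), mode = '%s'\n",
              object@mode))
  ident <- isTRUE(all.equal(object@idv, diag(9), check.attributes = FALSE))
  cat(sprintf("  intensity diffusion: %s; rBV range %.2f-%.2f (blood = %.2f)\n",
              if (ident) "identity (no blur)" else "non-trivial",
              min(object@rbv[names(object@rbv) != "blood"]),
              max(object@rbv[names(object@rbv) != "blood"]),
              object@rbv[["blood"]]))
})
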