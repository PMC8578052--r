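#' @import methods
NULL

#' Compartment, channel and parameter layout
#'
#' The kinetic model uses a fixed 11-compartment state: the blood pool, five
#' irreversible retention sites (lung, liver, bone, spleen, kidneys), the two
#' elimination routes split into transit sub-compartments (liver -> intestine,
#' kidneys -> bladder), and a diffuse "others" pool exchanging with blood.
#' Measurements resolve only 9 channels because the liver and kidney
#' retention/elimination sub-compartments are imaged as single organs.
#'
#' These orderings are fixed: every state vector, trajectory, mixing matrix
#' and measurement table in the package uses them.
#'
#' @return Character vectors of names, in canonical order.
#' @examples
#' stateNames()
#' channelNames()
#' paramNames()
#' @export
stateNames <- function() {
  c("Lung", "Blood", "LiverRet", "LiverElim", "Bone", "Spleen",
    "Intestine", "KidneyRet", "KidneyElim", "Bladder", "Others")
}

#' @rdname stateNames
#' @export
channelNames <- function() {
  c("lung", "blood", "liver", "bone", "spleen", "intestine",
    "kidneys", "bladder", "others")
}

#' @rdname stateNames
#' @export
paramNames <- function() {
  c("kKidneyElimination", "kLiverElimination", "kKidney", "kLiver",
    "kBone", "kSpleen", "kLung", "kOthers")
}

# destination compartment of each unknown Blood -> X rate, in paramNames() order
.paramDest <- c(kKidneyElimination = "KidneyElim",
                kLiverElimination  = "LiverElim",
                kKidney            = "KidneyRet",
                kLiver             = "LiverRet",
                kBone              = "Bone",
                kSpleen            = "Spleen",
                kLung              = "Lung",
                kOthers            = "Others")

#' Fine-grid solution of the kinetic model
#'
#' An 11 x T matrix of compartment amounts (% injected dose) on a uniform
#' time grid in minutes, as produced by [rk4Integrate()].
#'
#' @slot timesMin Numeric vector of grid times in minutes, starting at 0.
#' @slot states 11 x length(timesMin) numeric matrix, rows in [stateNames()]
#'   order.
#' @export
setClass("Trajectory",
  representation(timesMin = "numeric", states = "matrix"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (nrow(object@states) != length(stateNames()))
    msg <- c(msg, "states must have one row per model compartment")
  if (ncol(object@states) != length(object@timesMin))
    msg <- c(msg, "states must have one column per grid time")
  if (length(object@timesMin) >= 2) {
    d <- diff(object@timesMin)
    if (any(d <= 0)) msg <- c(msg, "grid times must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * max(d))
      msg <- c(msg, "grid must be uniform")
  }
  if (length(object@timesMin) && object@timesMin[1] != 0)
    msg <- c(msg, "grid must start at 0")
  if (length(msg)) msg else TRUE
})

#' Organ-level fluorescence measurements
#'
#' A 9-channel x time table of organ fluorescence in % injected dose, either
#' simulated ([simulateMeasurements()]) or read from a CSV of in vivo data
#' ([readMeasurements()]).
#'
#' @slot timesH Sampling times in hours, strictly increasing, nonnegative.
#' @slot values 9 x length(timesH) numeric matrix, rows in [channelNames()]
#'   order; no negative values.
#' @slot provenance Either `"simulated"` or `"in_vivo"`.
#' @export
setClass("MeasurementSet",
  representation(timesH = "numeric", values = "matrix",
                 provenance = "character"))

setValidity("MeasurementSet", function(object) {
  msg <- character()
  if (!identical(rownames(object@values), channelNames()))
    msg <- c(msg, "value rows must be the 9 measured channels in canonical order")
  if (ncol(object@values) != length(object@timesH))
    msg <- c(msg, "one value column per sampling time required")
  if (any(object@timesH < 0)) msg <- c(msg, "sampling times must be nonnegative")
  if (length(object@timesH) >= 2 && any(diff(object@timesH) <= 0))
    msg <- c(msg, "sampling times must be strictly increasing")
  if (any(object@values < 0)) msg <- c(msg, "measurements must be nonnegative")
  if (!object@provenance %in% c("simulated", "in_vivo"))
    msg <- c(msg, "provenance must be 'simulated' or 'in_vivo'")
  if (length(msg)) msg else TRUE
})

#' Measurement mixing operator
#'
#' The 9 x 11 operator M mapping model compartment amounts to measured organ
#' signals. M combines three effects: inter-organ fluorescence blur (the
#' intensity-diffusion matrix), the vascular signal carried by each organ's
#' relative blood volume, and the fusion of the liver/kidney elimination and
#' retention sub-compartments into single measured organs. Built by
#' [assembleMixing()].
#'
#' @slot M 9 x 11 numeric matrix, all entries nonnegative.
#' @slot idv 9 x 9 intensity-diffusion matrix (rows: source channel, columns:
#'   measured channel).
#' @slot rbv Relative blood volume per measured channel, in `[0, 1]`.
#' @slot collapse 9 x 11 0/1 sub-compartment collapse map.
#' @slot mode `"blend"` or `"additive"` composition of the blood-volume term.
#' @export
setClass("MixingMatrix",
  representation(M = "matrix", idv = "matrix", rbv = "numeric",
                 collapse = "matrix", mode = "character"))

setValidity("MixingMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@M), c(9L, 11L)))
    msg <- c(msg, "M must be 9 x 11")
  if (any(object@M < -1e-12)) msg <- c(msg, "M entries must be nonnegative")
  if (!object@mode %in% c("blend", "additive"))
    msg <- c(msg, "mode must be 'blend' or 'additive'")
  if (length(msg)) msg else TRUE
})

#' Result of a kinetic-parameter fit
#'
#' @slot estimates Named numeric vector of the 8 fitted rates (min^-1), in
#'   [paramNames()] order, inside the configured bounds.
#' @slot cost List with elements `sse`, `penalty`, `total` at the optimum.
#' @slot iterations Number of conjugate-gradient iterations performed.
#' @slot converged Logical; `FALSE` means the iteration cap was reached.
#' @slot gradNorm Final gradient norm in the unconstrained search space.
#' @slot trace Accepted cost values, one per iteration (non-increasing).
#' @slot config The resolved [fitConfig()] used.
#' @export
setClass("FitResult",
  representation(estimates = "numeric", cost = "list", iterations = "integer",
                 converged = "logical", gradNorm = "numeric", trace = "numeric",
                 config = "list"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!identical(names(object@estimates), paramNames()))
    msg <- c(msg, "estimates must be named by the 8 unknown rates")
  if (length(object@trace) >= 2 &&
      any(diff(object@trace) > 1e-8 * pmax(abs(object@trace[-1]), 1)))
    msg <- c(msg, "cost trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Labeled voxel masks on a common grid
#'
#' Disjoint binary organ masks used to compute an intensity-diffusion matrix
#' from segmentations; the complement of their union is treated as the
#' implicit "others" region. Built by [makePhantom()] or [readMaskSet()].
#'
#' @slot dims Integer grid shape (3 values).
#' @slot spacingMm Isotropic voxel spacing in millimetres.
#' @slot masks Named list of logical arrays, pairwise disjoint.
#' @export
setClass("VoxelMaskSet",
  representation(dims = "integer", spacingMm = "numeric", masks = "list"))

setValidity("VoxelMaskSet", function(object) {
  msg <- character()
  if (length(object@dims) != 3) msg <- c(msg, "dims must have length 3")
  if (object@spacingMm <= 0) msg <- c(msg, "voxel spacing must be positive")
  if (is.null(names(object@masks)) || anyDuplicated(names(object@masks)))
    msg <- c(msg, "masks must have unique names")
  tot <- 0L
  for (m in object@masks) {
    if (!identical(dim(m), object@dims))
      msg <- c(msg, "all masks must share the grid shape")
    tot <- tot + as.integer(m)
  }
  if (length(object@masks) && any(tot > 1L))
    msg <- c(msg, "masks must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' Parameter-recovery simulation report
#'
#' Output of [runStudy()]: per-replicate true and estimated rates, mean
#' relative errors per parameter/scheme/arm, and estimate-vs-truth regression
#' summaries.
#'
#' @slot records data.frame with one row per replicate x scheme x arm x
#'   parameter (`replicate`, `scheme`, `arm`, `param`, `true`, `est`,
#'   `converged`).
#' @slot errors data.frame of mean relative errors per scheme/arm/parameter.
#' @slot grand data.frame of grand mean relative errors per scheme/arm.
#' @slot slopes data.frame of OLS slope, slope SE and R^2 of estimate vs
#'   truth per scheme/arm/parameter.
#' @slot config The resolved [studyConfig()].
#' @export
setClass("RecoveryReport",
  representation(records = "data.frame", errors = "data.frame",
                 grand = "data.frame", slopes = "data.frame", config = "list"))
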