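#' Accessors for fmtpk objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x An fmtpk S4 object.
#' @param ... Further arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(x, ...) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("gridTimes", function(x, ...) standardGeneric("gridTimes"))

#' @rdname accessors
#' @export
setGeneric("compartmentStates",
           function(x, ...) standardGeneric("compartmentStates"))

#' @rdname accessors
#' @export
setGeneric("mixingOperator",
           function(x, ...) standardGeneric("mixingOperator"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x, ...) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("costBreakdown", function(x, ...) standardGeneric("costBreakdown"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("studyRecords", function(x, ...) standardGeneric("studyRecords"))

#' @rdname accessors
#' @export
setGeneric("errorTable", function(x, ...) standardGeneric("errorTable"))

#' @rdname accessors
#' @export
setGeneric("slopeTable", function(x, ...) standardGeneric("slopeTable"))

#' @rdname accessors
#' @param scheme,arm Restrict to one sampling scheme / model arm.
#' @export
setGeneric("grandMeanError",
           function(x, scheme, arm = "corrected", ...)
             standardGeneric("grandMeanError"))

#' @rdname accessors
#' @export
setGeneric("organMasks", function(x, ...) standardGeneric("organMasks"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x, ...) standardGeneric("voxelSpacing"))
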