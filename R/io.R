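#' Construct a measurement set
#'
#' @param timesH Sampling times in hours.
#' @param values 9 x length(timesH) matrix (rows: [channelNames()]) or a
#'   matrix whose rownames are a permutation of the channels.
#' @param provenance `"simulated"` or `"in_vivo"`.
#' @return A [MeasurementSet-class].
#' @export
measurementSet <- function(timesH, values,
                           provenance = c("simulated", "in_vivo")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (!is.null(rownames(values)) && !identical(rownames(values), channelNames())) {
    if (!setequal(rownames(values), channelNames()))
      stop("value rows must be the 9 measured channels")
    values <- values[channelNames(), , drop = FALSE]
  }
  rownames(values) <- channelNames()
  colnames(values) <- NULL
  new("MeasurementSet", timesH = as.numeric(timesH), values = values,
      provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("sampleTimes", "MeasurementSet", function(x, ...) x@timesH)

#' @rdname accessors
#' @export
setMethod("measurements", "MeasurementSet", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("provenance", "MeasurementSet", function(x, ...) x@provenance)

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet (%s): 9 channels x %d times (%.3g-%.3g h)\n",
              object@provenance, length(object@timesH),
              min(object@timesH), max(object@timesH)))
})

#' Read and write organ measurement tables
#'
#' The CSV schema has a `time_h` column followed by the nine channel
#' columns (`lung, blood, liver, bone, spleen, intestine, kidneys, bladder,
#' others`), one row per time point, values in %ID, '.' decimal separator.
#' Columns may appear in any order and are reordered canonically on read;
#' a missing channel column, duplicate times, or negative values are
#' rejected with a pointed error.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag to attach on read.
#' @return `readMeasurements()`: a [MeasurementSet-class];
#'   `writeMeasurements()`: the path, invisibly.
#' @export
readMeasurements <- function(path, provenance = "in_vivo") {
  df <- utils::read.csv(path, check.names = TRUE)
  if (!"time_h" %in% names(df)) stop("missing required column: time_h")
  missing <- setdiff(channelNames(), names(df))
  if (length(missing))
    stop("missing channel column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$time_h)) stop("duplicate sampling times in ", path)
  df <- df[order(df$time_h), , drop = FALSE]
  vals <- t(as.matrix(df[, channelNames(), drop = FALSE]))
  neg <- which(apply(vals < 0, 2, any))
  if (length(neg))
    stop("negative measurement value at row ", neg[1L])
  measurementSet(df$time_h, vals, provenance = provenance)
}

#' @rdname readMeasurements
#' @param meas A [MeasurementSet-class] to write.
#' @export
writeMeasurements <- function(meas, path) {
  stopifnot(is(meas, "MeasurementSet"))
  df <- data.frame(time_h = meas@timesH, t(meas@values), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write intensity-diffusion matrices
#'
#' 9 x 9 CSV with a leading `source` column of channel names and one column
#' per measured channel. The reference matrix ships at
#' `system.file("extdata", "idv_reference.csv", package = "fmtpk")`.
#'
#' @param path CSV file path.
#' @return `readIdv()`: a 9 x 9 matrix with channel dimnames;
#'   `writeIdv()`: the path, invisibly.
#' @export
readIdv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  if (names(df)[1L] != "source") stop("first column must be 'source'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$source
  .checkIdv(m)
}

#' @rdname readIdv
#' @param idv A 9 x 9 intensity-diffusion matrix.
#' @export
writeIdv <- function(idv, path) {
  idv <- .checkIdv(idv)
  df <- data.frame(source = rownames(idv), idv, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolved run configuration
#'
#' All tunable model/mixing/fit/study settings with their defaults.
#' `readRunConfig()` merges a YAML file over the defaults, rejecting
#' unknown keys, and records per-key provenance (`"default"` or `"file"`)
#' in the `"provenance"` attribute.
#'
#' Keys: `bounds.lo`, `bounds.hi`, `known_rates.<From-To>`,
#' `init.blood_pct`, `grid.step_min`, `grid.end_min`, `rbv.<channel>`,
#' `mixing.mode`, `idv.source` (printed|file), `idv.path`, `idv.fwhm_mm`,
#' `fit.c`, `fit.max_iter`, `fit.init`, `fit.n_starts`, `fit.constraint`,
#' `study.n`, `study.noise`, `study.noise_model`, `study.schemes`,
#' `study.seed`.
#'
#' @return Named list of settings (flattened keys with '.').
#' @export
defaultConfig <- function() {
  cfg <- list(
    "bounds.lo" = 0.001, "bounds.hi" = 0.02,
    "init.blood_pct" = 100, "grid.step_min" = 0.5, "grid.end_min" = 4320,
    "mixing.mode" = "blend", "idv.source" = "printed", "idv.path" = "",
    "idv.fwhm_mm" = 0.5,
    "fit.c" = 1e-4, "fit.max_iter" = 500L, "fit.init" = "midpoint",
    "fit.n_starts" = 5L, "fit.constraint" = "sigmoid",
    "study.n" = 100L, "study.noise" = 0.10,
    "study.noise_model" = "gaussian",
    "study.schemes" = c("7", "20", "50", "7-early", "20-early", "50-early"),
    "study.seed" = 1L)
  for (k in names(defaultKnownRates()))
    cfg[[paste0("known_rates.", gsub("->", "-", k, fixed = TRUE))]] <-
      defaultKnownRates()[[k]]
  rbv <- defaultRbv()
  for (k in names(rbv)) cfg[[paste0("rbv.", k)]] <- rbv[[k]]
  attr(cfg, "provenance") <- stats::setNames(rep("default", length(cfg)),
                                             names(cfg))
  cfg
}

#' @rdname defaultConfig
#' @param path YAML file of overrides (possibly nested; nesting is
#'   flattened with '.').
#' @export
readRunConfig <- function(path) {
  cfg <- defaultConfig()
  prov <- attr(cfg, "provenance")
  flat <- .flattenConfig(yaml::read_yaml(path))
  unknown <- setdiff(names(flat), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(flat)) {
    cfg[[k]] <- flat[[k]]
    prov[[k]] <- "file"
  }
  attr(cfg, "provenance") <- prov
  cfg
}

.flattenConfig <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(x[[k]]) && !is.null(names(x[[k]]))) {
      out <- c(out, .flattenConfig(x[[k]], key))
    } else {
      out[[key]] <- x[[k]]
    }
  }
  out
}

# materialize model objects from a flat config
.configKnownRates <- function(cfg) {
  keys <- grep("^known_rates\\.", names(cfg), value = TRUE)
  rates <- vapply(keys, function(k) as.numeric(cfg[[k]]), 0)
  names(rates) <- gsub("-", "->", sub("^known_rates\\.", "", keys), fixed = TRUE)
  rates
}

.configRbv <- function(cfg) {
  vapply(channelNames(), function(ch) as.numeric(cfg[[paste0("rbv.", ch)]]), 0)
}

.configMixing <- function(cfg) {
  idv <- switch(cfg[["idv.source"]],
    printed = printedIdv(),
    file = readIdv(cfg[["idv.path"]]),
    stop("idv.source must be 'printed' or 'file'"))
  assembleMixing(idv, .configRbv(cfg), mode = cfg[["mixing.mode"]])
}

.configFit <- function(cfg) {
  fitConfig(lo = cfg[["bounds.lo"]], hi = cfg[["bounds.hi"]],
            cWeight = cfg[["fit.c"]], maxIter = cfg[["fit.max_iter"]],
            init = cfg[["fit.init"]], nStarts = cfg[["fit.n_starts"]],
            constraint = cfg[["fit.constraint"]],
            stepMin = cfg[["grid.step_min"]], endMin = cfg[["grid.end_min"]],
            bloodPct = cfg[["init.blood_pct"]])
}
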