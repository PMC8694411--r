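#' Construct a VoltageExperiment
#'
#' Assemble tMFC voltage traces into the package's central container, a
#' [SummarizedExperiment::SummarizedExperiment] subclass with timepoints as
#' rows and individual fuel cells as columns.
#'
#' @param voltage numeric matrix of voltages (mV), timepoints x tMFCs.
#' @param day numeric vector of measurement days (strictly increasing),
#'   one per row.
#' @param treatment character vector of treatment labels, one per column.
#' @param tmfcId character vector of unique cell identifiers, one per
#'   column; defaults to `<treatment>_R<replicate>`.
#' @param missing logical matrix flagging interrupted measurements; defaults
#'   to all `FALSE` (with `NA` voltages auto-flagged).
#'
#' @return a [VoltageExperiment-class] object.
#' @examples
#' v <- matrix(rnorm(20, 300, 5), nrow = 10)
#' ve <- VoltageExperiment(v, day = seq(0, 4.5, by = 0.5),
#'                         treatment = c("control", "urea"))
#' ve
#' @export
VoltageExperiment <- function(voltage, day, treatment, tmfcId = NULL,
                              missing = NULL) {
  voltage <- as.matrix(voltage)
  if (length(day) != nrow(voltage))
    stop("length(day) must equal nrow(voltage)")
  if (length(treatment) != ncol(voltage))
    stop("length(treatment) must equal ncol(voltage)")
  if (is.null(tmfcId)) {
    tmfcId <- stats::ave(seq_along(treatment), treatment, FUN = seq_along)
    tmfcId <- paste0(treatment, "_R", tmfcId)
  }
  if (is.null(missing)) {
    missing <- is.na(voltage)
  } else {
    missing <- as.matrix(missing) | is.na(voltage)
  }
  dimnames(voltage) <- list(NULL, tmfcId)
  dimnames(missing) <- list(NULL, tmfcId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(voltage = voltage, missing = missing),
    rowData = S4Vectors::DataFrame(day = as.numeric(day)),
    colData = S4Vectors::DataFrame(tmfc_id = as.character(tmfcId),
                                   treatment = as.character(treatment),
                                   row.names = tmfcId))
  methods::new("VoltageExperiment", se)
}

#' @rdname VoltageExperiment
#' @export
setMethod("dayTimes", "VoltageExperiment", function(x)
  SummarizedExperiment::rowData(x)$day)

#' @rdname VoltageExperiment
#' @export
setMethod("tmfcIds", "VoltageExperiment", function(x)
  SummarizedExperiment::colData(x)$tmfc_id)

#' @rdname VoltageExperiment
#' @export
setMethod("treatmentLabels", "VoltageExperiment", function(x)
  SummarizedExperiment::colData(x)$treatment)

#' @rdname VoltageExperiment
#' @export
setMethod("voltageMatrix", "VoltageExperiment", function(x)
  SummarizedExperiment::assay(x, "voltage"))

#' @rdname VoltageExperiment
#' @export
setMethod("missingMatrix", "VoltageExperiment", function(x)
  SummarizedExperiment::assay(x, "missing"))

setMethod("show", "VoltageExperiment", function(object) {
  trt <- table(treatmentLabels(object))
  cat("VoltageExperiment:", ncol(object), "tMFCs x", nrow(object),
      "timepoints\n")
  d <- dayTimes(object)
  cat("  days:", format(min(d)), "to", format(max(d)), "\n")
  cat("  treatments:",
      paste0(names(trt), " (", as.integer(trt), ")", collapse = ", "), "\n")
  nm <- sum(missingMatrix(object))
  if (nm > 0) cat("  flagged missing:", nm, "measurements\n")
  invisible(NULL)
})

#' Long-format view of a VoltageExperiment
#'
#' Flattens the voltage matrix into the long table the mixed-effects layer
#' and the CSV writer use, optionally restricted to an observation window.
#'
#' @param x a [VoltageExperiment-class].
#' @param window optional [observationWindow()]; rows outside
#'   `[startDay, endDay]` are dropped.
#' @param dropMissing drop rows whose measurement is flagged missing
#'   (default `TRUE`).
#' @return data.frame with columns `tmfc_id`, `treatment`, `day`,
#'   `voltage_mV`, `missing`.
#' @export
asLongData <- function(x, window = NULL, dropMissing = TRUE) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  d <- dayTimes(x)
  keep <- rep(TRUE, length(d))
  if (!is.null(window))
    keep <- d >= window$startDay & d <= window$endDay
  v <- voltageMatrix(x)[keep, , drop = FALSE]
  m <- missingMatrix(x)[keep, , drop = FALSE]
  out <- data.frame(
    tmfc_id = rep(tmfcIds(x), each = nrow(v)),
    treatment = rep(treatmentLabels(x), each = nrow(v)),
    day = rep(d[keep], times = ncol(v)),
    voltage_mV = as.vector(v),
    missing = as.vector(m),
    stringsAsFactors = FALSE)
  if (dropMissing) out <- out[!out$missing, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop treatments from an experiment
#'
#' Removes all tMFCs carrying the given labels, as in the subset retraining
#' analysis where hard-to-separate compounds are excluded and the classifier
#' grid is re-run on the remainder.
#'
#' @param x a [VoltageExperiment-class].
#' @param dropLabels character vector of treatment labels to remove (may be
#'   empty, returning `x` unchanged).
#' @return the filtered [VoltageExperiment-class].
#' @export
subsetExperiment <- function(x, dropLabels = character()) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  if (length(dropLabels) == 0) return(x)
  keep <- !(treatmentLabels(x) %in% dropLabels)
  remaining <- unique(treatmentLabels(x)[keep])
  if (length(remaining) == 0)
    stop("cannot drop every treatment")
  if (length(remaining) < 2)
    stop("fewer than 2 treatments would remain")
  x[, keep]
}

#' Flag measurements as missing
#'
#' Marks timepoints of one series as interrupted, emulating gaps in data
#' acquisition. Times and stored voltages are unchanged; only the missing
#' mask is set, so downstream windowing drops windows covering the gap.
#'
#' @param x a [VoltageExperiment-class].
#' @param positions integer vector of 1-based row (timepoint) indices.
#' @param tmfc id of the series to flag; may be omitted for a single-column
#'   experiment.
#' @return the updated [VoltageExperiment-class].
#' @export
injectGaps <- function(x, positions, tmfc = NULL) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  if (is.null(tmfc)) {
    if (ncol(x) != 1L)
      stop("tmfc must be given for a multi-series experiment")
    col <- 1L
  } else {
    col <- match(tmfc, tmfcIds(x))
    if (is.na(col)) stop("unknown tmfc id: ", tmfc)
  }
  if (length(positions) == 0) return(x)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > nrow(x)))
    stop("gap positions out of range 1..", nrow(x))
  m <- missingMatrix(x)
  m[positions, col] <- TRUE
  SummarizedExperiment::assay(x, "missing") <- m
  x
}
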