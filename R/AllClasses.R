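#' @import methods
#' @importFrom stats var sd coef median quantile rnorm pchisq aov TukeyHSD
#'   as.formula model.matrix logLik AIC BIC setNames
NULL

#' VoltageExperiment: tMFC voltage traces as a SummarizedExperiment
#'
#' Container for terrestrial microbial fuel cell (tMFC) voltage time series.
#' Rows are timepoints (with the measurement day in `rowData`), columns are
#' individual tMFCs (with `tmfc_id` and `treatment` in `colData`), and two
#' assays hold the voltage matrix (mV) and a logical `missing` mask marking
#' interruptions in data acquisition.
#'
#' @slot ... inherits all slots from
#'   [SummarizedExperiment::SummarizedExperiment-class].
#'
#' @seealso [VoltageExperiment()], [simulateExperiment()], [readSeriesCSV()]
#' @export
setClass("VoltageExperiment", contains = "SummarizedExperiment")

setValidity("VoltageExperiment", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("voltage", "missing") %in% an))
    msgs <- c(msgs, "assays must include 'voltage' and 'missing'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("tmfc_id", "treatment") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain 'tmfc_id' and 'treatment'")
  rd <- SummarizedExperiment::rowData(object)
  if (!("day" %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must contain 'day'")
  } else {
    day <- rd$day
    if (anyNA(day) || any(!is.finite(day)))
      msgs <- c(msgs, "rowData day must be finite")
    else if (length(day) > 1L && any(diff(day) <= 0))
      msgs <- c(msgs, "rowData day must be strictly increasing")
  }
  if ("tmfc_id" %in% colnames(cd) && anyDuplicated(cd$tmfc_id))
    msgs <- c(msgs, "tmfc_id values must be unique")
  if (length(msgs)) msgs else TRUE
})

#' WindowSet: fixed-length voltage windows with labels
#'
#' A set of length-`w` voltage windows extracted from tMFC series by
#' stride-1 staggering. Each row of `values` is one window; `label`,
#' `sourceId` and `startIndex` record the treatment, the source tMFC and
#' the window's position in the (observation-window-restricted) source
#' series. `standardization` tags which scaling has been applied.
#'
#' @slot values numeric matrix, one window per row, `w` columns (mV, or
#'   standardized units once a [Standardizer] has been applied).
#' @slot label character, treatment label per window.
#' @slot sourceId character, source tMFC id per window.
#' @slot startIndex integer, 1-based start position per window.
#' @slot w integer(1), window length in points.
#' @slot standardization character(1) scheme tag ("raw", "all",
#'   "per_compound", "control").
#' @slot windowStart,windowEnd numeric(1), day range the windows came from.
#'
#' @seealso [stagger()], [buildDataset()], [splitDataset()]
#' @export
setClass("WindowSet",
  representation(values = "matrix", label = "character",
                 sourceId = "character", startIndex = "integer",
                 w = "integer", standardization = "character",
                 windowStart = "numeric", windowEnd = "numeric"))

setValidity("WindowSet", function(object) {
  msgs <- character()
  n <- nrow(object@values)
  if (ncol(object@values) != object@w)
    msgs <- c(msgs, "values must have w columns")
  if (length(object@label) != n || length(object@sourceId) != n ||
      length(object@startIndex) != n)
    msgs <- c(msgs, "label, sourceId and startIndex must match nrow(values)")
  if (anyNA(object@values))
    msgs <- c(msgs, "windows must not contain missing values")
  if (length(object@standardization) != 1L)
    msgs <- c(msgs, "standardization must be a single tag")
  if (length(msgs)) msgs else TRUE
})

#' Standardizer: fitted input-scaling parameters
#'
#' Holds the grouping scheme and per-group mean/sd used to z-score voltage
#' windows. `scheme = "raw"` stores nothing; `"all"` pools every training
#' value; `"per_compound"` keeps one (mean, sd) per treatment;
#' `"control"` scales every window by the control group's statistics.
#'
#' @slot scheme character(1), one of "raw", "all", "per_compound", "control".
#' @slot center,scale named numeric, per-group mean and sd (mV).
#'
#' @seealso [fitStandardizer()], [applyStandardizer()]
#' @export
setClass("Standardizer",
  representation(scheme = "character", center = "numeric", scale = "numeric"))

setValidity("Standardizer", function(object) {
  msgs <- character()
  if (!object@scheme %in% c("raw", "all", "per_compound", "control"))
    msgs <- c(msgs, "unknown scheme")
  if (length(object@center) != length(object@scale))
    msgs <- c(msgs, "center and scale must align")
  if (length(object@scale) && any(object@scale <= 0))
    msgs <- c(msgs, "stored sd values must be positive")
  if (length(msgs)) msgs else TRUE
})

#' RCEModel: prototype-neuron classifier state
#'
#' Software emulation of the NM500 chip's neuron array. Each committed
#' neuron is a prototype vector with a category and, for the RBF
#' (restricted-Coulomb-energy) method, an active influence field (AIF)
#' radius within which it fires. KNN models hold one neuron per training
#' window and ignore the AIF.
#'
#' @slot prototypes numeric matrix, one neuron per row, `w` columns.
#' @slot category character, treatment label per neuron.
#' @slot aif numeric, active influence field radius per neuron (NA for KNN).
#' @slot committedAt integer, training step at which each neuron committed.
#' @slot method character(1), "RBF" or "KNN".
#' @slot w integer(1), window length the model expects.
#' @slot labelSet character, treatment labels seen in training.
#' @slot config list, resolved [rceConfig()] (distance norm, field bounds,
#'   epochs, capacity, quantization range).
#' @slot epochs integer(1), epochs actually run; @slot converged logical(1).
#'
#' @seealso [trainRBF()], [trainKNN()], [classifyRBF()], [classifyKNN()]
#' @export
setClass("RCEModel",
  representation(prototypes = "matrix", category = "character",
                 aif = "numeric", committedAt = "integer",
                 method = "character", w = "integer",
                 labelSet = "character", config = "list",
                 epochs = "integer", converged = "logical"))

setValidity("RCEModel", function(object) {
  msgs <- character()
  n <- nrow(object@prototypes)
  if (length(object@category) != n || length(object@aif) != n ||
      length(object@committedAt) != n)
    msgs <- c(msgs, "per-neuron slots must match prototype count")
  if (!object@method %in% c("RBF", "KNN"))
    msgs <- c(msgs, "method must be RBF or KNN")
  if (ncol(object@prototypes) != object@w)
    msgs <- c(msgs, "prototypes must have w columns")
  if (object@method == "RBF" && n > 0) {
    if (anyNA(object@aif) || any(object@aif <= 0))
      msgs <- c(msgs, "RBF influence fields must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' LMEFit: summarized linear mixed-effects fit
#'
#' Wraps a maximum-likelihood `lmer` fit of voltage on days with a per-tMFC
#' random intercept (optionally a random slope), keeping the quantities the
#' analysis reports: fixed effects with Satterthwaite SEs/df/p, variance
#' components, log-likelihood, AIC/BIC and Nakagawa-Schielzeth marginal and
#' conditional R-squared.
#'
#' @slot fit the underlying `lmerMod`/`lmerModLmerTest` object.
#' @slot formulaTag character(1): "baseline", "treatment" or
#'   "single_treatment".
#' @slot fixedEffects data.frame with term, estimate, se, df, t, p.
#' @slot varianceComponents named numeric: sd_intercept, optional sd_slope,
#'   sd_residual.
#' @slot logLik,aic,bic numeric(1) (ML scale).
#' @slot r2Marginal,r2Conditional numeric(1).
#' @slot nObs,nGroups integer(1).
#' @slot singular logical(1), TRUE when the fit hit the variance boundary.
#'
#' @seealso [fitBaseline()], [fitTreatment()], [fitSingleTreatment()],
#'   [compareModels()]
#' @export
setClass("LMEFit",
  representation(fit = "ANY", formulaTag = "character",
                 fixedEffects = "data.frame",
                 varianceComponents = "numeric",
                 logLik = "numeric", aic = "numeric", bic = "numeric",
                 r2Marginal = "numeric", r2Conditional = "numeric",
                 nObs = "integer", nGroups = "integer",
                 singular = "logical"))

setValidity("LMEFit", function(object) {
  msgs <- character()
  if (!object@formulaTag %in% c("baseline", "treatment", "single_treatment"))
    msgs <- c(msgs, "unknown formulaTag")
  if (object@nGroups > object@nObs)
    msgs <- c(msgs, "more groups than observations")
  r2m <- object@r2Marginal; r2c <- object@r2Conditional
  if (is.finite(r2m) && is.finite(r2c) &&
      (r2m < -1e-8 || r2c > 1 + 1e-8 || r2m > r2c + 1e-8))
    msgs <- c(msgs, "need 0 <= marginal R2 <= conditional R2 <= 1")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionSummary: five-category classification outcome
#'
#' Percentages (and, when derived from predictions, counts) of test windows
#' falling in the five outcome bins used to score the classifier:
#' correct/incorrect crossed with Identified/Unclear confidence, plus
#' Unknown (no classification emitted).
#'
#' @slot pct named numeric(5): correct_identified, correct_unclear,
#'   incorrect_identified, incorrect_unclear, unknown (percent of test set).
#' @slot counts named numeric(5) of window counts (NA when the summary was
#'   built from published percentages rather than predictions).
#' @slot nTest numeric(1), test set size (NA when unknown).
#'
#' @seealso [confusionSummary()], [confusionFromPercents()],
#'   [generalAccuracy()], [identifiedAccuracy()]
#' @export
setClass("ConfusionSummary",
  representation(pct = "numeric", counts = "numeric", nTest = "numeric"))

.confusionBins <- c("correct_identified", "correct_unclear",
                    "incorrect_identified", "incorrect_unclear", "unknown")

setValidity("ConfusionSummary", function(object) {
  msgs <- character()
  if (!identical(names(object@pct), .confusionBins))
    msgs <- c(msgs, "pct must be named with the five outcome bins")
  else {
    if (any(object@pct < -1e-9)) msgs <- c(msgs, "percentages must be >= 0")
    # printed tables carry per-cell rounding to 0.1, so the row sum may be
    # off by up to one rounding unit
    if (abs(sum(object@pct) - 100) > 0.1 + 1e-9)
      msgs <- c(msgs, "percentages must sum to 100 (+/- 0.1 for rounding)")
  }
  if (!anyNA(object@counts)) {
    if (!identical(names(object@counts), .confusionBins))
      msgs <- c(msgs, "counts must be named with the five outcome bins")
    else if (!is.na(object@nTest) &&
             abs(sum(object@counts) - object@nTest) > 1e-9)
      msgs <- c(msgs, "counts must sum to nTest")
  }
  if (length(msgs)) msgs else TRUE
})
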