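#' Summarize predictions into the five outcome bins
#'
#' Crosses each prediction's confidence with its correctness:
#' Identified-correct, Unclear(Uncertain)-correct, Identified-incorrect,
#' Unclear-incorrect, and Unknown (no classification emitted).
#'
#' @param predictions data.frame from [classifyRBF()]/[classifyKNN()]
#'   (columns `label`, `confidence`).
#' @param truths character vector of true labels, same length.
#' @return a [ConfusionSummary-class].
#' @export
confusionSummary <- function(predictions, truths) {
  if (nrow(predictions) != length(truths))
    stop("predictions and truths differ in length (", nrow(predictions),
         " vs ", length(truths), ")")
  if (nrow(predictions) == 0L) stop("no predictions to summarize")
  conf <- predictions$confidence
  correct <- !is.na(predictions$label) & predictions$label == truths
  counts <- c(
    correct_identified   = sum(conf == "Identified" & correct),
    correct_unclear      = sum(conf == "Uncertain" & correct),
    incorrect_identified = sum(conf == "Identified" & !correct),
    incorrect_unclear    = sum(conf == "Uncertain" & !correct),
    unknown              = sum(conf == "Unknown"))
  n <- length(truths)
  methods::new("ConfusionSummary", pct = 100 * counts / n,
               counts = stats::setNames(as.numeric(counts), names(counts)),
               nTest = as.numeric(n))
}

#' Build a summary from published outcome percentages
#'
#' For re-scoring reported result rows whose underlying predictions are
#' unavailable: supply the five percentages directly (blank cells are 0).
#'
#' @param correctIdentified,correctUnclear,incorrectIdentified,
#'   incorrectUnclear,unknown percentages of the test set; must total 100
#'   up to one 0.1 rounding unit.
#' @return a [ConfusionSummary-class] (counts unknown).
#' @export
confusionFromPercents <- function(correctIdentified, correctUnclear = 0,
                                  incorrectIdentified = 0,
                                  incorrectUnclear = 0, unknown = 0) {
  methods::new("ConfusionSummary",
               pct = c(correct_identified = correctIdentified,
                       correct_unclear = correctUnclear,
                       incorrect_identified = incorrectIdentified,
                       incorrect_unclear = incorrectUnclear,
                       unknown = unknown),
               counts = rep(NA_real_, 5), nTest = NA_real_)
}

setMethod("show", "ConfusionSummary", function(object) {
  p <- object@pct
  cat("ConfusionSummary",
      if (!is.na(object@nTest)) paste0("(n = ", object@nTest, ")"), "\n")
  cat(sprintf("  correct:   %5.1f%% Identified, %5.1f%% Unclear\n",
              p[["correct_identified"]], p[["correct_unclear"]]))
  cat(sprintf("  incorrect: %5.1f%% Identified, %5.1f%% Unclear\n",
              p[["incorrect_identified"]], p[["incorrect_unclear"]]))
  cat(sprintf("  unknown:   %5.1f%%\n", p[["unknown"]]))
  invisible(NULL)
})

#' General Accuracy
#'
#' Percent correct among the classifications actually emitted:
#' `100 * (CI + CU) / (CI + CU + II + IU)`. Unknown outcomes carry no
#' classification and are excluded from the denominator.
#'
#' @param summary a [ConfusionSummary-class].
#' @return numeric(1), percent.
#' @export
generalAccuracy <- function(summary) {
  stopifnot(methods::is(summary, "ConfusionSummary"))
  p <- summary@pct
  den <- p[["correct_identified"]] + p[["correct_unclear"]] +
    p[["incorrect_identified"]] + p[["incorrect_unclear"]]
  if (den <= 0)
    stop("general accuracy undefined: every outcome is Unknown")
  100 * (p[["correct_identified"]] + p[["correct_unclear"]]) / den
}

#' Identified Accuracy
#'
#' Percent correct among Identified-confidence classifications only:
#' `100 * CI / (CI + II)`.
#'
#' @param summary a [ConfusionSummary-class].
#' @return numeric(1), percent.
#' @export
identifiedAccuracy <- function(summary) {
  stopifnot(methods::is(summary, "ConfusionSummary"))
  p <- summary@pct
  den <- p[["correct_identified"]] + p[["incorrect_identified"]]
  if (den <= 0)
    stop("identified accuracy undefined: no Identified outputs")
  100 * p[["correct_identified"]] / den
}

#' Per-true-label confusion table
#'
#' One row per true label with the percentage of its windows classified
#' correctly, marked Unknown, or sent to each other label -- itemising
#' where misclassifications go (e.g. DNT windows landing on petroleum).
#'
#' @inheritParams confusionSummary
#' @return data.frame: `truth`, `n`, `pct_correct`, `pct_unknown`, and one
#'   `pct_to_<label>` column per possible predicted label.
#' @export
confusionByClass <- function(predictions, truths) {
  if (nrow(predictions) != length(truths))
    stop("predictions and truths differ in length")
  if (length(truths) == 0L) stop("no predictions")
  labs <- sort(unique(c(truths, stats::na.omit(predictions$label))))
  rows <- lapply(sort(unique(truths)), function(tl) {
    sel <- truths == tl
    n <- sum(sel)
    pred <- predictions$label[sel]
    row <- data.frame(truth = tl, n = n,
                      pct_correct = 100 * sum(!is.na(pred) & pred == tl) / n,
                      pct_unknown = 100 * sum(is.na(pred)) / n,
                      stringsAsFactors = FALSE)
    for (ol in labs)
      row[[paste0("pct_to_", ol)]] <-
        if (ol == tl) NA_real_ else 100 * sum(!is.na(pred) & pred == ol) / n
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate the model-settings grid
#'
#' The full factorial of window length x standardization scheme x
#' classifier variant evaluated by the study design: 3 window lengths x 4
#' standardizations x 10 variants (RBF with the dominant, best-match and
#' unanimous interpreters plus minimum-consensus at m = 2 and 3; KNN with
#' k in {3, 4, 5, 10, 15}) = 120 model configurations.
#'
#' @param w window lengths (points).
#' @param standardization scheme tags.
#' @param knnK k values for the KNN variants.
#' @param minConsensus m values for the minimum-consensus interpreter.
#' @return data.frame with columns `w`, `standardization`, `method`,
#'   `interpreter`, `param` (k or m; NA otherwise), one row per model.
#' @export
gridSettings <- function(w = c(4L, 5L, 6L),
                         standardization = c("raw", "all", "per_compound",
                                             "control"),
                         knnK = c(3L, 4L, 5L, 10L, 15L),
                         minConsensus = c(2L, 3L)) {
  variants <- data.frame(method = "RBF",
                         interpreter = c("dominant", "best_match",
                                         "unanimous"),
                         param = NA_integer_, stringsAsFactors = FALSE)
  if (length(minConsensus))
    variants <- rbind(variants,
      data.frame(method = "RBF", interpreter = "min_consensus",
                 param = as.integer(minConsensus),
                 stringsAsFactors = FALSE))
  if (length(knnK))
    variants <- rbind(variants,
      data.frame(method = "KNN", interpreter = "dominant",
                 param = as.integer(knnK), stringsAsFactors = FALSE))
  out <- merge(merge(data.frame(w = as.integer(w)),
                     data.frame(standardization = standardization,
                                stringsAsFactors = FALSE)),
               variants)
  out <- out[order(out$w, out$standardization, out$method,
                   out$interpreter, out$param), ]
  rownames(out) <- NULL
  out
}

#' Run the full settings grid
#'
#' For every (window length, standardization) pair: build the staggered
#' dataset, split train/test, fit the standardizer on the training side
#' and apply it to both, train one RBF and one KNN neuron array, then
#' score every interpreter/k variant on the test windows. Training is
#' shared across variants of the same data configuration, exactly as a
#' single chip training run serves several read-out interpreters.
#'
#' @param x a [VoltageExperiment-class].
#' @param window an [observationWindow()].
#' @param settings a [gridSettings()] data.frame (subset it for partial
#'   runs).
#' @param seed root seed for splits and training shuffles.
#' @param testFraction,splitMode passed to [splitDataset()].
#' @param config an [rceConfig()].
#' @param paperMode fit the standardizer on the full pre-split dataset
#'   (the original single-pool procedure) instead of train-only.
#' @return data.frame: the settings columns plus the five outcome
#'   percentages, `general_accuracy`, `identified_accuracy`,
#'   `min_class_identified` (smallest per-true-label Identified share),
#'   `n_test`, `n_neurons` and an `error` column (NA unless that model
#'   failed; failures do not stop the grid).
#' @export
runGrid <- function(x, window = observationWindow(6, 31),
                    settings = gridSettings(), seed = 1L,
                    testFraction = 0.2,
                    splitMode = c("window", "replicate"),
                    config = rceConfig(), paperMode = FALSE) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  splitMode <- match.arg(splitMode)
  res <- settings
  metricCols <- c("pct_correct_identified", "pct_correct_unclear",
                  "pct_incorrect_identified", "pct_incorrect_unclear",
                  "pct_unknown", "general_accuracy", "identified_accuracy",
                  "min_class_identified")
  for (cn in metricCols) res[[cn]] <- NA_real_
  res$n_test <- NA_integer_; res$n_neurons <- NA_integer_
  res$error <- NA_character_

  for (wi in unique(settings$w)) {
    ws <- buildDataset(x, wi, window)
    parts <- splitDataset(ws, testFraction, splitMode,
                          seed = as.integer(seed) + wi)
    for (sc in unique(settings$standardization[settings$w == wi])) {
      rowsSel <- which(res$w == wi & res$standardization == sc)
      prep <- tryCatch({
        std <- fitStandardizer(if (paperMode) ws else parts$train, sc)
        list(train = applyStandardizer(parts$train, std),
             test = applyStandardizer(parts$test, std))
      }, error = function(e) e)
      if (inherits(prep, "error")) {
        res$error[rowsSel] <- conditionMessage(prep)
        next
      }
      truths <- windowLabels(prep$test)
      models <- list()
      for (ri in rowsSel) {
        method <- res$method[ri]
        out <- tryCatch({
          if (is.null(models[[method]])) {
            models[[method]] <- if (method == "RBF")
              trainRBF(prep$train, config,
                       shuffleSeed = as.integer(seed) + 100L * wi)
            else trainKNN(prep$train, config)
          }
          model <- models[[method]]
          preds <- if (method == "RBF")
            classifyRBF(model, windowValues(prep$test), res$interpreter[ri],
                        minConsensus = res$param[ri])
          else classifyKNN(model, windowValues(prep$test), k = res$param[ri])
          cs <- confusionSummary(preds, truths)
          byClass <- vapply(unique(truths), function(tl) {
            mean(preds$confidence[truths == tl] == "Identified") * 100
          }, numeric(1))
          list(cs = cs, preds = preds,
               minClassId = min(byClass), n = nNeurons(model))
        }, error = function(e) e)
        if (inherits(out, "error")) {
          res$error[ri] <- conditionMessage(out)
          next
        }
        p <- out$cs@pct
        res$pct_correct_identified[ri] <- p[["correct_identified"]]
        res$pct_correct_unclear[ri] <- p[["correct_unclear"]]
        res$pct_incorrect_identified[ri] <- p[["incorrect_identified"]]
        res$pct_incorrect_unclear[ri] <- p[["incorrect_unclear"]]
        res$pct_unknown[ri] <- p[["unknown"]]
        res$general_accuracy[ri] <-
          tryCatch(generalAccuracy(out$cs), error = function(e) NA_real_)
        res$identified_accuracy[ri] <-
          tryCatch(identifiedAccuracy(out$cs), error = function(e) NA_real_)
        res$min_class_identified[ri] <- out$minClassId
        res$n_test[ri] <- nWindows(prep$test)
        res$n_neurons[ri] <- out$n
      }
    }
  }
  res
}

#' Apply the model filters and rank
#'
#' Marks as excluded (never deletes) any model whose Unknown share exceeds
#' 50% of the test windows (a poor classifier) or whose Identified share
#' falls below 25% (insufficient confidence); both boundaries are strict
#' inequalities, so exactly 50% Unknown or 25% Identified is retained.
#' The remaining models are ranked by General then Identified accuracy.
#'
#' @param results a [runGrid()] data.frame.
#' @param perClassIdentified apply the 25% Identified rule to the weakest
#'   class (`min_class_identified`) instead of the model-wide share.
#' @return `results` with added `excluded`, `exclusion_reason` and `rank`
#'   (NA for excluded/failed models) columns, sorted by rank.
#' @export
filterModels <- function(results, perClassIdentified = FALSE) {
  idShare <- if (perClassIdentified) results$min_class_identified
    else results$pct_correct_identified + results$pct_incorrect_identified
  tooUnknown <- !is.na(results$pct_unknown) & results$pct_unknown > 50
  tooUnsure <- !is.na(idShare) & idShare < 25
  failed <- !is.na(results$error)
  results$excluded <- tooUnknown | tooUnsure | failed
  results$exclusion_reason <- NA_character_
  results$exclusion_reason[tooUnsure] <- "Identified share < 25%"
  results$exclusion_reason[tooUnknown] <- "Unknown share > 50%"
  results$exclusion_reason[failed] <- "model failed"
  keep <- which(!results$excluded)
  ord <- keep[order(-results$general_accuracy[keep],
                    -results$identified_accuracy[keep])]
  results$rank <- NA_integer_
  results$rank[ord] <- seq_along(ord)
  results[order(results$rank, na.last = TRUE), ]
}

#' Published benchmark model rows
#'
#' The ranked classifier results reported for the original tMFC
#' incubation (top ten by General accuracy and by Identified accuracy),
#' as outcome-bin percentages with the printed accuracy columns. The
#' underlying voltage data were never deposited, so these rows serve as
#' an arithmetic benchmark for the accuracy formulas
#' ([generalAccuracy()], [identifiedAccuracy()]), not as a reproduction
#' target.
#'
#' @return data.frame with ranking table, settings, the five outcome
#'   percentages and the printed `accuracy_all` / `accuracy_id` values.
#' @export
referenceModelResults <- function() {
  utils::read.csv(system.file("extdata", "reference_model_results.csv",
                              package = "tmfcsense", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
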