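#' Write voltage series to long-format CSV
#'
#' Canonical on-disk form of an experiment: one row per (tMFC, timepoint)
#' with columns `tmfc_id,treatment,day,voltage_mV,missing` (missing as
#' 0/1, '.' decimal, full numeric precision).
#'
#' @param x a [VoltageExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeriesCSV <- function(x, path) {
  d <- asLongData(x, dropMissing = FALSE)
  d$missing <- as.integer(d$missing)
  utils::write.csv(format(d, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read voltage series from long-format CSV
#'
#' Inverse of [writeSeriesCSV()]. Series are grouped by `tmfc_id`, times
#' sorted, and assembled onto the union day grid; days absent from a
#' series are flagged missing. Malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file with header
#'   `tmfc_id,treatment,day,voltage_mV,missing`.
#' @return a [VoltageExperiment-class].
#' @export
readSeriesCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(tmfc_id = "character",
                                      treatment = "character"))
  needed <- c("tmfc_id", "treatment", "day", "voltage_mV", "missing")
  absent <- setdiff(needed, colnames(d))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "))
  if (nrow(d) == 0L) stop("no data rows in ", path)
  badDay <- which(!is.finite(suppressWarnings(as.numeric(d$day))))
  if (length(badDay))
    stop("unparseable day at data row(s): ",
         paste(utils::head(badDay, 5), collapse = ", "))
  d$day <- as.numeric(d$day)
  d$voltage_mV <- suppressWarnings(as.numeric(d$voltage_mV))
  d$missing <- as.integer(d$missing) != 0L
  badV <- which(is.na(d$voltage_mV) & !d$missing)
  if (length(badV))
    stop("unparseable voltage at data row(s): ",
         paste(utils::head(badV, 5), collapse = ", "))
  dup <- duplicated(d[, c("tmfc_id", "day")])
  if (any(dup))
    stop("duplicate (tmfc_id, day) at data row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  ids <- unique(d$tmfc_id)
  days <- sort(unique(d$day))
  v <- matrix(NA_real_, length(days), length(ids))
  m <- matrix(TRUE, length(days), length(ids))
  trt <- character(length(ids))
  for (j in seq_along(ids)) {
    rows <- d[d$tmfc_id == ids[j], ]
    tl <- unique(rows$treatment)
    if (length(tl) != 1L)
      stop("tmfc ", ids[j], " carries multiple treatment labels")
    trt[j] <- tl
    ri <- match(rows$day, days)
    v[ri, j] <- rows$voltage_mV
    m[ri, j] <- rows$missing
  }
  VoltageExperiment(v, day = days, treatment = trt, tmfcId = ids,
                    missing = m)
}

#' Write grid results in the ranked report layout
#'
#' Serializes a (typically [filterModels()]-ranked) grid table using the
#' report column layout
#' `#pts,Standard.,Method,Interpreter,CorrectID,CorrectUnclear,
#' IncorrectID,IncorrectUnclear,Unknown,AccAll,AccID`.
#'
#' @param results a [runGrid()]/[filterModels()] data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGridCSV <- function(results, path) {
  interp <- c(dominant = "D", best_match = "BM", unanimous = "U",
              min_consensus = "MC")
  lab <- interp[results$interpreter]
  lab[results$interpreter == "min_consensus"] <-
    paste0("MC-", results$param[results$interpreter == "min_consensus"])
  method <- results$method
  method[method == "KNN"] <- paste0("KNN-", results$param[method == "KNN"])
  out <- data.frame(
    `#pts` = paste0(results$w, "pt"),
    Standard. = results$standardization, Method = method,
    Interpreter = lab,
    CorrectID = round(results$pct_correct_identified, 1),
    CorrectUnclear = round(results$pct_correct_unclear, 1),
    IncorrectID = round(results$pct_incorrect_identified, 1),
    IncorrectUnclear = round(results$pct_incorrect_unclear, 1),
    Unknown = round(results$pct_unknown, 1),
    AccAll = round(results$general_accuracy, 1),
    AccID = round(results$identified_accuracy, 1),
    check.names = FALSE, stringsAsFactors = FALSE)
  if ("excluded" %in% colnames(results)) {
    out$Excluded <- as.integer(results$excluded)
    out$Rank <- results$rank
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON document with optional blocks `generator` (fields of
#' [generatorConfig()]), `window` (`startDay`, `endDay`), `split`
#' (`testFraction`, `mode`), `grid` (fields of [gridSettings()]) and
#' top-level `seed`. Omitted blocks fall back to the study defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  pipelineConfig(
    generator = obj$generator, window = obj$window, split = obj$split,
    grid = obj$grid, seed = obj$seed %||% 1L,
    ingest = obj$ingest)
}

#' Assemble a pipeline configuration
#'
#' @param generator `NULL` for [defaultGeneratorConfig()], a
#'   `GeneratorConfig`, or a list of [generatorConfig()] arguments.
#' @param window `NULL` for days 6-31, `"auto"` to use
#'   [findStableOnset()], or a list with `startDay`/`endDay`.
#' @param split list with `testFraction` and `mode`.
#' @param grid `NULL` for the full 120-model grid or a list of
#'   [gridSettings()] arguments.
#' @param seed root seed for the whole run.
#' @param ingest optional path to a series CSV used instead of the
#'   generator.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(generator = NULL, window = NULL,
                           split = list(testFraction = 0.2,
                                        mode = "window"),
                           grid = NULL, seed = 1L, ingest = NULL) {
  seed <- as.integer(seed)
  gen <- if (inherits(generator, "GeneratorConfig")) generator
    else if (is.null(generator)) defaultGeneratorConfig(seed = seed)
    else do.call(generatorConfig, generator)
  win <- if (is.null(window)) observationWindow(6, 31)
    else if (identical(window, "auto")) "auto"
    else if (inherits(window, "ObservationWindow")) window
    else observationWindow(window$startDay, window$endDay)
  gs <- if (is.null(grid)) gridSettings() else do.call(gridSettings, grid)
  split$testFraction <- split$testFraction %||% 0.2
  split$mode <- split$mode %||% "window"
  structure(list(generator = gen, window = win, split = split,
                 grid = gs, seed = seed, ingest = ingest),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Chains every stage end to end: simulate (or ingest) the experiment,
#' compute grouped stability slopes and the observation window, build and
#' score the classifier grid, apply the model filters, and fit the
#' mixed-effects layer (baseline vs treatment comparison, per-treatment
#' fits, end-state ANOVA + Tukey). All tables are written under
#' `outputDir` along with a JSON manifest of seeds and settings, so a run
#' is reproducible from the manifest alone.
#'
#' @param config a [pipelineConfig()] (default: full study conditions).
#' @param outputDir directory for result files (created if needed).
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results (`experiment`,
#'   `window`, `slopes`, `grid`, `ranked`, `lme`, `anova`, `files`).
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = tempdir(),
                        quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- list()

  ve <- stage("data", {
    if (!is.null(config$ingest)) readSeriesCSV(config$ingest)
    else simulateExperiment(config$generator)
  })
  say("data: ", ncol(ve), " series x ", nrow(ve), " timepoints")
  files$series <- file.path(outputDir, "series.csv")
  writeSeriesCSV(ve, files$series)

  slopes <- stage("stability", groupSlopes(ve, 4L))
  files$slopes <- file.path(outputDir, "stability_slopes.csv")
  utils::write.csv(slopes, files$slopes, row.names = FALSE)
  win <- stage("stability", {
    if (identical(config$window, "auto")) findStableOnset(ve, 4L)
    else config$window
  })
  say(sprintf("observation window: days [%g, %g]", win$startDay,
              win$endDay))
  files$window <- file.path(outputDir, "observation_window.json")
  jsonlite::write_json(unclass(win), files$window, auto_unbox = TRUE,
                       digits = NA)

  grid <- stage("grid", runGrid(ve, win, config$grid, seed = config$seed,
                                testFraction = config$split$testFraction,
                                splitMode = config$split$mode))
  ranked <- filterModels(grid)
  files$grid <- file.path(outputDir, "grid_results.csv")
  writeGridCSV(ranked, files$grid)
  say("grid: ", nrow(grid), " models, ", sum(!ranked$excluded),
      " retained after filters")

  lme <- stage("lme", {
    base <- fitBaseline(ve, win)
    trt <- fitTreatment(ve, win)
    lrt <- compareModels(base, trt)
    singles <- lapply(unique(treatmentLabels(ve)), function(tl)
      fitSingleTreatment(ve, tl, win))
    names(singles) <- unique(treatmentLabels(ve))
    list(baseline = base, treatment = trt, lrt = lrt, single = singles)
  })
  files$lme <- file.path(outputDir, "lme_fixed_effects.csv")
  feTab <- do.call(rbind, c(
    list(cbind(model = "baseline", fixedEffects(lme$baseline)),
         cbind(model = "treatment", fixedEffects(lme$treatment))),
    lapply(names(lme$single), function(nm)
      cbind(model = paste0("single_", nm), fixedEffects(lme$single[[nm]])))))
  utils::write.csv(feTab, files$lme, row.names = FALSE)
  files$lrt <- file.path(outputDir, "model_comparison.json")
  jsonlite::write_json(list(
    lrt = unclass(lme$lrt),
    baseline = list(aic = lme$baseline@aic, bic = lme$baseline@bic,
                    logLik = lme$baseline@logLik,
                    r2 = as.list(rSquared(lme$baseline))),
    treatment = list(aic = lme$treatment@aic, bic = lme$treatment@bic,
                     logLik = lme$treatment@logLik,
                     r2 = as.list(rSquared(lme$treatment)))),
    files$lrt, auto_unbox = TRUE, digits = NA)

  anv <- stage("anova", endStateAnova(ve))
  files$tukey <- file.path(outputDir, "end_state_tukey.csv")
  utils::write.csv(anv$tukey, files$tukey, row.names = FALSE)

  files$manifest <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(list(
    package = "tmfcsense",
    version = as.character(utils::packageVersion("tmfcsense")),
    seed = config$seed,
    generator = lapply(unclass(config$generator), function(z)
      if (is.list(z)) lapply(z, as.vector) else as.vector(z)),
    window = if (identical(config$window, "auto")) "auto"
             else unclass(win),
    split = config$split,
    n_grid_models = nrow(config$grid)),
    files$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(experiment = ve, window = win, slopes = slopes,
                 grid = grid, ranked = ranked, lme = lme, anova = anv,
                 files = files))
}
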