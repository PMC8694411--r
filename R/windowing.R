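#' Staggered stride-1 windows from one series
#'
#' Splices a voltage series into every fixed-length window of `w`
#' consecutive points (stride 1), the augmentation that turns one trace
#' into `n - w + 1` overlapping training examples while preserving the
#' internal voltage fluctuation. Windows containing a flagged-missing
#' point, or spanning a timing gap larger than 1.5x the median sampling
#' interval, are excluded.
#'
#' @param x a single-column [VoltageExperiment-class] (or use
#'   [buildDataset()] for many series).
#' @param w window length in points; 4, 5 and 6 (2/2.5/3 days at
#'   twice-daily sampling) are the study's choices, other values are
#'   allowed with a warning.
#' @param window an [observationWindow()]; the series is restricted to
#'   `[startDay, endDay]` first.
#' @return a [WindowSet-class] (possibly with zero windows).
#' @export
stagger <- function(x, w, window = observationWindow(6, 31)) {
  stopifnot(methods::is(x, "VoltageExperiment"), ncol(x) == 1L)
  w <- as.integer(w)
  if (w < 2L) stop("w must be >= 2")
  if (!w %in% 4:6)
    warning("window length ", w, " is outside the studied range 4-6")
  d <- dayTimes(x)
  keep <- which(d >= window$startDay & d <= window$endDay)
  d <- d[keep]
  v <- voltageMatrix(x)[keep, 1]
  miss <- missingMatrix(x)[keep, 1]
  n <- length(v)
  emptySet <- methods::new("WindowSet",
    values = matrix(numeric(), 0, w), label = character(),
    sourceId = character(), startIndex = integer(), w = w,
    standardization = "raw",
    windowStart = window$startDay, windowEnd = window$endDay)
  if (n < w) return(emptySet)
  gapAfter <- c(diff(d) > 1.5 * median(diff(d)), FALSE)
  starts <- integer(); rows <- list()
  for (s in seq_len(n - w + 1L)) {
    span <- s:(s + w - 1L)
    if (any(miss[span])) next
    if (any(gapAfter[span[-w]])) next
    starts <- c(starts, s)
    rows[[length(rows) + 1L]] <- v[span]
  }
  if (!length(starts)) return(emptySet)
  methods::new("WindowSet",
    values = do.call(rbind, rows),
    label = rep(treatmentLabels(x), length(starts)),
    sourceId = rep(tmfcIds(x), length(starts)),
    startIndex = starts, w = w, standardization = "raw",
    windowStart = window$startDay, windowEnd = window$endDay)
}

#' Build the windowed dataset for a whole experiment
#'
#' Runs [stagger()] over every series and concatenates the results with
#' treatment labels attached.
#'
#' @param x a [VoltageExperiment-class] with at least one series.
#' @inheritParams stagger
#' @return a [WindowSet-class].
#' @examples
#' ve <- simulateExperiment(defaultGeneratorConfig(seed = 1))
#' ws <- buildDataset(ve, w = 6)
#' nWindows(ws)
#' @export
buildDataset <- function(x, w, window = observationWindow(6, 31)) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  if (ncol(x) == 0L) stop("empty experiment")
  sets <- lapply(seq_len(ncol(x)), function(j) stagger(x[, j], w, window))
  methods::new("WindowSet",
    values = do.call(rbind, lapply(sets, function(s) s@values)),
    label = unlist(lapply(sets, function(s) s@label)),
    sourceId = unlist(lapply(sets, function(s) s@sourceId)),
    startIndex = unlist(lapply(sets, function(s) s@startIndex)),
    w = as.integer(w), standardization = "raw",
    windowStart = window$startDay, windowEnd = window$endDay)
}

#' @rdname WindowSet
#' @export
setMethod("nWindows", "WindowSet", function(x) nrow(x@values))

#' @rdname WindowSet
#' @export
setMethod("windowValues", "WindowSet", function(x) x@values)

#' @rdname WindowSet
#' @export
setMethod("windowLabels", "WindowSet", function(x) x@label)

#' @rdname WindowSet
#' @export
setMethod("windowSources", "WindowSet", function(x) x@sourceId)

#' @rdname WindowSet
#' @param i window indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, values = x@values[i, , drop = FALSE],
                      label = x@label[i], sourceId = x@sourceId[i],
                      startIndex = x@startIndex[i])
})

setMethod("show", "WindowSet", function(object) {
  cat("WindowSet:", nWindows(object), "windows of", object@w, "points",
      sprintf("(days [%g, %g], %s)\n", object@windowStart,
              object@windowEnd, object@standardization))
  if (nWindows(object)) {
    tab <- table(object@label)
    cat("  labels:", paste0(names(tab), " (", as.integer(tab), ")",
                            collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Train/test split of a windowed dataset
#'
#' `mode = "window"` reproduces the study's split: a uniform random 20%
#' of the windows, sampled without replacement. Because staggered windows
#' overlap, that split leaks near-duplicates between the partitions, so
#' `mode = "replicate"` is offered as the leakage-free alternative: whole
#' tMFCs are assigned to the test side (in seeded random order) until the
#' window fraction first reaches `testFraction`.
#'
#' @param x a [WindowSet-class].
#' @param testFraction fraction of windows for the test set, in (0, 1).
#' @param mode `"window"` (default, study-faithful) or `"replicate"`.
#' @param seed RNG seed for the assignment.
#' @return `list(train =, test =)` of [WindowSet-class]; a partition of
#'   `x`.
#' @export
splitDataset <- function(x, testFraction = 0.2,
                         mode = c("window", "replicate"), seed = 1L) {
  stopifnot(methods::is(x, "WindowSet"))
  mode <- match.arg(mode)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  n <- nWindows(x)
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(as.integer(seed))
  if (mode == "window") {
    nTest <- round(testFraction * n)
    if (nTest == 0L || nTest == n)
      stop("dataset too small for a ", testFraction, " split (", n,
           " windows)")
    testIdx <- sort(sample.int(n, nTest))
  } else {
    ids <- unique(x@sourceId)
    if (length(ids) < 2L) stop("replicate split needs >= 2 source tMFCs")
    ord <- sample(ids)
    counts <- table(x@sourceId)[ord]
    cum <- cumsum(as.integer(counts)) / n
    take <- seq_len(which(cum >= testFraction)[1])
    testIdx <- which(x@sourceId %in% ord[take])
    if (length(testIdx) == n) stop("replicate split consumed every window")
  }
  list(train = x[setdiff(seq_len(n), testIdx)], test = x[testIdx])
}
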