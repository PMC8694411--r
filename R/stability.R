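#' Observation window
#'
#' Day range over which the voltage output is treated as stable and all
#' downstream analysis (windowing, standardization, classification, LME
#' fits) is run. The study default is days 6 to 31; [findStableOnset()]
#' derives a data-driven alternative from grouped slopes.
#'
#' @param startDay,endDay day range, `startDay < endDay`.
#' @param thresholdmV slope magnitude (mV per measurement) under which a
#'   group counts as stable.
#' @param quorum fraction of replicate slopes that must be stable.
#' @param stable `FALSE` when no onset satisfying the rule was found and
#'   the full range was returned instead.
#' @return a list of class `"ObservationWindow"`.
#' @export
observationWindow <- function(startDay, endDay, thresholdmV = 0.5,
                              quorum = 0.5, stable = TRUE) {
  if (!is.finite(startDay) || !is.finite(endDay) || startDay >= endDay)
    stop("need finite startDay < endDay")
  structure(list(startDay = as.numeric(startDay),
                 endDay = as.numeric(endDay),
                 thresholdmV = thresholdmV, quorum = quorum,
                 stable = isTRUE(stable)),
            class = "ObservationWindow")
}

#' @export
print.ObservationWindow <- function(x, ...) {
  cat(sprintf("ObservationWindow: days [%g, %g]%s\n", x$startDay, x$endDay,
              if (x$stable) "" else " (no stable onset found; full range)"))
  invisible(x)
}

#' Slopes over consecutive measurement groups
#'
#' Partitions each series' non-missing measurements into consecutive,
#' non-overlapping groups of `groupSize` points (trailing remainder
#' dropped) and computes the ordinary-least-squares slope of voltage
#' against measurement index within each group. At twice-daily sampling,
#' group sizes 3/4/5/6 correspond to 1.5/2/2.5/3 days. These grouped
#' slopes are the raw material for locating the stable observation window.
#'
#' @param x a [VoltageExperiment-class] (one or many series).
#' @param groupSize points per group; 3-6 are the supported study choices.
#' @param units `"per_measurement"` (default; the stability criterion is
#'   stated on this scale) or `"per_day"`.
#' @param perReplicate compute slopes per individual series (default) or on
#'   each treatment's mean trace.
#' @return data.frame with `tmfc_id`, `treatment`, `group_index`,
#'   `group_size`, `start_day`, `slope`. Series with fewer than `groupSize`
#'   usable points contribute no rows (with a warning).
#' @export
groupSlopes <- function(x, groupSize = 4L, units = c("per_measurement",
                        "per_day"), perReplicate = TRUE) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  units <- match.arg(units)
  groupSize <- as.integer(groupSize)
  if (!groupSize %in% 3:6)
    stop("groupSize must be one of 3, 4, 5, 6")
  d <- dayTimes(x)
  v <- voltageMatrix(x)
  m <- missingMatrix(x)
  if (!perReplicate) {
    # average over replicates within treatment, ignoring flagged points
    labs <- unique(treatmentLabels(x))
    vm <- sapply(labs, function(lab) {
      cols <- which(treatmentLabels(x) == lab)
      vv <- v[, cols, drop = FALSE]
      vv[m[, cols, drop = FALSE]] <- NA
      rowMeans(vv, na.rm = TRUE)
    })
    v <- as.matrix(vm)
    m <- is.na(v) | !is.finite(v)
    ids <- paste0("mean_", labs)
    trts <- labs
  } else {
    ids <- tmfcIds(x)
    trts <- treatmentLabels(x)
  }
  idx0 <- seq_len(groupSize) - 1  # within-group measurement index
  sxx <- sum((idx0 - mean(idx0))^2)
  out <- list()
  for (j in seq_len(ncol(v))) {
    ok <- which(!m[, j] & is.finite(v[, j]))
    nG <- length(ok) %/% groupSize
    if (nG == 0L) {
      warning("series ", ids[j], " has fewer than ", groupSize,
              " usable points; skipped")
      next
    }
    for (g in seq_len(nG)) {
      pts <- ok[((g - 1L) * groupSize + 1L):(g * groupSize)]
      y <- v[pts, j]
      slope <- sum((idx0 - mean(idx0)) * (y - mean(y))) / sxx
      if (units == "per_day") {
        dt <- mean(diff(d[pts]))
        slope <- slope / dt
      }
      out[[length(out) + 1L]] <- data.frame(
        tmfc_id = ids[j], treatment = trts[j], group_index = g,
        group_size = groupSize, start_day = d[pts[1]], slope = slope,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(tmfc_id = character(), treatment = character(),
                      group_index = integer(), group_size = integer(),
                      start_day = numeric(), slope = numeric()))
  do.call(rbind, out)
}

#' Find the stable observation onset
#'
#' Scans grouped slopes for the earliest group boundary after which the
#' voltage output stays stable: from that group index onward, the fraction
#' of replicate slopes with |slope| <= `threshold` exceeds `quorum` in
#' every group. Returns the corresponding [observationWindow()]; if no
#' such onset exists the full day range is returned flagged
#' `stable = FALSE`.
#'
#' @param x a [VoltageExperiment-class].
#' @param groupSize points per slope group (3-6).
#' @param threshold stability threshold in mV per measurement (default 0.5,
#'   the "0 +/- 0.5 mV" criterion).
#' @param quorum fraction of slopes that must be stable; "most" is read as
#'   a strict majority (default 0.5, exceeded strictly).
#' @param perReplicate see [groupSlopes()].
#' @return an [observationWindow()].
#' @export
findStableOnset <- function(x, groupSize = 4L, threshold = 0.5,
                            quorum = 0.5, perReplicate = TRUE) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty experiment")
  if (threshold <= 0) stop("threshold must be > 0")
  if (quorum <= 0 || quorum > 1) stop("quorum must lie in (0, 1]")
  sl <- groupSlopes(x, groupSize, perReplicate = perReplicate)
  if (nrow(sl) == 0L) stop("no slope groups could be formed")
  d <- dayTimes(x)
  endDay <- max(d)
  gIdx <- sort(unique(sl$group_index))
  fracStable <- vapply(gIdx, function(g) {
    s <- sl$slope[sl$group_index == g]
    mean(abs(s) <= threshold)
  }, numeric(1))
  ok <- fracStable > quorum
  # earliest index from which every later group is stable
  onset <- NA_integer_
  for (i in seq_along(gIdx)) {
    if (all(ok[i:length(ok)])) { onset <- i; break }
  }
  if (is.na(onset))
    return(observationWindow(min(d), endDay, threshold, quorum,
                             stable = FALSE))
  startDay <- min(sl$start_day[sl$group_index == gIdx[onset]])
  if (startDay >= endDay) startDay <- min(d)
  observationWindow(startDay, endDay, threshold, quorum, stable = TRUE)
}
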