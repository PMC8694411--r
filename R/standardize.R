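#' Fit a standardization scheme on training windows
#'
#' Computes the z-score parameters for one of the four input-scaling
#' schemes the classifier comparison covers:
#' \describe{
#'   \item{raw}{no scaling (identity).}
#'   \item{all}{one (mean, sd) pooled over every voltage value in the
#'     training windows; the transformed training set has mean 0, sd 1.}
#'   \item{per_compound}{one (mean, sd) per treatment label; each
#'     compound's windows are centred on its own statistics.}
#'   \item{control}{the control group's (mean, sd) applied to every
#'     window, so non-control treatments keep a nonzero transformed mean
#'     that encodes their offset from the control.}
#' }
#' Parameters are fitted on the training partition only (and applied to
#' test via [applyStandardizer()]) so no test statistics leak into the
#' model; fit on the full pre-split dataset instead if a fidelity run of
#' the original single-pool procedure is wanted.
#'
#' @param train a [WindowSet-class] of training windows.
#' @param scheme one of `"raw"`, `"all"`, `"per_compound"`, `"control"`.
#' @param sdDenominator `"sample"` (n-1, default) or `"population"` (n).
#' @return a [Standardizer-class].
#' @export
fitStandardizer <- function(train, scheme = c("raw", "all", "per_compound",
                            "control"), sdDenominator = c("sample",
                            "population")) {
  stopifnot(methods::is(train, "WindowSet"))
  scheme <- match.arg(scheme)
  sdDenominator <- match.arg(sdDenominator)
  if (nWindows(train) == 0L) stop("training set is empty")
  sdFun <- function(v) {
    s <- stats::sd(v)
    if (sdDenominator == "population")
      s <- s * sqrt((length(v) - 1) / length(v))
    s
  }
  grpStats <- function(v, nm) {
    s <- sdFun(v)
    if (!is.finite(s) || s <= 0)
      stop("zero variance in standardization group '", nm, "'")
    c(mean(v), s)
  }
  if (scheme == "raw") {
    return(methods::new("Standardizer", scheme = "raw",
                        center = numeric(), scale = numeric()))
  }
  if (scheme == "all") {
    st <- grpStats(as.vector(train@values), "all")
    return(methods::new("Standardizer", scheme = "all",
                        center = c(all = st[1]), scale = c(all = st[2])))
  }
  if (scheme == "control") {
    sel <- train@label == "control"
    if (!any(sel)) stop("scheme 'control' requires control-labelled windows")
    st <- grpStats(as.vector(train@values[sel, , drop = FALSE]), "control")
    return(methods::new("Standardizer", scheme = "control",
                        center = c(control = st[1]),
                        scale = c(control = st[2])))
  }
  labs <- unique(train@label)
  st <- vapply(labs, function(lab) {
    grpStats(as.vector(train@values[train@label == lab, , drop = FALSE]),
             lab)
  }, numeric(2))
  methods::new("Standardizer", scheme = "per_compound",
               center = stats::setNames(st[1, ], labs),
               scale = stats::setNames(st[2, ], labs))
}

#' Apply a fitted standardizer to a windowed dataset
#'
#' Transforms every window value as `(v - mean_g) / sd_g` for its group
#' and updates the dataset's standardization tag.
#'
#' @param x a [WindowSet-class].
#' @param std a [Standardizer-class] from [fitStandardizer()].
#' @return the transformed [WindowSet-class].
#' @export
applyStandardizer <- function(x, std) {
  stopifnot(methods::is(x, "WindowSet"), methods::is(std, "Standardizer"))
  v <- x@values
  if (std@scheme == "raw") {
    # identity, but still tag the dataset
  } else if (std@scheme %in% c("all", "control")) {
    v <- (v - std@center[[1]]) / std@scale[[1]]
  } else {
    unseen <- setdiff(unique(x@label), names(std@center))
    if (length(unseen))
      stop("no per-compound parameters for label(s): ",
           paste(unseen, collapse = ", "))
    for (lab in unique(x@label)) {
      sel <- x@label == lab
      v[sel, ] <- (v[sel, , drop = FALSE] - std@center[[lab]]) /
        std@scale[[lab]]
    }
  }
  methods::initialize(x, values = v, standardization = std@scheme)
}

setMethod("show", "Standardizer", function(object) {
  cat("Standardizer: scheme", object@scheme, "\n")
  if (length(object@center)) {
    for (nm in names(object@center))
      cat(sprintf("  %s: mean %.4g, sd %.4g\n", nm, object@center[[nm]],
                  object@scale[[nm]]))
  }
  invisible(NULL)
})

#' Serialize / restore a standardizer
#'
#' JSON round-trip of the scheme and per-group parameters, so a scaling
#' fitted at training time can be reapplied at classification time.
#'
#' @param std a [Standardizer-class]; @param path file path.
#' @return `readStandardizer` returns the [Standardizer-class].
#' @export
writeStandardizer <- function(std, path) {
  stopifnot(methods::is(std, "Standardizer"))
  jsonlite::write_json(
    list(scheme = std@scheme, center = as.list(std@center),
         scale = as.list(std@scale)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeStandardizer
#' @export
readStandardizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("Standardizer", scheme = obj$scheme,
               center = unlist(obj$center) %||% numeric(),
               scale = unlist(obj$scale) %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
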