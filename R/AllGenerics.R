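#' @rdname VoltageExperiment
#' @param x a `VoltageExperiment`.
#' @export
setGeneric("dayTimes", function(x) standardGeneric("dayTimes"))

#' @rdname VoltageExperiment
#' @export
setGeneric("tmfcIds", function(x) standardGeneric("tmfcIds"))

#' @rdname VoltageExperiment
#' @export
setGeneric("treatmentLabels", function(x) standardGeneric("treatmentLabels"))

#' @rdname VoltageExperiment
#' @export
setGeneric("voltageMatrix", function(x) standardGeneric("voltageMatrix"))

#' @rdname VoltageExperiment
#' @export
setGeneric("missingMatrix", function(x) standardGeneric("missingMatrix"))

#' @rdname WindowSet
#' @param x a `WindowSet`.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname WindowSet
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))

#' @rdname WindowSet
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname WindowSet
#' @export
setGeneric("windowSources", function(x) standardGeneric("windowSources"))

#' Number of committed neurons in a model
#' @param x an [RCEModel].
#' @return integer(1).
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
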