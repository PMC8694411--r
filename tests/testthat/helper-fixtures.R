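# Shared fixtures, all built in code.

# single-series experiment from explicit voltages
tinySeries <- function(values, days = seq_along(values) - 1,
                       treatment = "control", id = "control_R1") {
  VoltageExperiment(matrix(values, ncol = 1), day = days,
                    treatment = treatment, tmfcId = id)
}

# the ten staggering-example voltages (control replicate R1, days 6-10.5)
exampleSeries <- function() {
  readSeriesCSV(system.file("extdata", "control_r1_days6to10.csv",
                            package = "tmfcsense", mustWork = TRUE))
}

exampleVoltages <- c(253.7, 245.1, 244.4, 259.9, 259.0, 250.4,
                     241.9, 252.6, 250.2, 253.4)

# a WindowSet built directly from a matrix
makeWindowSet <- function(values, labels, sources = NULL,
                          standardization = "raw") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(sources)) sources <- paste0(labels, "_s", seq_len(n))
  methods::new("WindowSet", values = values, label = labels,
               sourceId = sources, startIndex = rep(1L, n),
               w = ncol(values), standardization = standardization,
               windowStart = 0, windowEnd = 1)
}

# two well-separated gaussian clusters with different labels
clusterWindows <- function(n = 40, w = 4, sep = 20, sd = 1, seed = 42) {
  set.seed(seed)
  a <- matrix(rnorm(n * w, 0, sd), n, w)
  b <- matrix(rnorm(n * w, sep, sd), n, w)
  makeWindowSet(rbind(a, b), rep(c("A", "B"), each = n),
                sources = rep(c("A_R1", "B_R1"), each = n))
}

# hand-constructed RBF model: every neuron explicit
manualRBFModel <- function(prototypes, category, aif,
                           distance = "L1") {
  cfg <- unclass(rceConfig(distance = distance, maxIF = max(aif),
                           minIF = min(aif) / 1000))
  methods::new("RCEModel", prototypes = as.matrix(prototypes),
               category = category, aif = aif,
               committedAt = seq_along(category), method = "RBF",
               w = ncol(as.matrix(prototypes)),
               labelSet = sort(unique(category)), config = cfg,
               epochs = 1L, converged = TRUE)
}

# degenerate (noise-free) generator for exact-line checks
noiselessConfig <- function(alpha = 339.94, beta = 1.73,
                            offsets = list(control = c(0, 0)),
                            transient = NULL, ...) {
  generatorConfig(alpha = alpha, beta = beta, treatmentOffsets = offsets,
                  sdA = 0, sdB = 0, rhoAB = 0, sdEps = 0,
                  transient = transient, seed = 1L, ...)
}
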