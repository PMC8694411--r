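#' Configuration for the RCE / KNN neuron array
#'
#' Settings for the software emulation of the NM500 neuromorphic chip.
#' The chip compares inputs to committed prototype neurons with a
#' Manhattan (L1) metric; L-infinity is offered as the alternative norm.
#' The influence-field bounds control how far an RBF neuron can fire:
#' when left `NULL`, `maxIF` is resolved at training time to the 95th
#' percentile of pairwise training distances (scale-adaptive, so raw mV
#' and z-scored inputs behave alike) and `minIF` to `1e-3 * maxIF`.
#' `quantize8bit` emulates the chip's 8-bit component registers by
#' clipping/scaling inputs to integers 0-255 before distances are taken.
#'
#' @param distance `"L1"` (default, the hardware norm) or `"Linf"`.
#' @param maxIF initial/maximum influence field radius (`NULL` = auto).
#' @param minIF floor radius, > 0 (`NULL` = auto).
#' @param maxEpochs maximum passes over the training set (>= 1).
#' @param maxNeurons neuron capacity; training errors out beyond it.
#' @param quantize8bit logical, emulate 8-bit input quantization.
#' @return a list of class `"RCEConfig"`.
#' @export
rceConfig <- function(distance = c("L1", "Linf"), maxIF = NULL,
                      minIF = NULL, maxEpochs = 10L, maxNeurons = 10000L,
                      quantize8bit = FALSE) {
  distance <- match.arg(distance)
  if (!is.null(maxIF) && (!is.finite(maxIF) || maxIF <= 0))
    stop("maxIF must be > 0")
  if (!is.null(minIF) && (!is.finite(minIF) || minIF <= 0))
    stop("minIF must be > 0")
  if (!is.null(minIF) && !is.null(maxIF) && minIF > maxIF)
    stop("need minIF <= maxIF")
  if (maxEpochs < 1) stop("maxEpochs must be >= 1")
  structure(list(distance = distance, maxIF = maxIF, minIF = minIF,
                 maxEpochs = as.integer(maxEpochs),
                 maxNeurons = as.integer(maxNeurons),
                 quantize8bit = isTRUE(quantize8bit),
                 qMin = NULL, qMax = NULL),
            class = "RCEConfig")
}

.quantize <- function(x, qMin, qMax) {
  if (qMax <= qMin) qMax <- qMin + 1
  q <- round((x - qMin) / (qMax - qMin) * 255)
  pmin(pmax(q, 0), 255)
}

#' Distance between two component vectors
#'
#' The norm the neuron array uses: L1 (sum of absolute component
#' differences, the NM500 hardware convention) or L-infinity (largest
#' component difference). Under 8-bit quantization components are first
#' mapped to integers 0-255 over the configured range and the distance is
#' an integer.
#'
#' @param a,b numeric vectors of equal length.
#' @param config an [rceConfig()]; for quantized distances its `qMin`/
#'   `qMax` must be resolved (as in a trained model's config).
#' @return numeric(1) distance.
#' @export
rceDistance <- function(a, b, config = rceConfig()) {
  if (length(a) != length(b))
    stop("vectors differ in length (", length(a), " vs ", length(b), ")")
  if (isTRUE(config$quantize8bit)) {
    if (is.null(config$qMin))
      stop("quantized distance needs a resolved qMin/qMax")
    a <- .quantize(a, config$qMin, config$qMax)
    b <- .quantize(b, config$qMin, config$qMax)
  }
  if (config$distance == "L1") sum(abs(a - b)) else max(abs(a - b))
}

# distances from one input to all prototype rows
.distToProtos <- function(protos, x, config) {
  dif <- abs(sweep(protos, 2L, x))
  if (config$distance == "L1") rowSums(dif) else apply(dif, 1L, max)
}

.prepInputs <- function(X, config) {
  if (isTRUE(config$quantize8bit)) .quantize(X, config$qMin, config$qMax)
  else X
}

#' Train the restricted-Coulomb-energy (RBF) neuron array
#'
#' Implements the standard RCE learning rule the chip's RBF mode is built
#' on. Training windows are presented in a seeded shuffled order; for each
#' input:
#' \enumerate{
#'   \item every currently firing neuron of a *different* category shrinks
#'     its active influence field (AIF) to the distance to the input (never
#'     below `minIF`), so it stops firing there;
#'   \item if no firing neuron of the *correct* category exists, a new
#'     neuron is committed at the input, with AIF set to the distance to
#'     the nearest different-category prototype, clamped to
#'     `[minIF, maxIF]` (`maxIF` when no other category exists yet).
#' }
#' Passes repeat until an epoch makes no commitment and no shrink, or
#' `maxEpochs` is reached. At convergence no wrong-category neuron fires
#' on any training window, so training-set recall through the best-match
#' interpreter is 100%.
#'
#' @param train a [WindowSet-class] of training windows.
#' @param config an [rceConfig()].
#' @param shuffleSeed seed fixing the presentation order.
#' @return an [RCEModel-class] with `method = "RBF"`.
#' @export
trainRBF <- function(train, config = rceConfig(), shuffleSeed = 1L) {
  stopifnot(methods::is(train, "WindowSet"))
  n <- nWindows(train)
  if (n == 0L) stop("training set is empty")
  config <- resolveRCEConfig(config, train)
  X <- .prepInputs(train@values, config)
  y <- train@label

  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(as.integer(shuffleSeed))
  ord <- sample.int(n)

  protos <- matrix(numeric(), 0, ncol(X))
  cat_ <- character(); aif <- numeric(); committed <- integer()
  step <- 0L; epoch <- 0L; converged <- FALSE
  while (epoch < config$maxEpochs) {
    epoch <- epoch + 1L
    changed <- FALSE
    for (i in ord) {
      step <- step + 1L
      x <- X[i, ]
      if (nrow(protos)) {
        d <- .distToProtos(protos, x, config)
        fired <- d < aif
        wrongFired <- which(fired & cat_ != y[i])
        if (length(wrongFired)) {
          newAif <- pmax(config$minIF, d[wrongFired])
          if (any(newAif != aif[wrongFired])) changed <- TRUE
          aif[wrongFired] <- newAif
        }
        hasCorrect <- any(fired & cat_ == y[i])
      } else {
        hasCorrect <- FALSE
      }
      if (!hasCorrect) {
        if (nrow(protos) >= config$maxNeurons)
          stop("neuron capacity exceeded (", nrow(protos), " neurons)")
        diffCat <- which(cat_ != y[i])
        newAif <- if (length(diffCat))
          min(max(min(d[diffCat]), config$minIF), config$maxIF)
        else config$maxIF
        protos <- rbind(protos, x)
        cat_ <- c(cat_, y[i]); aif <- c(aif, newAif)
        committed <- c(committed, step)
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  dimnames(protos) <- NULL
  methods::new("RCEModel", prototypes = protos, category = cat_,
               aif = aif, committedAt = committed, method = "RBF",
               w = train@w, labelSet = sort(unique(y)),
               config = unclass(config), epochs = epoch,
               converged = converged)
}

# fill in data-dependent config fields (field bounds, quantization range)
resolveRCEConfig <- function(config, train) {
  stopifnot(inherits(config, "RCEConfig") || is.list(config))
  X <- train@values
  if (isTRUE(config$quantize8bit) && is.null(config$qMin)) {
    config$qMin <- min(X); config$qMax <- max(X)
  }
  if (is.null(config$maxIF)) {
    n <- nrow(X)
    idx <- if (n > 400L) {
      # deterministic thinning for the percentile estimate
      unique(round(seq(1L, n, length.out = 400L)))
    } else seq_len(n)
    Xs <- .prepInputs(X[idx, , drop = FALSE], config)
    dm <- if (config$distance == "L1")
      as.matrix(stats::dist(Xs, method = "manhattan"))
    else as.matrix(stats::dist(Xs, method = "maximum"))
    pd <- dm[upper.tri(dm)]
    pd <- pd[pd > 0]
    config$maxIF <- if (length(pd)) stats::quantile(pd, 0.95, names = FALSE)
      else 1
  }
  if (is.null(config$minIF)) config$minIF <- 1e-3 * config$maxIF
  config
}

#' Train the KNN neuron array
#'
#' The chip's KNN mode commits one neuron per training window (prototype =
#' the window, category = its label); influence fields are unused because
#' every neuron fires for every input.
#'
#' @param train a [WindowSet-class].
#' @param config an [rceConfig()] (distance norm and quantization apply).
#' @return an [RCEModel-class] with `method = "KNN"`.
#' @export
trainKNN <- function(train, config = rceConfig()) {
  stopifnot(methods::is(train, "WindowSet"))
  n <- nWindows(train)
  if (n == 0L) stop("training set is empty")
  config <- resolveRCEConfig(config, train)
  X <- .prepInputs(train@values, config)
  dimnames(X) <- NULL
  methods::new("RCEModel", prototypes = X, category = train@label,
               aif = rep(NA_real_, n), committedAt = seq_len(n),
               method = "KNN", w = train@w,
               labelSet = sort(unique(train@label)),
               config = unclass(config), epochs = 1L, converged = TRUE)
}

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "RCEModel", function(x) nrow(x@prototypes))

setMethod("show", "RCEModel", function(object) {
  cat("RCEModel (", object@method, "): ", nNeurons(object),
      " neurons, w = ", object@w, ", labels: ",
      paste(object@labelSet, collapse = ", "), "\n", sep = "")
  if (object@method == "RBF")
    cat(sprintf("  epochs: %d (%s), AIF in [%.4g, %.4g]\n", object@epochs,
                if (object@converged) "converged" else "max epochs",
                min(object@aif), max(object@aif)))
  invisible(NULL)
})

#' Fired neurons for one input
#'
#' The firing rule of the RBF mode: a neuron fires when the distance from
#' the input to its prototype is strictly below its active influence
#' field. Exposed mainly for inspection and oracle-style verification.
#'
#' @param model a trained RBF [RCEModel-class].
#' @param x numeric vector of length `model@w` (raw input; quantization is
#'   applied internally if the model uses it).
#' @return data.frame of the fired neurons (`neuron`, `distance`,
#'   `category`, `aif`), sorted by ascending distance.
#' @export
firedNeurons <- function(model, x) {
  stopifnot(methods::is(model, "RCEModel"), model@method == "RBF")
  if (length(x) != model@w)
    stop("input length ", length(x), " != model w ", model@w)
  xq <- if (isTRUE(model@config$quantize8bit))
    .quantize(x, model@config$qMin, model@config$qMax) else x
  d <- .distToProtos(model@prototypes, xq, model@config)
  idx <- which(d < model@aif)
  out <- data.frame(neuron = idx, distance = d[idx],
                    category = model@category[idx], aif = model@aif[idx])
  out[order(out$distance, out$neuron), , drop = FALSE]
}

.pluralityLabel <- function(cats, dists) {
  tab <- table(cats)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # tie: the nearest neuron among the tied categories decides
  sel <- cats %in% top
  cats[sel][which.min(dists[sel])]
}

#' Classify inputs with the RBF method
#'
#' Fires the neuron array at each input and converts the fired set to a
#' label and a confidence bin: `Unknown` when no neuron fires (no
#' classification is given), `Identified` when all fired neurons agree,
#' `Uncertain` otherwise. The interpreter then selects the label:
#' \describe{
#'   \item{dominant}{plurality category among the fired neurons (ties go
#'     to the nearest tied neuron's category).}
#'   \item{best_match}{category of the fired neuron closest to the input.}
#'   \item{unanimous}{as dominant, but `Uncertain` results are re-binned
#'     to `Unknown` (no label).}
#'   \item{min_consensus}{as dominant, but the plurality category must
#'     have at least `minConsensus` fired neurons, else `Unknown`.}
#' }
#'
#' @param model a trained RBF [RCEModel-class].
#' @param x numeric vector of length `w`, or a matrix with one input per
#'   row (e.g. [windowValues()] of a test set).
#' @param interpreter one of `"dominant"`, `"best_match"`, `"unanimous"`,
#'   `"min_consensus"`.
#' @param minConsensus required agreeing-neuron count for
#'   `"min_consensus"`.
#' @return data.frame with one row per input: `label` (NA for Unknown),
#'   `confidence` ("Identified"/"Uncertain"/"Unknown"), `n_fired`,
#'   `best_distance`.
#' @export
classifyRBF <- function(model, x,
                        interpreter = c("dominant", "best_match",
                                        "unanimous", "min_consensus"),
                        minConsensus = NULL) {
  stopifnot(methods::is(model, "RCEModel"), model@method == "RBF")
  interpreter <- match.arg(interpreter)
  if (interpreter == "min_consensus" &&
      (is.null(minConsensus) || is.na(minConsensus) || minConsensus < 1))
    stop("interpreter 'min_consensus' requires minConsensus >= 1")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model@w)
    stop("input width ", ncol(X), " != model w ", model@w)
  X <- .prepInputs(X, model@config)
  out <- data.frame(label = rep(NA_character_, nrow(X)),
                    confidence = rep("Unknown", nrow(X)),
                    n_fired = 0L, best_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(X))) {
    d <- .distToProtos(model@prototypes, X[r, ], model@config)
    fired <- which(d < model@aif)
    if (!length(fired)) next
    fc <- model@category[fired]; fd <- d[fired]
    conf <- if (length(unique(fc)) == 1L) "Identified" else "Uncertain"
    lab <- switch(interpreter,
      dominant = .pluralityLabel(fc, fd),
      best_match = fc[which.min(fd)],
      unanimous = .pluralityLabel(fc, fd),
      min_consensus = .pluralityLabel(fc, fd))
    if (interpreter == "unanimous" && conf == "Uncertain") {
      conf <- "Unknown"; lab <- NA_character_
    }
    if (interpreter == "min_consensus" && !is.na(lab) &&
        sum(fc == lab) < minConsensus) {
      conf <- "Unknown"; lab <- NA_character_
    }
    out$label[r] <- lab
    out$confidence[r] <- conf
    out$n_fired[r] <- length(fired)
    out$best_distance[r] <- min(fd)
  }
  out
}

#' Classify inputs with the KNN method
#'
#' All neurons fire; the k nearest (ties at the k-th distance broken by
#' training order) vote. The label is the plurality category (the only
#' interpreter of this mode); confidence is `Identified` when all k
#' neighbours agree and `Uncertain` otherwise -- KNN can never output
#' `Unknown`.
#'
#' @param model a KNN [RCEModel-class] from [trainKNN()].
#' @param x input vector or matrix (one input per row).
#' @param k neighbour count, `1 <= k <= nNeurons(model)`.
#' @return data.frame as in [classifyRBF()].
#' @export
classifyKNN <- function(model, x, k) {
  stopifnot(methods::is(model, "RCEModel"), model@method == "KNN")
  k <- as.integer(k)
  if (k < 1L || k > nNeurons(model))
    stop("k must lie in 1..", nNeurons(model))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model@w)
    stop("input width ", ncol(X), " != model w ", model@w)
  X <- .prepInputs(X, model@config)
  out <- data.frame(label = character(nrow(X)),
                    confidence = character(nrow(X)),
                    n_fired = k, best_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(X))) {
    d <- .distToProtos(model@prototypes, X[r, ], model@config)
    nb <- order(d)[seq_len(k)]   # stable: ties broken by training order
    fc <- model@category[nb]; fd <- d[nb]
    out$label[r] <- .pluralityLabel(fc, fd)
    out$confidence[r] <- if (length(unique(fc)) == 1L) "Identified"
                         else "Uncertain"
    out$best_distance[r] <- fd[1]
  }
  out
}

#' Serialize / restore a trained model
#'
#' JSON round-trip of the full neuron array (prototype, category, AIF),
#' method and resolved configuration. Restored models classify
#' identically to the original.
#'
#' @param model an [RCEModel-class]; @param path file path.
#' @return `readRCEModel` returns the [RCEModel-class].
#' @export
writeRCEModel <- function(model, path) {
  stopifnot(methods::is(model, "RCEModel"))
  cfg <- model@config
  jsonlite::write_json(list(
    method = model@method, w = model@w, labelSet = model@labelSet,
    epochs = model@epochs, converged = model@converged,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    neurons = list(prototypes = model@prototypes,
                   category = model@category, aif = model@aif,
                   committedAt = model@committedAt)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeRCEModel
#' @export
readRCEModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$maxEpochs <- as.integer(cfg$maxEpochs)
  cfg$maxNeurons <- as.integer(cfg$maxNeurons)
  protos <- obj$neurons$prototypes
  if (is.null(dim(protos))) protos <- matrix(protos, ncol = obj$w)
  dimnames(protos) <- NULL
  methods::new("RCEModel",
               prototypes = protos,
               category = as.character(obj$neurons$category),
               aif = as.numeric(obj$neurons$aif),
               committedAt = as.integer(obj$neurons$committedAt),
               method = obj$method, w = as.integer(obj$w),
               labelSet = as.character(obj$labelSet),
               config = cfg, epochs = as.integer(obj$epochs),
               converged = as.logical(obj$converged))
}
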