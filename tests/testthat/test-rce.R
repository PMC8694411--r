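# brute-force distance oracle
bruteL1 <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s
}

test_that("component distances follow the configured norm", {
  expect_identical(rceDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rceDistance(c(0, 0), c(3, 4)), 7)
  expect_identical(rceDistance(c(0, 0), c(3, 4), rceConfig("Linf")), 4)
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(rceDistance(a, b), bruteL1(a, b), tolerance = 1e-12)
    expect_equal(rceDistance(a, b, rceConfig("Linf")), max(abs(a - b)),
                 tolerance = 1e-12)
  }
  expect_error(rceDistance(1:3, 1:4), "length")
})

test_that("a single training window commits one neuron at full field", {
  ws <- makeWindowSet(matrix(c(1, 2, 3, 4), 1, 4), "urea")
  m <- trainRBF(ws, rceConfig(maxIF = 10, minIF = 0.01))
  expect_identical(nNeurons(m), 1L)
  expect_identical(m@aif, 10)
  r <- classifyRBF(m, c(1, 2, 3, 4))
  expect_identical(r$label, "urea")
  expect_identical(r$confidence, "Identified")
})

test_that("identical vectors with conflicting labels shrink to the floor and disagree", {
  ws <- makeWindowSet(rbind(c(1, 1, 1), c(1, 1, 1)), c("A", "B"),
                      sources = c("A_R1", "B_R1"))
  m <- trainRBF(ws, rceConfig(maxIF = 5, minIF = 0.001), shuffleSeed = 1)
  expect_identical(nNeurons(m), 2L)
  expect_identical(m@aif, c(0.001, 0.001))
  r <- classifyRBF(m, c(1, 1, 1), "dominant")
  expect_identical(r$confidence, "Uncertain")
  expect_identical(classifyRBF(m, c(1, 1, 1), "unanimous")$confidence,
                   "Unknown")
})

test_that("training converges on separated clusters with perfect recall", {
  ws <- clusterWindows(n = 40, w = 4, sep = 20, sd = 1)
  m <- trainRBF(ws, shuffleSeed = 7)
  expect_true(m@converged)
  for (interp in c("best_match", "dominant")) {
    preds <- classifyRBF(m, windowValues(ws), interp)
    expect_identical(preds$label, windowLabels(ws))
    expect_true(all(preds$confidence == "Identified"))
  }
})

test_that("the fired set equals a brute-force scan of every neuron", {
  ws <- clusterWindows(n = 60, w = 5, sep = 8, sd = 2, seed = 5)
  m <- trainRBF(ws, shuffleSeed = 3)
  expect_lte(nNeurons(m), 200L)
  set.seed(6)
  for (r in 1:25) {
    x <- rnorm(5, sample(c(0, 8), 1), 4)
    fired <- firedNeurons(m, x)
    oracle <- integer()
    for (j in seq_len(nNeurons(m))) {
      if (bruteL1(m@prototypes[j, ], x) < m@aif[j])
        oracle <- c(oracle, j)
    }
    expect_setequal(fired$neuron, oracle)
    expect_false(is.unsorted(fired$distance))
  }
})

test_that("interpreters follow the fired-set truth table", {
  # three neurons firing with categories (A, A, B), distances 0.4 < 0.6 < 1.6
  m <- manualRBFModel(rbind(c(0, 0), c(1, 0), c(2, 0)), c("A", "A", "B"),
                      aif = c(10, 10, 10))
  x <- c(0.4, 0)
  dom <- classifyRBF(m, x, "dominant")
  expect_identical(dom$label, "A")
  expect_identical(dom$confidence, "Uncertain")
  expect_identical(dom$n_fired, 3L)
  bm <- classifyRBF(m, x, "best_match")
  expect_identical(bm$label, "A")
  un <- classifyRBF(m, x, "unanimous")
  expect_identical(un$confidence, "Unknown")
  expect_true(is.na(un$label))
  mc3 <- classifyRBF(m, x, "min_consensus", minConsensus = 3)
  expect_identical(mc3$confidence, "Unknown")
  mc2 <- classifyRBF(m, x, "min_consensus", minConsensus = 2)
  expect_identical(mc2$label, "A")
  # plurality tie resolved toward the nearest tied neuron
  tie <- manualRBFModel(rbind(c(0, 0), c(1, 0)), c("B", "A"),
                        aif = c(10, 10))
  expect_identical(classifyRBF(tie, c(0.4, 0), "dominant")$label, "B")
  # far input: nothing fires
  far <- classifyRBF(m, c(1000, 1000), "dominant")
  expect_identical(far$confidence, "Unknown")
  expect_true(is.na(far$label))
  expect_identical(far$n_fired, 0L)
  expect_error(classifyRBF(m, x, "min_consensus"), "minConsensus")
})

test_that("interpreter hierarchy holds on random inputs", {
  ws <- clusterWindows(n = 30, w = 4, sep = 5, sd = 2, seed = 9)
  m <- trainRBF(ws, shuffleSeed = 2)
  set.seed(10)
  X <- matrix(rnorm(200, 2.5, 4), 50, 4)
  dom <- classifyRBF(m, X, "dominant")
  un <- classifyRBF(m, X, "unanimous")
  mc1 <- classifyRBF(m, X, "min_consensus", minConsensus = 1)
  # unanimous answers are a subset of dominant's and agree where present
  ans <- !is.na(un$label)
  expect_true(all(!is.na(dom$label[ans])))
  expect_identical(un$label[ans], dom$label[ans])
  # minimum consensus with m = 1 is exactly dominant
  expect_identical(mc1$label, dom$label)
  expect_identical(mc1$confidence, dom$confidence)
})

test_that("influence fields never grow as training continues", {
  ws <- clusterWindows(n = 50, w = 4, sep = 4, sd = 2.5, seed = 11)
  m1 <- trainRBF(ws, rceConfig(maxEpochs = 1L), shuffleSeed = 4)
  m2 <- trainRBF(ws, rceConfig(maxEpochs = 3L), shuffleSeed = 4)
  shared <- seq_len(nNeurons(m1))
  expect_identical(m2@category[shared], m1@category)
  expect_true(all(m2@aif[shared] <= m1@aif + 1e-12))
  expect_true(all(m2@aif >= m2@config$minIF - 1e-12))
  expect_true(all(m2@aif <= m2@config$maxIF + 1e-12))
})

test_that("KNN commits one neuron per training window, duplicates included", {
  vals <- rbind(c(1, 2), c(1, 2), c(5, 6))
  ws <- makeWindowSet(vals, c("A", "A", "B"))
  m <- trainKNN(ws)
  expect_identical(nNeurons(m), 3L)
  expect_identical(m@prototypes[1, ], m@prototypes[2, ])
  expect_true(all(is.na(m@aif)))
})

test_that("KNN classification matches brute-force nearest neighbours", {
  ws <- clusterWindows(n = 25, w = 4, sep = 10, sd = 3, seed = 15)
  m <- trainKNN(ws)
  set.seed(16)
  for (i in 1:20) {
    x <- rnorm(4, 5, 6)
    d <- apply(windowValues(ws), 1, bruteL1, b = x)
    expect_identical(classifyKNN(m, x, 1)$label,
                     windowLabels(ws)[which.min(d)])
  }
  # k = n with a strict majority
  maj <- makeWindowSet(rbind(c(0, 0), c(1, 1), c(10, 10)),
                       c("A", "A", "B"))
  expect_identical(classifyKNN(trainKNN(maj), c(0, 0), 3)$label, "A")
  # k = 3 with neighbour categories (A, B, B) -> plurality B, Uncertain
  tri <- makeWindowSet(rbind(0, 1, 2), c("A", "B", "B"))
  r <- classifyKNN(trainKNN(tri), 0, 3)
  expect_identical(r$label, "B")
  expect_identical(r$confidence, "Uncertain")
  expect_error(classifyKNN(m, rnorm(4), 0), "k must")
  expect_error(classifyKNN(m, rnorm(4), 100), "k must")
})

test_that("KNN never outputs Unknown and k=1 equals best-match", {
  ws <- clusterWindows(n = 30, w = 4, sep = 6, sd = 2, seed = 17)
  km <- trainKNN(ws)
  set.seed(18)
  X <- matrix(rnorm(160, 3, 5), 40, 4)
  knn1 <- classifyKNN(km, X, 1)
  expect_false(any(knn1$confidence == "Unknown"))
  # best-match read-out over the same all-firing neuron array (every
  # training window a prototype with an unbounded field) is k = 1
  allFire <- manualRBFModel(windowValues(ws), windowLabels(ws),
                            aif = rep(1e9, nWindows(ws)))
  bm <- classifyRBF(allFire, X, "best_match")
  expect_identical(knn1$label, bm$label)
})

test_that("model JSON round-trip classifies identically", {
  ws <- clusterWindows(n = 20, w = 4, sep = 10, sd = 2, seed = 19)
  for (m in list(trainRBF(ws, shuffleSeed = 5), trainKNN(ws))) {
    path <- tempfile(fileext = ".json")
    writeRCEModel(m, path)
    back <- readRCEModel(path)
    expect_equal(back@prototypes, m@prototypes, tolerance = 0)
    expect_identical(back@category, m@category)
    expect_equal(back@aif, m@aif, tolerance = 0)
    set.seed(20)
    X <- matrix(rnorm(80, 5, 6), 20, 4)
    if (m@method == "RBF") {
      expect_identical(classifyRBF(back, X, "dominant"),
                       classifyRBF(m, X, "dominant"))
    } else {
      expect_identical(classifyKNN(back, X, 3), classifyKNN(m, X, 3))
    }
  }
})

test_that("8-bit quantization yields integer distances and sane labels", {
  ws <- clusterWindows(n = 20, w = 4, sep = 50, sd = 2, seed = 21)
  m <- trainRBF(ws, rceConfig(quantize8bit = TRUE), shuffleSeed = 1)
  x <- windowValues(ws)[1, ]
  fired <- firedNeurons(m, x)
  expect_true(all(fired$distance == round(fired$distance)))
  preds <- classifyRBF(m, windowValues(ws), "best_match")
  expect_identical(preds$label, windowLabels(ws))
})

test_that("neuron capacity overflow is reported", {
  ws <- clusterWindows(n = 30, w = 4, sep = 3, sd = 3, seed = 22)
  expect_error(trainRBF(ws, rceConfig(maxNeurons = 2L)), "capacity")
})
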