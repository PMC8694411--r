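predFrame <- function(labels, confidence) {
  data.frame(label = labels, confidence = confidence,
             stringsAsFactors = FALSE)
}

test_that("outcome binning matches a hand tally", {
  allGood <- predFrame(rep("urea", 4), rep("Identified", 4))
  cs <- confusionSummary(allGood, rep("urea", 4))
  expect_equal(unname(cs@pct), c(100, 0, 0, 0, 0))

  allUnknown <- predFrame(rep(NA_character_, 3), rep("Unknown", 3))
  cs2 <- confusionSummary(allUnknown, rep("urea", 3))
  expect_equal(unname(cs2@pct), c(0, 0, 0, 0, 100))

  # ten hand-built outcomes: 3 CI, 2 CU, 1 II, 2 IU, 2 U
  preds <- predFrame(
    c("A", "A", "A", "A", "A", "B", "B", "B", NA, NA),
    c("Identified", "Identified", "Identified", "Uncertain", "Uncertain",
      "Identified", "Uncertain", "Uncertain", "Unknown", "Unknown"))
  truths <- c("A", "A", "A", "A", "A", "A", "A", "A", "A", "A")
  cs3 <- confusionSummary(preds, truths)
  expect_equal(unname(cs3@counts), c(3, 2, 1, 2, 2))
  expect_equal(unname(cs3@pct), c(30, 20, 10, 20, 20))
  expect_identical(cs3@nTest, 10)
  expect_error(confusionSummary(preds, truths[1:5]), "length")
})

test_that("accuracy formulas reproduce the published benchmark cells", {
  flagship <- confusionFromPercents(69.1, 0, 2.4, 0, 28.5)
  expect_equal(round(generalAccuracy(flagship), 1), 96.6)
  expect_equal(round(identifiedAccuracy(flagship), 1), 96.6)

  row5pt <- confusionFromPercents(72.7, 0, 6.3, 0, 21.0)
  expect_equal(round(generalAccuracy(row5pt), 1), 92.0)

  # dominant-interpreter row: printed 94.7 against computed 94.76
  dom <- confusionFromPercents(69.1, 3.3, 2.4, 1.6, 23.6)
  expect_lt(abs(generalAccuracy(dom) - 94.7), 0.2)

  perfectId <- confusionFromPercents(68.3, 0, 0, 8.9, 22.8)
  expect_identical(identifiedAccuracy(perfectId), 100)
  even <- confusionFromPercents(25, 25, 25, 25, 0)
  expect_identical(identifiedAccuracy(even), 50)

  allU <- confusionFromPercents(0, 0, 0, 0, 100)
  expect_error(generalAccuracy(allU), "Unknown")
  expect_error(identifiedAccuracy(allU), "Identified")
})

test_that("every published result row is internally consistent within rounding", {
  ref <- referenceModelResults()
  for (i in seq_len(nrow(ref))) {
    cs <- confusionFromPercents(ref$correct_id[i], ref$correct_unclear[i],
                                ref$incorrect_id[i],
                                ref$incorrect_unclear[i], ref$unknown[i])
    expect_lt(abs(generalAccuracy(cs) - ref$accuracy_all[i]), 0.2)
    expect_lt(abs(identifiedAccuracy(cs) - ref$accuracy_id[i]), 0.2)
  }
})

test_that("model filters mark, rank, and never alter summaries", {
  base <- data.frame(w = 6L, standardization = "all", method = "RBF",
                     interpreter = c("a", "b", "c", "d"), param = NA,
                     pct_correct_identified = c(40, 69.1, 20, 30),
                     pct_correct_unclear = c(0, 0, 10, 10),
                     pct_incorrect_identified = c(5, 2.4, 10, 5),
                     pct_incorrect_unclear = c(0, 0, 10, 5),
                     pct_unknown = c(61.5, 28.5, 50.0, 50.0),
                     general_accuracy = c(88.9, 96.6, 60, 80),
                     identified_accuracy = c(88.9, 96.6, 50, 93.75),
                     min_class_identified = c(30, 60, 15, 28),
                     error = NA_character_, stringsAsFactors = FALSE)
  out <- filterModels(base)
  byInterp <- function(d, i) d[d$interpreter == i, ]
  expect_true(byInterp(out, "a")$excluded)          # 61.5% unknown
  expect_match(byInterp(out, "a")$exclusion_reason, "Unknown")
  expect_false(byInterp(out, "c")$excluded)         # exactly 50% retained
  expect_false(byInterp(out, "d")$excluded)
  expect_identical(byInterp(out, "b")$rank, 1L)
  # summaries untouched
  expect_identical(out$pct_unknown[order(out$interpreter)],
                   base$pct_unknown[order(base$interpreter)])

  # identified share below 25% removed (24.9 boundary)
  low <- base[2, ]
  low$pct_correct_identified <- 20.0
  low$pct_incorrect_identified <- 4.9
  low$pct_unknown <- 28.5
  expect_true(filterModels(low)$excluded)
  lowExact <- low
  lowExact$pct_incorrect_identified <- 5.0   # exactly 25: retained
  expect_false(filterModels(lowExact)$excluded)
  # per-class variant uses the weakest class
  weakClass <- lowExact
  weakClass$min_class_identified <- 10
  expect_false(filterModels(weakClass)$excluded)
  expect_true(filterModels(weakClass, perClassIdentified = TRUE)$excluded)
})

test_that("the default settings grid enumerates 120 model configurations", {
  g <- gridSettings()
  expect_identical(nrow(g), 120L)
  expect_identical(nrow(unique(g)), 120L)
  expect_identical(sort(unique(g$w)), c(4L, 5L, 6L))
  expect_identical(sum(g$method == "KNN"), 60L)
  one <- gridSettings(w = 6L, standardization = "all", knnK = integer(),
                      minConsensus = integer())
  expect_identical(nrow(one), 3L)  # the three parameter-free interpreters
})

test_that("grid runs are deterministic and robust to per-model failure", {
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 37))
  small <- gridSettings(w = 6L, standardization = c("raw", "all"),
                        knnK = 3L, minConsensus = 2L)
  a <- runGrid(ve, settings = small, seed = 4)
  b <- runGrid(ve, settings = small, seed = 4)
  expect_identical(a, b)
  expect_true(all(is.na(a$error)))
  expect_true(all(abs(rowSums(a[, c("pct_correct_identified",
    "pct_correct_unclear", "pct_incorrect_identified",
    "pct_incorrect_unclear", "pct_unknown")]) - 100) < 1e-9))
})

test_that("per-class confusion itemises misclassification destinations", {
  perfect <- predFrame(c("A", "A", "B", "B"), rep("Identified", 4))
  tab <- confusionByClass(perfect, c("A", "A", "B", "B"))
  expect_equal(tab$pct_correct, c(100, 100))
  expect_equal(tab$pct_to_B[tab$truth == "A"], 0)

  # hand-built 12-prediction tally
  preds <- predFrame(
    c("A", "A", "B", NA, "A", "B", "B", "C", NA, "C", "A", "C"),
    c(rep("Identified", 3), "Unknown", rep("Uncertain", 4), "Unknown",
      "Identified", "Identified", "Uncertain"))
  truths <- c(rep("A", 4), rep("B", 4), rep("C", 4))
  tab2 <- confusionByClass(preds, truths)
  expect_equal(tab2$pct_correct, c(50, 50, 50), tolerance = 1e-12)
  expect_equal(tab2$pct_unknown, c(25, 0, 25), tolerance = 1e-12)
  expect_equal(tab2$pct_to_B[tab2$truth == "A"], 25, tolerance = 1e-12)
  expect_equal(tab2$pct_to_A[tab2$truth == "B"], 25, tolerance = 1e-12)
  expect_equal(tab2$pct_to_C[tab2$truth == "B"], 25, tolerance = 1e-12)
})

test_that("control confuses with DNT more than with urea on synthetic data", {
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 43))
  ws <- buildDataset(ve, 6)
  sp <- splitDataset(ws, 0.2, seed = 43)
  std <- fitStandardizer(sp$train, "all")
  m <- trainRBF(applyStandardizer(sp$train, std), shuffleSeed = 43)
  te <- applyStandardizer(sp$test, std)
  preds <- classifyRBF(m, windowValues(te), "dominant")
  tab <- confusionByClass(preds, windowLabels(te))
  cdnt <- tab$pct_to_DNT[tab$truth == "control"] +
    tab$pct_to_control[tab$truth == "DNT"]
  curea <- tab$pct_to_urea[tab$truth == "control"] +
    tab$pct_to_control[tab$truth == "urea"]
  expect_gt(cdnt, curea)
})

test_that("dropping hard-to-separate compounds does not lower the best accuracy", {
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 45))
  sub <- subsetExperiment(ve, c("DNT", "petroleum"))
  expect_identical(ncol(sub), 24L)
  expect_identical(ncol(subsetExperiment(ve, character())), 36L)
  expect_error(subsetExperiment(ve, unique(treatmentLabels(ve))), "every")
  expect_error(subsetExperiment(
    ve, setdiff(unique(treatmentLabels(ve)), "urea")), "fewer than 2")

  small <- gridSettings(w = 6L, standardization = "all",
                        knnK = integer(), minConsensus = integer())
  full <- runGrid(ve, settings = small, seed = 45)
  reduced <- runGrid(sub, settings = small, seed = 45)
  expect_gte(max(reduced$general_accuracy, na.rm = TRUE),
             max(full$general_accuracy, na.rm = TRUE))
})

test_that("conservative read-outs avoid confident mistakes on separated data", {
  ws <- clusterWindows(n = 60, w = 6, sep = 25, sd = 1, seed = 47)
  sp <- splitDataset(ws, 0.2, seed = 47)
  m <- trainRBF(sp$train, shuffleSeed = 47)
  preds <- classifyRBF(m, windowValues(sp$test), "unanimous")
  cs <- confusionSummary(preds, windowLabels(sp$test))
  expect_identical(cs@pct[["incorrect_identified"]], 0)
})
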