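winDefault <- observationWindow(6, 31)

test_that("zero-noise data recover the shared line exactly", {
  cfg <- noiselessConfig(nReplicates = 3L)
  ve <- simulateExperiment(cfg)
  fit <- fitBaseline(ve, winDefault)
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate[fe$term == "(Intercept)"], 339.94,
               tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "Days"], 1.73, tolerance = 1e-6)
  expect_lt(fit@varianceComponents[["sd_intercept"]], 1e-4)
  expect_true(fit@singular)  # boundary fit is flagged, not hidden
})

test_that("information criteria follow their definitions exactly", {
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 23))
  fit <- fitBaseline(ve, winDefault)
  k <- attr(logLik(fit@fit), "df")
  n <- fit@nObs
  expect_equal(fit@aic, -2 * fit@logLik + 2 * k, tolerance = 1e-8)
  expect_equal(fit@bic - fit@aic, k * (log(n) - 2), tolerance = 1e-8)
})

test_that("baseline parameters are recovered at the study design size", {
  # 36 cells generated from the pooled-fit coefficients; the estimate
  # must fall within 2 printed SEs (32.35 / 0.72) of the generating value
  for (seed in c(1, 2, 3)) {
    cfg <- generatorConfig(alpha = 177.42, beta = 4.48,
                           treatmentOffsets = list(control = c(0, 0)),
                           sdA = 61, sdB = 1.7, rhoAB = -0.2, sdEps = 4,
                           nReplicates = 36L,
                           transient = list(onsetLevel = 0, rampEndDay = 5),
                           seed = seed)
    fit <- fitBaseline(simulateExperiment(cfg), winDefault)
    fe <- fixedEffects(fit)
    expect_lt(abs(fe$estimate[fe$term == "(Intercept)"] - 177.42),
              2 * 32.35)
    expect_lt(abs(fe$estimate[fe$term == "Days"] - 4.48), 2 * 0.72)
  }
})

test_that("treatment contrasts are recovered within two printed SEs", {
  cfg <- defaultGeneratorConfig(seed = 41)
  ve <- simulateExperiment(cfg)
  fit <- fitTreatment(ve, winDefault)
  fe <- fixedEffects(fit)
  expect_lt(abs(fe$estimate[fe$term == "Treatmentgasoline"] - (-472.09)),
            2 * 40.06)
  expect_lt(abs(fe$estimate[fe$term == "Days:Treatmenturea"] - 7.08),
            2 * 1.47)
  # reference coding: control terms absent, all five others present
  expect_false(any(grepl("Treatmentcontrol", fe$term)))
  expect_identical(sum(grepl("^Treatment", fe$term)), 5L)
  expect_error(fitTreatment(ve, winDefault, reference = "benzene"),
               "reference")
})

test_that("single-treatment fits isolate within-treatment variability", {
  cfg <- noiselessConfig(nReplicates = 2L)
  ve <- simulateExperiment(cfg)
  # boundary fit on noise-free data: convergence chatter is expected
  fit <- suppressWarnings(fitSingleTreatment(ve, "control", winDefault))
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate[fe$term == "Days"], 1.73, tolerance = 1e-6)
  expect_error(fitSingleTreatment(ve, "urea", winDefault), "urea")

  # generated variability ordering: urea/fertilizer tight,
  # petroleum/gasoline loose (20 replicates so the SE estimate settles)
  cfgv <- defaultGeneratorConfig(seed = 27)
  cfgv$nReplicates <- 20L
  vev <- simulateExperiment(cfgv)
  ses <- vapply(c("fertilizer", "urea", "gasoline", "petroleum"),
                function(tl) {
    fe <- suppressWarnings(
      fixedEffects(fitSingleTreatment(vev, tl, winDefault)))
    fe$se[fe$term == "(Intercept)"]
  }, numeric(1))
  expect_lt(max(ses[c("fertilizer", "urea")]),
            min(ses[c("gasoline", "petroleum")]))
})

test_that("likelihood-ratio test compares nested fits correctly", {
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 29))
  fb <- fitBaseline(ve, winDefault)
  ft <- fitTreatment(ve, winDefault)
  self <- compareModels(fb, fb)
  expect_identical(self$statistic, 0)
  expect_identical(self$p, 1)
  lrt <- compareModels(fb, ft)
  expect_equal(lrt$statistic, 2 * (ft@logLik - fb@logLik),
               tolerance = 1e-10)
  expect_identical(lrt$df, 10L)
  # strong generated treatment effects: decisive rejection
  expect_lt(lrt$p, 1e-3)
  expect_identical(lrt$preferred, "treatment")
  expect_lt(lrt$deltaAIC, 0)
  # adding parameters never decreases the ML log-likelihood
  expect_gte(ft@logLik, fb@logLik)
  sub <- fitBaseline(subsetExperiment(ve, "urea"), winDefault)
  expect_error(compareModels(sub, ft), "different data")
})

test_that("R-squared partitions variance as defined", {
  # pure fixed-effect data: everything explained
  cfg <- noiselessConfig(nReplicates = 3L)
  fit <- fitBaseline(simulateExperiment(cfg), winDefault)
  r2 <- rSquared(fit)
  expect_equal(r2[["marginal"]], 1, tolerance = 1e-6)
  expect_equal(r2[["conditional"]], 1, tolerance = 1e-6)

  # pure noise: fixed effects explain ~nothing
  set.seed(35)
  m <- replicate(10, {
    cfgN <- generatorConfig(alpha = 0, beta = 0,
                            treatmentOffsets = list(control = c(0, 0)),
                            sdA = 0, sdB = 0, sdEps = 5,
                            nReplicates = 6L, durationDays = 31,
                            seed = sample.int(1e6, 1))
    rSquared(fitBaseline(simulateExperiment(cfgN), winDefault))[["marginal"]]
  })
  expect_lt(mean(m), 0.02)

  # treatment fixed effects dominate the treatment model, not the baseline
  ve <- simulateExperiment(defaultGeneratorConfig(seed = 31))
  r2b <- rSquared(fitBaseline(ve, winDefault))
  r2t <- rSquared(fitTreatment(ve, winDefault))
  expect_gt(r2t[["marginal"]], r2b[["marginal"]] + 0.3)
  expect_lte(r2b[["marginal"]], r2b[["conditional"]] + 1e-8)
})

test_that("end-state ANOVA and Tukey comparisons behave as defined", {
  # equal group means with within-group spread: F is exactly 0
  v <- matrix(rep(c(1, 2, 3), 2), nrow = 1)
  ve <- VoltageExperiment(v, day = 0,
                          treatment = rep(c("A", "B"), each = 3))
  res <- endStateAnova(ve)
  expect_equal(res$fStatistic, 0, tolerance = 1e-12)

  # two groups: F equals the squared equal-variance t statistic
  set.seed(33)
  v2 <- matrix(c(rnorm(6, 300, 10), rnorm(6, 340, 10)), nrow = 1)
  ve2 <- VoltageExperiment(v2, day = 0,
                           treatment = rep(c("A", "B"), each = 6))
  res2 <- endStateAnova(ve2)
  tt <- t.test(v2[1, 1:6], v2[1, 7:12], var.equal = TRUE)
  expect_equal(res2$fStatistic, unname(tt$statistic)^2, tolerance = 1e-9)

  # urea separates decisively from control at the generated effect size;
  # uniform between-cell variability so the pooled Tukey error term is
  # not dominated by the high-variance petroleum cells
  for (seed in 1:5) {
    cfgU <- defaultGeneratorConfig(seed = seed)
    cfgU$sdScale[] <- 1
    res3 <- endStateAnova(simulateExperiment(cfgU))
    row <- grepl("urea", res3$tukey$comparison) &
      grepl("control", res3$tukey$comparison)
    expect_lt(res3$tukey$p_adj[row], 0.05)
  }

  # missing final measurements are reported by series
  veM <- injectGaps(simulateExperiment(defaultGeneratorConfig(seed = 9)),
                    63, tmfc = "urea_R2")
  expect_error(endStateAnova(veM), "urea_R2")
})
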