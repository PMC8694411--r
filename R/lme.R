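#' @importFrom lme4 lmer fixef VarCorr getME isSingular
NULL

# shared fitting core: ML lmer fit + extracted summaries
.fitLME <- function(data, formulaTag, randomSlope = FALSE,
                    reference = "control",
                    ddf = c("satterthwaite", "normal")) {
  ddf <- match.arg(ddf)
  data$tMFC <- factor(data$tmfc_id)
  data$Days <- data$day
  data$Voltage <- data$voltage_mV
  re <- if (randomSlope) "(Days | tMFC)" else "(1 | tMFC)"
  fixed <- switch(formulaTag,
    baseline = "Voltage ~ Days",
    single_treatment = "Voltage ~ Days",
    treatment = "Voltage ~ Days + Treatment + Days:Treatment")
  if (formulaTag == "treatment") {
    if (!reference %in% data$treatment)
      stop("reference label '", reference, "' not present")
    data$Treatment <- stats::relevel(factor(data$treatment),
                                     ref = reference)
  }
  fml <- stats::as.formula(paste(fixed, "+", re))
  if (ddf == "satterthwaite") {
    fit <- suppressMessages(
      lmerTest::lmer(fml, data = data, REML = FALSE))
    co <- stats::coef(summary(fit))
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], df = co[, "df"],
                     t = co[, "t value"], p = co[, "Pr(>|t|)"],
                     row.names = NULL, stringsAsFactors = FALSE)
  } else {
    # labelled normal-approximation fallback: Wald z tests, df = Inf
    fit <- suppressMessages(lme4::lmer(fml, data = data, REML = FALSE))
    co <- stats::coef(summary(fit))
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], df = Inf,
                     t = co[, "t value"],
                     p = 2 * stats::pnorm(-abs(co[, "t value"])),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sdInt <- vc$sdcor[vc$grp == "tMFC" & vc$var1 == "(Intercept)" &
                    is.na(vc$var2)][1]
  sdRes <- vc$sdcor[vc$grp == "Residual"][1]
  comps <- c(sd_intercept = sdInt, sd_residual = sdRes)
  if (randomSlope) {
    sdSlope <- vc$sdcor[vc$grp == "tMFC" & vc$var1 == "Days" &
                        is.na(vc$var2)][1]
    comps <- c(comps[1], sd_slope = sdSlope, comps[2])
  }
  r2 <- .nakagawaR2(fit)
  ll <- as.numeric(stats::logLik(fit))
  methods::new("LMEFit", fit = fit, formulaTag = formulaTag,
               fixedEffects = fe, varianceComponents = comps,
               logLik = ll, aic = stats::AIC(fit), bic = stats::BIC(fit),
               r2Marginal = r2[1], r2Conditional = r2[2],
               nObs = nrow(data),
               nGroups = length(unique(data$tMFC)),
               singular = lme4::isSingular(fit))
}

# Nakagawa-Schielzeth R2: fixed-effect variance over total; random-effect
# variance taken as the mean per-observation Var(Zb) so random slopes are
# handled correctly.
.nakagawaR2 <- function(fit) {
  varF <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  sigma2 <- stats::sigma(fit)^2
  Z <- lme4::getME(fit, "Z")
  Lambda <- lme4::getME(fit, "Lambda")
  Sb <- sigma2 * Matrix::tcrossprod(Lambda)
  ZS <- Z %*% Sb
  varR <- mean(Matrix::rowSums(ZS * Z))
  tot <- varF + varR + sigma2
  if (tot <= 0) return(c(NA_real_, NA_real_))
  c(varF / tot, (varF + varR) / tot)
}

#' Baseline mixed-effects fit
#'
#' Maximum-likelihood fit of `Voltage ~ Days + (1 | tMFC)` over the
#' observation window: a single population intercept/slope with a random
#' intercept per cell (optionally a random slope). Satterthwaite
#' SEs/df/p-values accompany the fixed effects; AIC/BIC use the ML
#' log-likelihood so the fit is comparable to [fitTreatment()] by
#' [compareModels()].
#'
#' @param x a [VoltageExperiment-class].
#' @param window an [observationWindow()] (default days 6-31).
#' @param randomSlope add a per-cell random slope (`(Days | tMFC)`). The
#'   random-intercept form is the default operational model.
#' @param interceptAtDay day at which the intercept is interpreted; `Days`
#'   is shifted so day `interceptAtDay` maps to 0 (default 0 = experiment
#'   start, so the intercept extrapolates the stable-phase line back to
#'   the origin).
#' @param ddf degrees-of-freedom method for the fixed-effect tests:
#'   `"satterthwaite"` (default) or the faster `"normal"` Wald-z
#'   approximation (df reported as Inf). Log-likelihood, AIC/BIC and
#'   estimates are identical under either.
#' @return an [LMEFit-class]; singular variance-component fits are flagged
#'   in `@singular`, not silently dropped.
#' @export
fitBaseline <- function(x, window = observationWindow(6, 31),
                        randomSlope = FALSE, interceptAtDay = 0,
                        ddf = c("satterthwaite", "normal")) {
  d <- asLongData(x, window)
  .checkLMEData(d, minGroups = 2L)
  d$day <- d$day - interceptAtDay
  .fitLME(d, "baseline", randomSlope, ddf = ddf)
}

#' Treatment mixed-effects fit
#'
#' Maximum-likelihood fit of
#' `Voltage ~ Days + Treatment + Days:Treatment + (1 | tMFC)` with the
#' treatment factor reference-coded against the control, so each
#' treatment's fixed effects are its intercept and slope *contrasts*
#' relative to the control group.
#'
#' @inheritParams fitBaseline
#' @param reference treatment label used as the reference level.
#' @return an [LMEFit-class].
#' @export
fitTreatment <- function(x, window = observationWindow(6, 31),
                         reference = "control", randomSlope = FALSE,
                         interceptAtDay = 0,
                         ddf = c("satterthwaite", "normal")) {
  d <- asLongData(x, window)
  .checkLMEData(d, minGroups = 2L)
  d$day <- d$day - interceptAtDay
  .fitLME(d, "treatment", randomSlope, reference, ddf = ddf)
}

#' Single-treatment mixed-effects fit
#'
#' The baseline-form fit restricted to one treatment's replicates; its
#' standard errors quantify the within-treatment variability of the cells.
#'
#' @inheritParams fitBaseline
#' @param treatment the treatment label to fit.
#' @return an [LMEFit-class].
#' @export
fitSingleTreatment <- function(x, treatment,
                               window = observationWindow(6, 31),
                               randomSlope = FALSE, interceptAtDay = 0,
                               ddf = c("satterthwaite", "normal")) {
  keep <- treatmentLabels(x) == treatment
  if (!any(keep)) stop("no series with treatment '", treatment, "'")
  if (sum(keep) < 2L)
    stop("single-treatment fit needs >= 2 replicates")
  d <- asLongData(x[, keep], window)
  .checkLMEData(d, minGroups = 2L)
  d$day <- d$day - interceptAtDay
  .fitLME(d, "single_treatment", randomSlope, ddf = ddf)
}

.checkLMEData <- function(d, minGroups) {
  if (nrow(d) == 0L) stop("no observations in the window")
  tab <- table(d$tmfc_id)
  if (length(tab) < minGroups)
    stop("need >= ", minGroups, " tMFC groups")
  if (any(tab < 3L))
    stop("every tMFC needs >= 3 observations in the window")
  invisible(NULL)
}

setMethod("show", "LMEFit", function(object) {
  cat("LMEFit (", object@formulaTag, "): ", object@nObs, " obs, ",
      object@nGroups, " tMFCs", if (object@singular) " [singular]" else "",
      "\n", sep = "")
  fe <- object@fixedEffects
  cat(sprintf("  %-28s %9.3f (%.3f)  p=%.3g\n", fe$term, fe$estimate,
              fe$se, fe$p), sep = "")
  cat(sprintf("  sd components: %s\n",
              paste(names(object@varianceComponents),
                    signif(object@varianceComponents, 4), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  logLik %.2f, AIC %.2f, BIC %.2f, R2 marginal %.3f / conditional %.3f\n",
              object@logLik, object@aic, object@bic, object@r2Marginal,
              object@r2Conditional))
  invisible(NULL)
})

#' Fixed-effect table of an LME fit
#' @param fit an [LMEFit-class].
#' @return data.frame with term, estimate, se, df, t, p.
#' @export
fixedEffects <- function(fit) {
  stopifnot(methods::is(fit, "LMEFit"))
  fit@fixedEffects
}

#' Marginal and conditional R-squared
#'
#' Variance-partition R2 for mixed models: the marginal value is the share
#' of total variance (fixed + random + residual) explained by the fixed
#' effects alone; the conditional value adds the random-effect variance to
#' the numerator.
#'
#' @param fit an [LMEFit-class].
#' @return named numeric `c(marginal =, conditional =)`.
#' @export
rSquared <- function(fit) {
  stopifnot(methods::is(fit, "LMEFit"))
  c(marginal = fit@r2Marginal, conditional = fit@r2Conditional)
}

#' Likelihood-ratio comparison of nested ML fits
#'
#' Computes `2 * (logLik_full - logLik_reduced)` with a chi-square
#' reference on the parameter-count difference, and reports the AIC/BIC
#' deltas that corroborate the decision. Both fits must be ML fits of the
#' same observations.
#'
#' @param fitReduced,fitFull nested [LMEFit-class] objects (reduced within
#'   full).
#' @param alpha significance level used to pick `preferred`.
#' @return list of class `"LRTResult"`: `statistic`, `df`, `p`,
#'   `preferred` (a formula tag), `deltaAIC`, `deltaBIC`.
#' @export
compareModels <- function(fitReduced, fitFull, alpha = 0.05) {
  stopifnot(methods::is(fitReduced, "LMEFit"),
            methods::is(fitFull, "LMEFit"))
  if (fitReduced@nObs != fitFull@nObs)
    stop("fits use different data (", fitReduced@nObs, " vs ",
         fitFull@nObs, " observations)")
  kR <- attr(stats::logLik(fitReduced@fit), "df")
  kF <- attr(stats::logLik(fitFull@fit), "df")
  if (kF < kR) stop("fitFull has fewer parameters than fitReduced")
  stat <- 2 * (fitFull@logLik - fitReduced@logLik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  if (stat < 0)
    stop("full model has lower likelihood; models are not nested")
  df <- kF - kR
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 preferred = if (p < alpha) fitFull@formulaTag
                             else fitReduced@formulaTag,
                 deltaAIC = fitFull@aic - fitReduced@aic,
                 deltaBIC = fitFull@bic - fitReduced@bic),
            class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.3g -> prefer '%s'\n",
              x$statistic, x$df, x$p, x$preferred))
  cat(sprintf("  deltaAIC = %.2f, deltaBIC = %.2f (full - reduced)\n",
              x$deltaAIC, x$deltaBIC))
  invisible(x)
}

#' End-of-study ANOVA with Tukey HSD
#'
#' One-way analysis of variance of the final-timepoint voltages across
#' treatments, followed by Tukey honest-significant-difference pairwise
#' comparisons -- the end-state contrast between treated and control
#' cells.
#'
#' @param x a [VoltageExperiment-class].
#' @param endDay day of the "final" measurement (default: last day in the
#'   experiment). Cells whose measurement at that day is flagged missing
#'   cause an error naming them.
#' @return list with `fStatistic`, `p`, `anova` (the `summary.aov` table)
#'   and `tukey` (data.frame of pairwise differences with adjusted p).
#' @export
endStateAnova <- function(x, endDay = NULL) {
  stopifnot(methods::is(x, "VoltageExperiment"))
  d <- dayTimes(x)
  if (is.null(endDay)) endDay <- max(d)
  row <- which.min(abs(d - endDay))
  v <- voltageMatrix(x)[row, ]
  miss <- missingMatrix(x)[row, ]
  if (any(miss))
    stop("final measurement missing for: ",
         paste(tmfcIds(x)[miss], collapse = ", "))
  trt <- factor(treatmentLabels(x))
  if (nlevels(trt) < 2L) stop("need >= 2 treatments")
  if (any(table(trt) < 2L)) stop("need >= 2 replicates per treatment")
  dat <- data.frame(voltage = as.numeric(v), treatment = trt)
  fit <- stats::aov(voltage ~ treatment, data = dat)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$treatment
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(fStatistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       anova = sm, tukey = tukey)
}
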