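# shared REML random-intercept machinery for the two phenotype models
fit_random_intercept_lmm <- function(formula, data, group = "strain") {
  response <- all.vars(formula)[1]
  y <- data[[response]]
  if (var(y) == 0) {
    # degenerate response: nothing to estimate or test
    terms <- attr(stats::terms(formula), "term.labels")
    ft <- data.frame(term = c("(Intercept)", terms), numDF = NA_integer_,
                     denDF = NA_integer_, F = 0, p = NA_real_)
    return(structure(list(method = "degenerate",
                          fixed = c(`(Intercept)` = y[1]),
                          var_random = 0, var_resid = 0, ftable = ft,
                          logLik = NA_real_, model = NULL),
                     class = "lmm_fit"))
  }
  if (length(unique(data[[group]])) < 2) {
    warning(sprintf("single %s level: random intercept unidentifiable, %s",
                    group, "falling back to a fixed-effects model"),
            call. = FALSE)
    fit <- lm(formula, data = data)
    av <- anova(fit)
    ft <- data.frame(term = rownames(av), numDF = av$Df,
                     denDF = df.residual(fit), F = av$`F value`,
                     p = av$`Pr(>F)`)
    return(structure(list(method = "lm", fixed = coef(fit),
                          vcov = vcov(fit), var_random = NA_real_,
                          var_resid = summary(fit)$sigma^2,
                          ftable = ft[!is.na(ft$F), , drop = FALSE],
                          logLik = as.numeric(logLik(fit)), model = fit),
                     class = "lmm_fit"))
  }
  fit <- nlme::lme(fixed = formula, random = stats::as.formula(
    paste0("~ 1 | ", group)), data = data, method = "REML")
  av <- stats::anova(fit, type = "marginal")
  ft <- data.frame(term = rownames(av), numDF = av$numDF, denDF = av$denDF,
                   F = av$`F-value`, p = av$`p-value`)
  vc <- nlme::VarCorr(fit)
  structure(list(method = "lme", fixed = nlme::fixef(fit), vcov = vcov(fit),
                 var_random = as.numeric(vc["(Intercept)", "Variance"]),
                 var_resid = fit$sigma^2, ftable = ft,
                 logLik = as.numeric(logLik(fit)), model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept linear mixed model (%s)\n", x$method))
  cat(sprintf("  strain variance = %.4g, residual variance = %.4g\n",
              x$var_random, x$var_resid))
  print(x$ftable, row.names = FALSE)
  invisible(x)
}

#' Mixed model of aggregate shape over development
#'
#' Fits `PC1 ~ condition:time + condition + time` with a strain-level
#' random intercept by REML, and reports marginal F tests for each
#' fixed term (containment denominator degrees of freedom). With a
#' single strain the random intercept is unidentifiable and a
#' fixed-effects model is fitted with a warning; a constant response
#' yields a degenerate fit with all F = 0 and zero variances.
#'
#' @param pc1 numeric PC1 shape scores, one per aggregate.
#' @param condition factor/character, `clonal` vs `chimeric`.
#' @param time developmental phase per aggregate, e.g. `loose`,
#'   `tight`, `tipped` (categorical).
#' @param strain strain identity (random-effect grouping).
#' @return An object of class `lmm_fit`: fixed coefficients and their
#'   covariance, strain and residual variances, marginal F table, REML
#'   log-likelihood, and the underlying model object.
#' @export
fit_shape_lmm <- function(pc1, condition, time, strain) {
  d <- data.frame(PC1 = pc1, condition = factor(condition),
                  time = factor(time), strain = factor(strain))
  fit_random_intercept_lmm(PC1 ~ condition + time + condition:time, d)
}

#' Mixed model of aggregate splitting
#'
#' Linear-probability mixed model of a binary split indicator:
#' `splitting ~ condition:time + condition + time + shape` with a
#' strain-level random intercept (the linear, not logistic, treatment
#' mirrors the shape model's framework; set `logistic = TRUE` for a
#' binomial GLMM-style fallback via `glm` when preferred).
#'
#' @param splitting 0/1 indicator: did the aggregate split over the
#'   interval?
#' @param condition `clonal` vs `chimeric`.
#' @param interval time interval label (two levels, e.g.
#'   `loose-tight`, `tight-tipped`).
#' @param shape PC1 shape score at the start of the interval.
#' @param strain strain identity.
#' @param logistic fit a fixed-effects logistic model instead (no
#'   random intercept; provided as a check, not the default).
#' @return An `lmm_fit` (or, for `logistic = TRUE`, a `glm` object).
#' @export
fit_splitting_lmm <- function(splitting, condition, interval, shape, strain,
                              logistic = FALSE) {
  if (!all(splitting %in% c(0, 1))) stopf("splitting must be 0/1")
  d <- data.frame(splitting = as.numeric(splitting),
                  condition = factor(condition), time = factor(interval),
                  shape = shape, strain = factor(strain))
  if (logistic)
    return(stats::glm(splitting ~ condition + time + shape + condition:time,
                      family = stats::binomial(), data = d))
  fit_random_intercept_lmm(
    splitting ~ condition + time + shape + condition:time, d)
}
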