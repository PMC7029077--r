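#' Penalized-spline model of distance against developmental time
#'
#' Fits a generalized additive model of transcriptome distance on the
#' hr index with thin-plate regression splines, a parametric condition
#' offset, and a pair-level random intercept, with smoothing parameters
#' chosen by REML:
#' `distance ~ condition + s(hr, by = condition) + s(pair, bs = "re")`
#' when `shared_smooth = FALSE` (one smooth per condition) or
#' `distance ~ condition + s(hr) + s(pair, bs = "re")` when `TRUE`.
#'
#' Reports the total effective degrees of freedom, the REML score, AIC
#' and its small-sample correction AICc (computed with the total edf as
#' the parameter count), and the parametric condition coefficient with
#' its t statistic.
#'
#' @param profile a `distance_profile` from
#'   [reference_distance_profile()] (its `query_meta` must carry
#'   `condition` and `pair`), or a long data frame with columns
#'   `distance`, `hr`, `condition`, `pair`.
#' @param shared_smooth single smooth shared by both conditions?
#' @param k spline basis dimension (capped below the number of
#'   distinct hr values).
#' @return Object of class `spline_model`: list with the mgcv fit
#'   (`fit`), `data`, `shared_smooth`, `edf`, `reml`, `aic`, `aicc`,
#'   `deviance`, `condition_coef` (estimate, t, p; `NA` when only one
#'   condition is present) and `hr_range`.
#' @export
fit_condition_spline_model <- function(profile, shared_smooth = FALSE, k = 10) {
  df <- if (inherits(profile, "distance_profile")) {
    meta <- profile$query_meta
    if (is.null(meta) || !all(c("condition", "pair") %in% names(meta)))
      stopf("profile$query_meta must carry 'condition' and 'pair'")
    data.frame(distance = as.vector(profile$distance),
               hr = rep(profile$hr, each = nrow(profile$distance)),
               condition = rep(meta$condition, ncol(profile$distance)),
               pair = rep(meta$pair, ncol(profile$distance)))
  } else as.data.frame(profile)
  need <- c("distance", "hr", "condition", "pair")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  n_hr <- length(unique(df$hr))
  if (n_hr < 4) stopf("need >= 4 distinct hr values to fit a spline")
  df$condition <- factor(df$condition)
  df$pair <- factor(df$pair)
  k <- max(4, min(k, n_hr - 1))
  two_cond <- nlevels(df$condition) > 1
  multi_pair <- nlevels(df$pair) > 1

  rhs <- if (two_cond && !shared_smooth) {
    "condition + s(hr, by = condition, bs = \"tp\", k = k)"
  } else if (two_cond) {
    "condition + s(hr, bs = \"tp\", k = k)"
  } else {
    "s(hr, bs = \"tp\", k = k)"
  }
  if (multi_pair) rhs <- paste(rhs, "+ s(pair, bs = \"re\")")
  form <- stats::as.formula(paste("distance ~", rhs))
  fit <- mgcv::gam(form, data = df, method = "REML")

  n <- nrow(df)
  edf <- sum(fit$edf) + 1          # + scale parameter
  aic <- stats::AIC(fit)
  aicc <- if (n - edf - 1 > 0) aic + 2 * edf * (edf + 1) / (n - edf - 1) else Inf
  cond_coef <- c(estimate = NA_real_, t = NA_real_, p = NA_real_)
  if (two_cond) {
    pt <- summary(fit)$p.table
    row <- grep("^condition", rownames(pt))[1]
    cond_coef <- c(estimate = pt[row, "Estimate"], t = pt[row, "t value"],
                   p = pt[row, "Pr(>|t|)"])
  }
  structure(list(fit = fit, data = df, shared_smooth = shared_smooth,
                 edf = edf, reml = as.numeric(fit$gcv.ubre), aic = aic,
                 aicc = aicc, deviance = stats::deviance(fit),
                 condition_coef = cond_coef,
                 hr_range = range(df$hr)),
            class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("Penalized-spline staging model (%s smooth)\n",
              if (x$shared_smooth) "shared" else "per-condition"))
  cat(sprintf("  n = %d, edf = %.2f, REML = %.2f, AICc = %.2f\n",
              nrow(x$data), x$edf, x$reml, x$aicc))
  if (is.finite(x$condition_coef["estimate"]))
    cat(sprintf("  condition offset = %.3f (t = %.2f, p = %.3g)\n",
                x$condition_coef["estimate"], x$condition_coef["t"],
                x$condition_coef["p"]))
  invisible(x)
}

#' Compare per-condition and shared-smooth staging models
#'
#' Reports the AICc difference and an approximate F test on the
#' deviance difference (with the edf difference as numerator degrees
#' of freedom). The more complex per-condition model is selected only
#' when it has the lower AICc *and* the test passes `alpha`; otherwise
#' the simpler shared-smooth model is kept.
#'
#' @param model_varying per-condition `spline_model`
#'   (`shared_smooth = FALSE`).
#' @param model_shared shared-smooth `spline_model`.
#' @param alpha significance level for the deviance test.
#' @return List: `delta_aicc` (shared minus varying), `deviance_diff`,
#'   `df_diff`, `F`, `p`, `selected` (`"varying"` or `"shared"`).
#' @export
select_model <- function(model_varying, model_shared, alpha = 0.05) {
  stopifnot(inherits(model_varying, "spline_model"),
            inherits(model_shared, "spline_model"))
  if (nrow(model_varying$data) != nrow(model_shared$data) ||
      !isTRUE(all.equal(model_varying$data$distance,
                        model_shared$data$distance)))
    stopf("models were fitted on different data")
  dev_diff <- model_shared$deviance - model_varying$deviance
  df_diff <- model_varying$edf - model_shared$edf
  n <- nrow(model_varying$data)
  scale <- model_varying$fit$sig2
  Fstat <- if (df_diff > 0 && scale > 0) (dev_diff / df_diff) / scale else NA_real_
  p <- if (is.finite(Fstat) && Fstat >= 0) {
    pf(Fstat, df_diff, n - model_varying$edf, lower.tail = FALSE)
  } else NA_real_
  delta_aicc <- model_shared$aicc - model_varying$aicc
  selected <- if (!is.na(p) && p < alpha && delta_aicc > 0) "varying" else "shared"
  list(delta_aicc = delta_aicc, deviance_diff = dev_diff, df_diff = df_diff,
       F = Fstat, p = p, selected = selected)
}

# fitted staging curve for one condition, random effect excluded
predict_condition_curve <- function(model, condition, hr) {
  df <- model$data
  nd <- data.frame(hr = hr,
                   condition = factor(condition, levels = levels(df$condition)),
                   pair = factor(levels(df$pair)[1], levels = levels(df$pair)))
  exclude <- if (nlevels(df$pair) > 1) "s(pair)" else NULL
  as.numeric(mgcv::predict.gam(model$fit, newdata = nd, exclude = exclude,
                               newdata.guaranteed = TRUE))
}

#' Locate local minima of the fitted staging curve by finite differences
#'
#' Evaluates the fitted per-condition curve on a fine hr grid (step
#' 0.1 by default) extended one step beyond each end of the observed
#' range, approximates the 1st derivative by the slope between
#' successive steps and the 2nd derivative by the change in slope, and
#' reports a local minimum wherever the 1st derivative crosses zero
#' from negative to positive with a positive 2nd derivative. The
#' crossing location is linearly interpolated; minima outside the
#' observed hr range are discarded. A monotone curve yields no rows.
#'
#' @param model a `spline_model`.
#' @param step finite-difference step (> 0).
#' @param conditions conditions to scan; default all in the model.
#' @return Data frame: `condition`, `hr`, `fitted`, `second_deriv`
#'   (one row per located minimum).
#' @export
locate_minima <- function(model, step = 0.1, conditions = NULL) {
  stopifnot(inherits(model, "spline_model"))
  if (step <= 0) stopf("step must be > 0")
  conds <- conditions %||% levels(model$data$condition)
  lo <- model$hr_range[1]; hi <- model$hr_range[2]
  grid <- seq(lo - step, hi + step, by = step)
  out <- NULL
  for (cond in conds) {
    f <- predict_condition_curve(model, cond, grid)
    d1 <- diff(f) / step                       # at midpoints of grid
    mid <- grid[-length(grid)] + step / 2
    d2 <- diff(d1) / step                      # at interior grid points
    for (i in seq_len(length(d1) - 1)) {
      if (d1[i] < 0 && d1[i + 1] >= 0 && d2[i] > 0) {
        hr0 <- mid[i] + (0 - d1[i]) * (mid[i + 1] - mid[i]) /
          (d1[i + 1] - d1[i])
        if (hr0 >= lo && hr0 <= hi) {
          fit0 <- predict_condition_curve(model, cond, hr0)
          out <- rbind(out, data.frame(condition = cond, hr = hr0,
                                       fitted = fit0, second_deriv = d2[i]))
        }
      }
    }
  }
  out %||% data.frame(condition = character(0), hr = numeric(0),
                      fitted = numeric(0), second_deriv = numeric(0))
}
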