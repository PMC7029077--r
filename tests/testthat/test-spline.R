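# long-format staging data on hr = 1..19 with four pairs per condition
make_stage_data <- function(f_clonal, f_chimeric = f_clonal, noise_sd = 0,
                            seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(hr = 1:19, pair = paste0("p", 1:4),
                        condition = c("clonal", "chimeric"),
                        stringsAsFactors = FALSE)
    f <- ifelse(grid$condition == "clonal", f_clonal(grid$hr),
                f_chimeric(grid$hr))
    grid$distance <- f + rnorm(nrow(grid), 0, noise_sd)
    grid
  })
}

test_that("a noiseless quadratic is fitted to high accuracy with no offset", {
  d <- make_stage_data(function(h) (h - 10)^2)
  # a basis roomy enough that approximation error is negligible against
  # the analytic truth
  m <- fit_condition_spline_model(d, shared_smooth = FALSE, k = 15)
  grid <- seq(2, 18, by = 0.5)
  fit <- dictydev:::predict_condition_curve(m, "clonal", grid)
  expect_lt(max(abs(fit - (grid - 10)^2)), 0.05)
  expect_lt(abs(m$condition_coef[["estimate"]]), 0.05)
})

test_that("the finite-difference minimum of a quadratic is at 10.0", {
  d <- make_stage_data(function(h) (h - 10)^2)
  m <- fit_condition_spline_model(d, shared_smooth = TRUE)
  mn <- locate_minima(m, step = 0.1)
  for (cond in c("clonal", "chimeric")) {
    hit <- mn[mn$condition == cond, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$hr, 10.0, tolerance = 0.1)
    expect_gt(hit$second_deriv, 0)
  }
})

test_that("monotone fitted curves yield no minima", {
  d <- make_stage_data(function(h) 2 * h + 1)
  m <- suppressWarnings(fit_condition_spline_model(d, shared_smooth = TRUE))
  expect_equal(nrow(locate_minima(m)), 0)
})

test_that("a W-shaped curve yields both planted minima", {
  # quartic with local minima at hr 5 and 14
  f <- function(h) ((h - 5)^2 * (h - 14)^2) / 100
  d <- make_stage_data(f)
  m <- fit_condition_spline_model(d, shared_smooth = TRUE, k = 12)
  mn <- locate_minima(m)
  cl <- sort(mn$hr[mn$condition == "clonal"])
  expect_equal(length(cl), 2)
  expect_equal(cl, c(5, 14), tolerance = 0.2 / 5)
})

test_that("a constant response collapses the smooth to ~1 edf", {
  d <- make_stage_data(function(h) rep(3, length(h)))
  # tiny seeded jitter so the REML fit is not exactly degenerate
  d$distance <- d$distance + withr::with_seed(2, rnorm(nrow(d), 0, 1e-3))
  m <- suppressWarnings(fit_condition_spline_model(d, shared_smooth = TRUE))
  sm <- m$fit$smooth[[1]]
  edf_smooth <- sum(m$fit$edf[sm$first.para:sm$last.para])
  expect_lt(edf_smooth, 1.5)
  expect_lt(abs(m$condition_coef[["estimate"]]), 0.01)
})

test_that("model comparison keeps the simpler model when fits are identical", {
  d <- make_stage_data(function(h) (h - 10)^2, noise_sd = 0.5)
  ms <- fit_condition_spline_model(d, shared_smooth = TRUE)
  sel <- select_model(ms, ms)
  expect_equal(sel$delta_aicc, 0)
  expect_equal(sel$selected, "shared")
  other <- make_stage_data(function(h) h, noise_sd = 0.5, seed = 99)
  mo <- fit_condition_spline_model(other, shared_smooth = TRUE)
  expect_error(select_model(mo, ms), "different data")
})

test_that("model selection tracks the truth across simulated replicates", {
  n_sims <- 20
  votes_diff <- vapply(seq_len(n_sims), function(s) {
    d <- make_stage_data(function(h) (h - 10)^2 / 8,
                         function(h) (h - 12)^2 / 8,
                         noise_sd = 0.3, seed = s)
    mv <- fit_condition_spline_model(d, FALSE)
    ms <- fit_condition_spline_model(d, TRUE)
    select_model(mv, ms)$selected == "varying"
  }, logical(1))
  expect_gte(mean(votes_diff), 0.9)
  votes_same <- vapply(seq_len(n_sims), function(s) {
    d <- make_stage_data(function(h) (h - 10)^2 / 8,
                         noise_sd = 0.3, seed = 100 + s)
    mv <- fit_condition_spline_model(d, FALSE)
    ms <- fit_condition_spline_model(d, TRUE)
    select_model(mv, ms)$selected == "shared"
  }, logical(1))
  expect_gte(mean(votes_same), 0.9)
})

test_that("finite differences match analytic derivatives of a smooth fit", {
  # fitted curve ~ cubic: check O(step^2) agreement of the derivative
  f <- function(h) 0.05 * (h - 8)^3 + 2 * h
  d <- make_stage_data(f)
  m <- fit_condition_spline_model(d, shared_smooth = TRUE, k = 12)
  step <- 0.1
  grid <- seq(4, 16, by = step)
  fit <- dictydev:::predict_condition_curve(m, "clonal", grid)
  d1 <- diff(fit) / step
  mid <- grid[-length(grid)] + step / 2
  true_d1 <- 0.15 * (mid - 8)^2 + 2
  expect_lt(max(abs(d1 - true_d1)), 0.25)
})
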