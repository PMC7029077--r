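test_that("correlated candidates collapse to one kept parameter", {
  withr::with_seed(3, {
    x <- rnorm(100)
    tbl <- data.frame(a = x, b = 2 * x + 1, c = rnorm(100))
    kept <- select_shape_parameters(tbl, c("a", "b", "c"))
    expect_identical(kept, c("a", "c"))
    # independent candidates all survive
    ind <- data.frame(u = rnorm(100), v = rnorm(100), w = rnorm(100))
    expect_identical(select_shape_parameters(ind, c("u", "v", "w")),
                     c("u", "v", "w"))
    expect_warning(
      select_shape_parameters(data.frame(k = rep(1, 10), u = rnorm(10),
                                         v = rnorm(10)),
                              c("k", "u", "v")), "constant")
  })
})

test_that("the canonical four shape parameters survive while perimeter falls", {
  # sizes spanning an order of magnitude: perimeter tracks sqrt(area)
  # tightly (r > 0.9) while the dimensionless shapes stay independent
  withr::with_seed(8, {
    area <- exp(rnorm(300, log(500), 0.5))
    tbl <- data.frame(
      area = area,
      perimeter = 2 * sqrt(pi * area) * exp(rnorm(300, 0, 0.03)),
      circularity = pmin(1, rbeta(300, 8, 2)),
      aspect_ratio = 1 + rexp(300, 2),
      solidity = pmin(1, rbeta(300, 20, 1)))
    expect_gt(abs(cor(tbl$area, tbl$perimeter)), 0.9)
    kept <- select_shape_parameters(
      tbl, c("area", "perimeter", "circularity", "aspect_ratio", "solidity"))
    expect_identical(kept, c("area", "circularity", "aspect_ratio",
                             "solidity"))
  })
})

test_that("shape PCA matches an eigendecomposition oracle", {
  withr::with_seed(21, {
    tbl <- as.data.frame(matrix(rnorm(20), 5, 4))
    names(tbl) <- c("area", "b", "c", "d")
    pca <- shape_pca(tbl, names(tbl))
    Z <- scale(as.matrix(tbl))
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
    eig <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
    expect_equal(pca$sdev^2, eig$values, tolerance = 1e-8)
    for (j in 1:4) {     # loadings match up to sign
      expect_equal(unname(abs(pca$loadings[, j])), abs(eig$vectors[, j]),
                   tolerance = 1e-8)
    }
    # orthonormal loadings, centred scores, PC1 anchored on area
    expect_equal(unname(crossprod(pca$loadings)), diag(4), tolerance = 1e-8)
    expect_equal(unname(colMeans(pca$scores)), rep(0, 4), tolerance = 1e-10)
    expect_gte(pca$loadings["area", 1], 0)
    expect_true(all(diff(pca$explained) <= 1e-12))
  })
})

test_that("two perfectly correlated columns give PC1 all the variance", {
  x <- rnorm(30)
  pca <- shape_pca(data.frame(a = x, b = -3 * x), c("a", "b"))
  expect_equal(pca$explained[1], 1)
  expect_error(shape_pca(data.frame(a = 1:2, b = 2:1, c = c(1, 2)),
                         c("a", "b", "c")), "rows")
})

test_that("shape LMM recovers planted variance components", {
  withr::with_seed(42, {
    n_strain <- 8; n_obs <- 300
    strain <- rep(paste0("s", seq_len(n_strain)), each = n_obs)
    u_lvl <- rnorm(n_strain, 0, 2)
    u <- u_lvl[as.integer(factor(strain))]
    condition <- rep(rep(c("clonal", "chimeric"), length.out = n_obs),
                     n_strain)
    time <- sample(c("loose", "tight", "tipped"), n_strain * n_obs, TRUE)
    y <- u + rnorm(n_strain * n_obs, 0, 1)
    fit <- fit_shape_lmm(y, condition, time, strain)
    # with 8 strains the realized between-strain variance, not the
    # nominal one, is the recoverable target
    expect_lt(abs(fit$var_random - var(u_lvl)) / var(u_lvl), 0.2)
    expect_lt(abs(fit$var_resid - 1), 0.2)
    expect_true(all(c("condition", "time", "condition:time") %in%
                      fit$ftable$term))
  })
})

test_that("shape LMM type-I error for condition is near nominal", {
  withr::with_seed(7, {
    rejections <- vapply(1:200, function(i) {
      strain <- rep(paste0("s", 1:6), each = 30)
      u <- rnorm(6, 0, 1)[as.integer(factor(strain))]
      condition <- sample(c("clonal", "chimeric"), 180, TRUE)
      time <- sample(c("loose", "tight", "tipped"), 180, TRUE)
      y <- u + rnorm(180)
      fit <- fit_shape_lmm(y, condition, time, strain)
      fit$ftable$p[fit$ftable$term == "condition"] < 0.05
    }, logical(1))
    expect_gte(mean(rejections), 0.03)
    expect_lte(mean(rejections), 0.07)
  })
})

test_that("degenerate LMM inputs are handled explicitly", {
  # constant response: zero variances, zero F
  fit <- fit_shape_lmm(rep(2, 40), rep(c("clonal", "chimeric"), 20),
                       rep(c("loose", "tight"), each = 20),
                       rep(c("s1", "s2"), 20))
  expect_equal(fit$var_random, 0)
  expect_equal(fit$var_resid, 0)
  expect_true(all(fit$ftable$F == 0))
  # single strain: fixed-effects fallback with a warning
  expect_warning(
    fit1 <- fit_shape_lmm(rnorm(40), rep(c("clonal", "chimeric"), 20),
                          rep(c("loose", "tight"), each = 20),
                          rep("s1", 40)),
    "single")
  expect_identical(fit1$method, "lm")
})

test_that("splitting model detects a planted condition-by-interval interaction", {
  withr::with_seed(19, {
    hits <- vapply(1:50, function(i) {
      n <- 2800
      strain <- sample(paste0("s", 1:8), n, TRUE)
      condition <- sample(c("clonal", "chimeric"), n, TRUE)
      interval <- sample(c("early", "late"), n, TRUE)
      shape <- rnorm(n)
      # clonal splitting declines across intervals; chimeric stays flat
      p_split <- ifelse(condition == "clonal",
                        ifelse(interval == "early", 0.5, 0.25), 0.35)
      y <- rbinom(n, 1, p_split)
      fit <- fit_splitting_lmm(y, condition, interval, shape, strain)
      fit$ftable$p[fit$ftable$term == "condition:time"] < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.8)
  })
})

test_that("a dominant shape covariate carries the largest F", {
  withr::with_seed(23, {
    n <- 600
    strain <- sample(paste0("s", 1:4), n, TRUE)
    condition <- sample(c("clonal", "chimeric"), n, TRUE)
    interval <- sample(c("early", "late"), n, TRUE)
    shape <- rnorm(n)
    y <- as.numeric(runif(n) < stats::plogis(3 * shape))
    fit <- fit_splitting_lmm(y, condition, interval, shape, strain)
    ft <- fit$ftable[fit$ftable$term != "(Intercept)", ]
    expect_equal(ft$term[which.max(ft$F)], "shape")
  })
})

test_that("an all-zero splitting response degenerates cleanly", {
  fit <- fit_splitting_lmm(rep(0, 40), rep(c("clonal", "chimeric"), 20),
                           rep(c("early", "late"), each = 20),
                           rnorm(40), rep(c("s1", "s2"), 20))
  expect_equal(unname(fit$fixed[["(Intercept)"]]), 0)
  expect_true(all(fit$ftable$F == 0))
  expect_error(fit_splitting_lmm(c(0, 2), "clonal", "early", 1, "s1"),
               "0/1")
})
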