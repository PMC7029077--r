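# Negative-binomial log-link GLM by IRLS, fixed dispersion.
#
# Weights use the NB variance function on the working scale,
# W = mu / (1 + alpha * mu); convergence is judged on the deviance
# (tolerance 1e-8 relative), with a hard cap on iterations.
nb_irls <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100) {
  nb_deviance <- function(y, mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
    2 * sum(t1 - t2)
  }
  # start from the linear fit to shifted log counts
  beta <- tryCatch(qr.coef(qr(X), log(y + 0.5) - offset),
                   error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  dev <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    beta <- drop(beta_new)
    dev_new <- nb_deviance(y, exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30)))
    if (is.finite(dev_new) && abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e) NULL)
  list(beta = beta, cov = cov, deviance = dev, converged = converged && !is.null(cov))
}

#' Wald test of the chimeric-vs-clonal condition contrast
#'
#' Fits, for every gene, a negative-binomial log-link GLM of counts on
#' the `batch + pair + condition` design with `log(size factor)` as
#' offset and the gene's dispersion held fixed, then tests the
#' condition coefficient (chimeric minus clonal; positive log2FC means
#' up in chimeras) with a Wald z statistic against the standard
#' normal. p-values are BH-adjusted across tested genes. Genes whose
#' IRLS fit fails to converge are flagged `tested = FALSE` and carry no
#' p-value.
#'
#' @param counts integer matrix, genes x samples (typically after
#'   [filter_low_expression()]).
#' @param size_factors size factors from [estimate_size_factors()].
#' @param dispersions per-gene `alpha`, e.g. `estimate_dispersions()$alpha`.
#' @param metadata sample metadata with `batch`, `pair`, `condition`
#'   columns; the design matrix uses dummy coding with alphabetically
#'   first reference levels and `clonal` as the condition reference.
#' @param fdr_threshold FDR label threshold for `chimera_biased`
#'   (default 0.10).
#' @return A `de_result` data frame with columns `gene`, `baseMean`
#'   (mean normalized count), `log2FC`, `SE`, `stat`, `pvalue`, `padj`,
#'   `tested`, `chimera_biased`.
#' @examples
#' sim <- simulate_counts(count_sim_spec(n_genes = 60, n_de = 6, seed = 1))
#' sf <- estimate_size_factors(sim$counts)
#' disp <- estimate_dispersions(sim$counts, sf, condition_design(sim$metadata))
#' de <- test_condition_contrast(sim$counts, sf, disp$alpha, sim$metadata)
#' head(de)
#' @export
test_condition_contrast <- function(counts, size_factors, dispersions,
                                    metadata, fdr_threshold = 0.10) {
  check_count_matrix(counts)
  check_metadata(counts, metadata)
  X <- condition_design(metadata)
  if (qr(X)$rank < ncol(X))
    stopf("design matrix is rank deficient; check batch/pair/condition levels")
  cond_col <- which(colnames(X) == attr(X, "condition_col"))
  offset <- log(size_factors)
  alpha <- rep(dispersions, length.out = nrow(counts))
  if (!is.null(names(dispersions)) && all(rownames(counts) %in% names(dispersions)))
    alpha <- dispersions[rownames(counts)]

  ng <- nrow(counts)
  log2FC <- SE <- stat <- pvalue <- rep(NA_real_, ng)
  tested <- logical(ng)
  for (g in seq_len(ng)) {
    fit <- nb_irls(counts[g, ], X, offset, alpha[g])
    if (!fit$converged) next
    b <- fit$beta[cond_col]
    se_nat <- sqrt(fit$cov[cond_col, cond_col])
    if (!is.finite(b) || !is.finite(se_nat) || se_nat <= 0) next
    log2FC[g] <- b / log(2)
    SE[g] <- se_nat / log(2)
    stat[g] <- b / se_nat
    pvalue[g] <- 2 * pnorm(-abs(stat[g]))
    tested[g] <- TRUE
  }
  padj <- rep(NA_real_, ng)
  padj[tested] <- p.adjust(pvalue[tested], method = "BH")
  res <- data.frame(gene = rownames(counts),
                    baseMean = rowMeans(sweep(counts, 2, size_factors, "/")),
                    log2FC = log2FC, SE = SE, stat = stat, pvalue = pvalue,
                    padj = padj, tested = tested,
                    chimera_biased = !is.na(padj) & padj < fdr_threshold,
                    row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}
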