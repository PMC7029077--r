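#' Regularized log2 transform of counts
#'
#' Variance-stabilizing transform for downstream distance analysis:
#' counts are normalized by size factors, shifted-log transformed
#' (`log2(K/s + 0.5)`) and each gene's per-sample deviations from a
#' fitted mean are shrunk toward that mean with an intensity that
#' vanishes as counts grow. With `blind = FALSE` the fitted mean is the
#' design-model (OLS) fit, so known structure (batch, pair, condition)
#' is not shrunk away; with `blind = TRUE` it is the gene's grand mean.
#'
#' The shrinkage factor is `lambda_g = mu_g / (mu_g + k)` with `mu_g`
#' the gene's mean normalized count, so the transform is monotone in
#' the count for a fixed gene and approaches the plain shifted log for
#' high-count genes. The scale `k` defaults to the `a1` coefficient of
#' the mean-dispersion trend (the "extra-Poisson per-mean" scale), the
#' count scale below which sampling noise dominates log fold changes.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors size factors from [estimate_size_factors()].
#' @param metadata sample metadata (used when `blind = FALSE`).
#' @param blind if `TRUE`, shrink toward the grand mean instead of the
#'   design fit.
#' @param shrink_scale override for `k` (counts); `NULL` = from trend.
#' @return Matrix of transformed values, same dimensions as `counts`.
#' @export
rlog_like_transform <- function(counts, size_factors, metadata = NULL,
                                blind = FALSE, shrink_scale = NULL) {
  check_count_matrix(counts)
  z <- sweep(counts, 2, size_factors, "/")
  y <- log2(z + 0.5)
  mu <- rowMeans(z)
  if (blind || is.null(metadata)) {
    fitted <- matrix(rowMeans(y), nrow(y), ncol(y))
  } else {
    X <- condition_design(metadata)
    H <- X %*% solve(crossprod(X), t(X))
    fitted <- y %*% t(H)
  }
  if (is.null(shrink_scale)) {
    disp <- estimate_dispersions(counts, size_factors,
                                 if (blind || is.null(metadata)) {
                                   matrix(1, ncol(counts), 1)
                                 } else condition_design(metadata))
    shrink_scale <- max(disp$trend["a1"], 1)
  }
  lambda <- mu / (mu + shrink_scale)
  out <- fitted + lambda * (y - fitted)
  dimnames(out) <- dimnames(counts)
  out
}
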