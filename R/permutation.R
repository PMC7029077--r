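#' Permutation test for a candidate gene set's mean log2 fold change
#'
#' Tests whether a gene set's mean log2 fold change is more extreme
#' than expected for a random set of the same size: each of `n_perm`
#' permutations draws `|set|` values without replacement from the full
#' log2FC table and the empirical p-value is the fraction of
#' permutation means at or beyond the observed mean (`<=` for
#' direction `"lesser"`, `>=` for `"greater"`; ties count). No `+1`
#' correction is applied, so `p = 0` is possible at finite `n_perm`
#' and the resolution is `1/n_perm`.
#'
#' @param gene_set character vector of set members.
#' @param log2fc named numeric vector of log2 fold changes over the
#'   whole data set (e.g. `setNames(de$log2FC, de$gene)` over tested
#'   genes), or a `de_result`.
#' @param n_perm number of permutations (default 10000).
#' @param direction `"lesser"` (is the set down-regulated?) or
#'   `"greater"`.
#' @param seed integer seed; results are reproducible and invariant to
#'   the order of genes in the table.
#' @param set_id label carried into the output.
#' @return One-row data frame: `set_id`, `n_genes`, `observed_mean`,
#'   `n_perm`, `p`, `direction`, `seed`.
#' @examples
#' lfc <- setNames(rnorm(1000), paste0("g", 1:1000))
#' permutation_set_test(names(sort(lfc))[1:10], lfc, n_perm = 1000,
#'                      seed = 1)$p  # extreme-low set: tiny p
#' @export
permutation_set_test <- function(gene_set, log2fc, n_perm = 10000,
                                 direction = c("lesser", "greater"),
                                 seed = 1L, set_id = "set") {
  direction <- match.arg(direction)
  if (inherits(log2fc, "de_result") || is.data.frame(log2fc))
    log2fc <- setNames(log2fc$log2FC[log2fc$tested],
                       log2fc$gene[log2fc$tested])
  if (n_perm < 1) stopf("n_perm must be >= 1")
  gene_set <- unique(gene_set)
  if (length(setdiff(gene_set, names(log2fc))))
    stopf("gene set contains genes absent from the log2FC table")
  k <- length(gene_set)
  N <- length(log2fc)
  if (k > N) stopf("gene set is larger than the log2FC table")
  obs <- mean(log2fc[gene_set])
  # sort for order invariance of the sampled values
  pool <- as.numeric(log2fc[order(names(log2fc))])
  perm_means <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm),
           function(i) mean(pool[sample.int(N, k)]), numeric(1))
  })
  tol <- 1e-12 * (abs(obs) + 1)        # count exact ties despite rounding
  p <- if (direction == "lesser") {
    mean(perm_means <= obs + tol)
  } else {
    mean(perm_means >= obs - tol)
  }
  data.frame(set_id = set_id, n_genes = k, observed_mean = obs,
             n_perm = as.integer(n_perm), p = p, direction = direction,
             seed = as.integer(seed))
}
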