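#' Median fold-change summary of a gene set
#'
#' Summarizes a gene set's differential expression by the median log2
#' fold change, the corresponding median fold change (`2^median`, exact
#' by monotonicity of `2^x`), and a nonparametric bootstrap standard
#' error of the median.
#'
#' @param de a `de_result` from [test_condition_contrast()].
#' @param gene_set character vector of gene ids; must all be tested in
#'   `de`.
#' @param set_id label carried into the output.
#' @param n_boot bootstrap resamples for the SE of the median.
#' @param seed seed for the bootstrap.
#' @return One-row data frame: `set_id`, `n_genes`, `median_log2fc`,
#'   `median_fc`, `se_median`.
#' @examples
#' de <- data.frame(gene = c("a", "b", "c"), log2FC = c(-1.2, -1.0, -0.5),
#'                  tested = TRUE)
#' class(de) <- c("de_result", "data.frame")
#' summarize_gene_set_fc(de, c("a", "b", "c"))$median_fc  # 2^-1 = 0.5
#' @export
summarize_gene_set_fc <- function(de, gene_set, set_id = "set",
                                  n_boot = 1000, seed = 1L) {
  if (!length(gene_set)) stopf("gene set is empty")
  idx <- match(gene_set, de$gene)
  if (anyNA(idx))
    stopf("gene set contains genes absent from the DE table: %s",
          paste(head(gene_set[is.na(idx)], 3), collapse = ", "))
  if (!all(de$tested[idx]))
    stopf("gene set contains untested genes")
  lfc <- de$log2FC[idx]
  med <- median(lfc)
  se <- with_seed(derive_seed(seed, "fc-boot"), {
    boots <- replicate(n_boot, median(sample(lfc, replace = TRUE)))
    sd(boots)
  })
  data.frame(set_id = set_id, n_genes = length(lfc), median_log2fc = med,
             median_fc = 2^med, se_median = se)
}
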