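#' Per-term median log2 fold changes at deepest annotation level
#'
#' Summarizes the overall expression shift of ontology terms: each gene
#' contributes only at its most specific annotated term(s) — a term is
#' dropped for a gene when one of that term's descendants also
#' annotates the gene — then the median log2 fold change of the
#' contributing, tested genes is taken per term. Only terms within the
#' (inclusive) member-count window are reported. A gene with two
#' incomparable most-specific terms contributes to both.
#'
#' @param onto an [ontology_annotation()] (direct or propagated; the
#'   deepest-level rule reduces both to the same minimal terms).
#' @param de a `de_result` from [test_condition_contrast()].
#' @param size_window inclusive (min, max) member-count window,
#'   default `c(13, 399)`.
#' @param namespace restrict to terms of this namespace; `NULL` keeps
#'   all.
#' @return List with `table` (per-term `term`, `n_genes`,
#'   `median_log2fc`, `median_fc`) sorted by `median_log2fc`, and
#'   `overall`, a named vector giving the median across term medians
#'   and the median across all contributing member genes (the two
#'   natural readings of an "overall" term-level median).
#' @export
term_median_log2fc <- function(onto, de, size_window = c(13, 399),
                               namespace = "biological_process") {
  stopifnot(inherits(onto, "ontology_annotation"))
  keep_terms <- onto$terms$id
  if (!is.null(namespace))
    keep_terms <- onto$terms$id[onto$terms$namespace == namespace]
  ann <- unique(onto$annotations[onto$annotations$term %in% keep_terms,
                                 c("gene", "term")])
  anc <- term_ancestors(onto$terms$id, onto$edges)
  # deepest level: drop (gene, term) when a descendant of term also
  # annotates the gene, i.e. term is an ancestor of another of the
  # gene's terms
  by_gene <- split(ann$term, ann$gene)
  deepest <- lapply(by_gene, function(ts) {
    ancestors_here <- unique(unlist(anc[ts], use.names = FALSE))
    setdiff(ts, ancestors_here)
  })
  pairs <- data.frame(gene = rep(names(deepest), lengths(deepest)),
                      term = unlist(deepest, use.names = FALSE))

  lfc <- setNames(de$log2FC, de$gene)
  tested <- setNames(de$tested, de$gene)
  pairs <- pairs[pairs$gene %in% de$gene[de$tested], , drop = FALSE]
  members <- split(pairs$gene, pairs$term)
  n <- lengths(members)
  members <- members[n >= size_window[1] & n <= size_window[2]]
  if (!length(members)) {
    tab <- data.frame(term = character(0), n_genes = integer(0),
                      median_log2fc = numeric(0), median_fc = numeric(0))
    return(list(table = tab,
                overall = c(median_of_term_medians = NA_real_,
                            median_of_member_genes = NA_real_)))
  }
  med <- vapply(members, function(g) median(lfc[g]), numeric(1))
  tab <- data.frame(term = names(members), n_genes = lengths(members),
                    median_log2fc = unname(med), median_fc = 2^unname(med))
  tab <- tab[order(tab$median_log2fc), , drop = FALSE]
  rownames(tab) <- NULL
  all_members <- unique(unlist(members, use.names = FALSE))
  list(table = tab,
       overall = c(median_of_term_medians = median(med),
                   median_of_member_genes = median(lfc[all_members])))
}
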