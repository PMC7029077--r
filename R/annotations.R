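#' Filter annotations by qualifier, evidence code and source
#'
#' Drops annotation rows that are irrelevant or unreliable for
#' enrichment analysis: any qualifier containing `NOT`, the `ND` (no
#' biological data) evidence code, and `IEA` (inferred from electronic
#' annotation) evidence specifically from the InterPro or HAMAP
#' sources. `IEA` annotations from other sources are retained.
#'
#' @param x an [ontology_annotation()] or a data frame of assignments
#'   with `gene`, `term`, `evidence`, `source`, `qualifier` columns.
#' @return Object of the same class with the filtered assignment table.
#' @export
filter_annotations <- function(x) {
  ann <- if (inherits(x, "ontology_annotation")) x$annotations else x
  need <- c("gene", "term", "evidence", "source", "qualifier")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stopf("assignments are missing field(s): %s", paste(miss, collapse = ", "))
  drop <- grepl("NOT", ann$qualifier, fixed = TRUE) |
    ann$evidence == "ND" |
    (ann$evidence == "IEA" & ann$source %in% c("InterPro", "HAMAP"))
  kept <- ann[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (inherits(x, "ontology_annotation")) {
    x$annotations <- kept
    x
  } else kept
}

# named list: term id -> character vector of all ancestors (transitive)
term_ancestors <- function(terms, edges) {
  order <- topological_term_order(terms, edges)
  parents <- split(edges$parent, edges$term)
  anc <- setNames(vector("list", length(terms)), terms)
  for (t in order) {   # parents come before children in 'order'
    ps <- unique(parents[[t]] %||% character(0))
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate annotations to all ancestor terms
#'
#' Takes the ancestor closure of the gene-to-term assignment table:
#' every gene directly annotated to a term becomes annotated to all of
#' that term's ancestors as well (the "true path" convention required
#' for term sizes over the DAG). Idempotent; errors on a cyclic graph.
#'
#' @param onto an [ontology_annotation()].
#' @return The ontology with a propagated assignment table
#'   (`propagated = TRUE`); propagated rows inherit the evidence,
#'   source and qualifier of the direct row they came from, and
#'   duplicate gene-term pairs are collapsed to the first occurrence.
#' @export
propagate_annotations <- function(onto) {
  stopifnot(inherits(onto, "ontology_annotation"))
  anc <- term_ancestors(onto$terms$id, onto$edges)
  ann <- onto$annotations
  extra <- lapply(seq_len(nrow(ann)), function(i) {
    up <- anc[[ann$term[i]]]
    if (!length(up)) return(NULL)
    out <- ann[rep(i, length(up)), , drop = FALSE]
    out$term <- up
    out
  })
  all_rows <- rbind(ann, do.call(rbind, extra))
  all_rows <- all_rows[!duplicated(all_rows[, c("gene", "term")]), , drop = FALSE]
  rownames(all_rows) <- NULL
  onto$annotations <- all_rows
  onto$propagated <- TRUE
  onto
}

# named list: term -> genes, from an annotation table
term_gene_sets <- function(onto) {
  sets <- split(onto$annotations$gene, onto$annotations$term)
  lapply(sets, unique)
}
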