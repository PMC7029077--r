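#' Upper-tail hypergeometric enrichment test for one term
#'
#' Tests over-representation of a term's genes in a selected list drawn
#' from a finite universe: `p = P(X >= observed)` for `X`
#' hypergeometric with the universe partitioned by term membership, and
#' `expected = |selected| * term_size_in_universe / |universe|`.
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param universe character vector; the gene universe.
#' @param term_genes character vector of the term's genes.
#' @return One-row data frame: `expected`, `observed`, `size` (term
#'   size within the universe), `p`, `genes` (selected members,
#'   `;`-joined). `observed = 0` gives `p = 1` exactly.
#' @examples
#' hypergeom_term_test(paste0("g", 1:10), paste0("g", 1:100),
#'                     paste0("g", c(1, 2, 50)))
#' @export
hypergeom_term_test <- function(selected, universe, term_genes) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stopf("selected genes must be a subset of the universe")
  term_in_u <- unique(intersect(term_genes, universe))
  m <- length(term_in_u)
  k <- length(selected)
  hits <- intersect(selected, term_in_u)
  obs <- length(hits)
  p <- if (obs == 0) 1 else phyper(obs - 1, m, length(universe) - m, k,
                                   lower.tail = FALSE)
  data.frame(expected = k * m / length(universe), observed = obs, size = m,
             p = p, genes = paste(sort(hits), collapse = ";"))
}

#' Large-universe tail probability from an expected count
#'
#' Reconstructs the upper-tail probability `P(X >= observed)` for a
#' term directly from the reported expected count and term size, under
#' the large-universe limit of the hypergeometric null in which each of
#' the term's genes is independently selected with probability
#' `expected / size` (binomial; a Poisson with mean `expected` gives
#' the same value to reporting precision). Useful for checking printed
#' enrichment-table arithmetic when the underlying universe is not
#' available.
#'
#' @param expected expected annotated count among selected genes.
#' @param observed observed count.
#' @param size term size.
#' @param method `"binomial"` or `"poisson"`.
#' @return The tail probability.
#' @examples
#' round(upper_tail_from_expected(0.044, 2, 13), 3)
#' @export
upper_tail_from_expected <- function(expected, observed, size,
                                     method = c("binomial", "poisson")) {
  method <- match.arg(method)
  if (observed == 0) return(1)
  if (method == "binomial") {
    q <- expected / size
    1 - sum(dbinom(0:(observed - 1), size, q))
  } else {
    1 - sum(exp(-expected) * expected^(0:(observed - 1)) /
              factorial(0:(observed - 1)))
  }
}

#' Conditional GO-style enrichment over the term DAG
#'
#' Hypergeometric enrichment that respects the nested structure of
#' ontology terms by testing children before parents: terms are visited
#' in reverse topological order, and whenever a term is significant at
#' `alpha`, its annotated genes are removed from every ancestor's gene
#' list before those ancestors are tested. On a flat DAG (all terms
#' children of the root) this reduces to the unconditional per-term
#' test, as does `alpha = 0` (nothing is ever deemed significant, so
#' nothing is removed).
#'
#' The universe for the hypergeometric margins is restricted to genes
#' carrying at least one annotation; both the full and annotated
#' universe sizes are reported as attributes.
#'
#' @param selected selected gene list (subset of `universe`).
#' @param universe gene universe (e.g. all genes tested for DE).
#' @param onto a propagated [ontology_annotation()] (see
#'   [propagate_annotations()]); unpropagated input is an error.
#' @param alpha conditioning/reporting significance level.
#' @param size_window exclusive (min, max) term-size window used for
#'   the `in_window` reporting flag; terms outside it are still tested.
#' @return Data frame with one row per term: `term`, `expected`,
#'   `observed`, `size`, `p`, `genes`, `significant`, `in_window`,
#'   sorted by `p`.
#' @export
conditional_go_enrichment <- function(selected, universe, onto, alpha = 0.05,
                                      size_window = c(8, 400)) {
  stopifnot(inherits(onto, "ontology_annotation"))
  if (!onto$propagated)
    stopf("conditional enrichment needs propagated annotations; run propagate_annotations() first")
  annotated <- unique(onto$annotations$gene)
  uni_ann <- intersect(unique(universe), annotated)
  sel_ann <- intersect(unique(selected), uni_ann)
  sets <- term_gene_sets(onto)
  sets <- lapply(sets, intersect, uni_ann)
  terms <- names(sets)[vapply(sets, length, 1L) > 0]
  topo <- topological_term_order(onto$terms$id, onto$edges)
  topo <- rev(topo[topo %in% terms])           # children before parents
  anc <- term_ancestors(onto$terms$id, onto$edges)

  current <- sets
  rows <- vector("list", length(topo))
  for (i in seq_along(topo)) {
    t <- topo[i]
    res <- hypergeom_term_test(sel_ann, uni_ann, current[[t]])
    rows[[i]] <- cbind(term = t, res)
    if (res$p < alpha) {
      for (up in intersect(anc[[t]], terms))
        current[[up]] <- setdiff(current[[up]], sets[[t]])
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out$in_window <- out$size > size_window[1] & out$size < size_window[2]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- length(unique(universe))
  attr(out, "annotated_universe_size") <- length(uni_ann)
  attr(out, "selected_annotated") <- length(sel_ann)
  out
}

#' KEGG-style pathway enrichment with FDR correction
#'
#' Per-pathway upper-tail hypergeometric tests with
#' Benjamini-Hochberg adjustment across pathways.
#'
#' @param selected selected gene list (subset of `universe`).
#' @param universe gene universe.
#' @param pathways named list of pathway gene vectors (each a subset of
#'   the universe).
#' @param fdr adjusted-p significance threshold (default 0.05).
#' @return Data frame: `pathway`, `expected`, `observed`, `size`, `p`,
#'   `padj`, `significant`, `genes`, sorted by `p`.
#' @export
kegg_enrichment <- function(selected, universe, pathways, fdr = 0.05) {
  if (!length(pathways)) {
    return(data.frame(pathway = character(0), expected = numeric(0),
                      observed = integer(0), size = integer(0),
                      p = numeric(0), padj = numeric(0),
                      significant = logical(0), genes = character(0)))
  }
  rows <- lapply(names(pathways), function(pw)
    cbind(pathway = pw, hypergeom_term_test(selected, universe, pathways[[pw]])))
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$significant <- out$padj < fdr
  out <- out[order(out$p), c("pathway", "expected", "observed", "size", "p",
                             "padj", "significant", "genes")]
  rownames(out) <- NULL
  out
}
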