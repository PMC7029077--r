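#' Ontology annotation container
#'
#' Bundles a term table, an `is_a`-style parent edge table and a
#' GAF-like gene-to-term assignment table. The term graph must be a
#' DAG; a cycle raises an error.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `term`, `parent` (child-to-parent
#'   `is_a` links).
#' @param annotations data frame with columns `gene`, `term`, `evidence`,
#'   `source`, `qualifier`.
#' @param propagated logical; `TRUE` once ancestor closure has been taken.
#' @return An object of class `ontology_annotation`.
#' @export
ontology_annotation <- function(terms, edges, annotations, propagated = FALSE) {
  need <- c("gene", "term", "evidence", "source", "qualifier")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stopf("annotations are missing field(s): %s", paste(miss, collapse = ", "))
  if (!all(c("term", "parent") %in% names(edges)))
    stopf("edges must have columns 'term' and 'parent'")
  if (!all(c("id", "name", "namespace") %in% names(terms)))
    stopf("terms must have columns 'id', 'name', 'namespace'")
  bad <- setdiff(annotations$term, terms$id)
  if (length(bad))
    stopf("annotations reference unknown term(s): %s",
          paste(head(bad, 3), collapse = ", "))
  topological_term_order(terms$id, edges)  # errors on cycles
  structure(list(terms = terms, edges = edges, annotations = annotations,
                 propagated = isTRUE(propagated)),
            class = "ontology_annotation")
}

# Terms sorted parents-before-children; errors if the graph has a cycle.
topological_term_order <- function(ids, edges) {
  edges <- edges[edges$term %in% ids & edges$parent %in% ids, , drop = FALSE]
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(factor(edges$term, levels = ids))
  indeg[names(tab)] <- as.integer(tab)     # in-degree = number of parents
  children <- split(edges$term, edges$parent)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]] %||% character(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stopf("term graph contains a cycle (involving e.g. %s)",
          paste(head(setdiff(ids, out), 3), collapse = ", "))
  out
}

#' Specification for a synthetic ontology annotation set
#'
#' Builds a single-rooted acyclic term graph with a GAF-like assignment
#' table (evidence codes, sources, optional `NOT` qualifiers) and plants
#' over-representation of a designated "selected" gene list in a chosen
#' number of terms at given odds.
#'
#' @param n_terms number of non-root terms.
#' @param n_genes size of the gene universe.
#' @param dag_depth maximum depth below the root.
#' @param term_size_distribution `function(n)` returning `n` direct term
#'   sizes (gene counts) — defaults to a dispersed NB around 25, floored
#'   at 5.
#' @param n_selected size of the designated selected gene list.
#' @param n_enriched_terms number of terms in which selected genes are
#'   over-represented.
#' @param enrichment_odds odds multiplier (> 1 plants enrichment; exactly
#'   1 plants none and the truth list is empty).
#' @param evidence_code_mix named probabilities over evidence classes
#'   `EXP`, `IDA`, `ISS`, `IEA:InterPro`, `IEA:HAMAP`, `IEA:UniProtKB`,
#'   `ND`.
#' @param qualifier_mix proportion of assignments carrying a `NOT`
#'   qualifier.
#' @param namespace ontology namespace label for all terms.
#' @param seed integer seed.
#' @return An object of class `annotation_sim_spec`.
#' @export
annotation_sim_spec <- function(n_terms = 60,
                                n_genes = 2000,
                                dag_depth = 4,
                                term_size_distribution = NULL,
                                n_selected = 100,
                                n_enriched_terms = 3,
                                enrichment_odds = 8,
                                evidence_code_mix = c(EXP = 0.15, IDA = 0.35,
                                                      ISS = 0.2,
                                                      `IEA:InterPro` = 0.1,
                                                      `IEA:HAMAP` = 0.05,
                                                      `IEA:UniProtKB` = 0.1,
                                                      ND = 0.05),
                                qualifier_mix = 0.02,
                                namespace = "biological_process",
                                seed = 1L) {
  if (n_enriched_terms > n_terms) stopf("n_enriched_terms exceeds n_terms")
  if (enrichment_odds < 1) stopf("enrichment_odds must be >= 1")
  if (dag_depth < 1) stopf("dag_depth must be >= 1")
  if (is.null(term_size_distribution))
    term_size_distribution <- function(n) pmax(5L, rnbinom(n, mu = 25, size = 2))
  structure(list(n_terms = as.integer(n_terms), n_genes = as.integer(n_genes),
                 dag_depth = as.integer(dag_depth),
                 term_size_distribution = term_size_distribution,
                 n_selected = as.integer(n_selected),
                 n_enriched_terms = as.integer(n_enriched_terms),
                 enrichment_odds = enrichment_odds,
                 evidence_code_mix = evidence_code_mix,
                 qualifier_mix = qualifier_mix, namespace = namespace,
                 seed = as.integer(seed)),
            class = "annotation_sim_spec")
}

#' Simulate DAG-structured annotations with planted enrichment
#'
#' @param spec an [annotation_sim_spec()].
#' @return A list of class `annotation_sim` with elements `ontology` (an
#'   [ontology_annotation()] of direct, unpropagated assignments),
#'   `selected` (the designated gene list), `universe` (all genes),
#'   `enriched_terms` (truth: ids with planted enrichment; empty when
#'   `enrichment_odds == 1`), and `spec`.
#' @examples
#' ann <- simulate_annotations(annotation_sim_spec(n_terms = 20, seed = 4))
#' head(ann$ontology$annotations)
#' ann$enriched_terms
#' @export
simulate_annotations <- function(spec) {
  stopifnot(inherits(spec, "annotation_sim_spec"))
  with_seed(derive_seed(spec$seed, "annotations"), {
    genes <- sprintf("gene%05d", seq_len(spec$n_genes))
    root <- "T:0000"
    ids <- sprintf("T:%04d", seq_len(spec$n_terms))
    depth <- sample.int(spec$dag_depth, spec$n_terms, replace = TRUE)
    # acyclic by construction: parents only among strictly shallower terms
    edges <- do.call(rbind, lapply(seq_len(spec$n_terms), function(i) {
      shallower <- ids[depth < depth[i]]
      parents <- if (!length(shallower)) root else {
        n_par <- sample(1:min(2, length(shallower)), 1)
        sample(shallower, n_par)
      }
      data.frame(term = ids[i], parent = parents)
    }))
    terms <- data.frame(id = c(root, ids),
                        name = c("root", sprintf("synthetic term %d",
                                                 seq_len(spec$n_terms))),
                        namespace = spec$namespace)

    selected <- sample(genes, spec$n_selected)
    enriched <- if (spec$enrichment_odds > 1 && spec$n_enriched_terms > 0) {
      sample(ids, spec$n_enriched_terms)
    } else character(0)

    sizes <- spec$term_size_distribution(spec$n_terms)
    w_base <- rep(1, spec$n_genes)
    w_enr <- ifelse(genes %in% selected, spec$enrichment_odds, 1)
    assign_rows <- lapply(seq_len(spec$n_terms), function(i) {
      w <- if (ids[i] %in% enriched) w_enr else w_base
      members <- sample(genes, min(sizes[i], spec$n_genes), prob = w)
      data.frame(gene = members, term = ids[i])
    })
    ann <- do.call(rbind, assign_rows)
    mix <- spec$evidence_code_mix / sum(spec$evidence_code_mix)
    code <- sample(names(mix), nrow(ann), replace = TRUE, prob = mix)
    ann$evidence <- sub(":.*$", "", code)
    ann$source <- ifelse(grepl(":", code), sub("^.*:", "", code), "dictyBase")
    ann$qualifier <- ifelse(runif(nrow(ann)) < spec$qualifier_mix, "NOT", "")
    rownames(ann) <- NULL

    structure(list(ontology = ontology_annotation(terms, edges, ann),
                   selected = selected, universe = genes,
                   enriched_terms = sort(enriched), spec = spec),
              class = "annotation_sim")
  })
}
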