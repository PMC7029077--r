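# Shared fixture builders; everything is generated in code at test time.

# Small ontology: root <- A <- (B, C); D <- root; gene assignments direct.
toy_ontology <- function() {
  terms <- data.frame(id = c("root", "A", "B", "C", "D"),
                      name = c("root", "a", "b", "c", "d"),
                      namespace = "biological_process")
  edges <- data.frame(term = c("A", "B", "C", "D"),
                      parent = c("root", "A", "A", "root"))
  ann <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                    term = c("B", "B", "C", "A", "D"),
                    evidence = "IDA", source = "dictyBase", qualifier = "")
  ontology_annotation(terms, edges, ann)
}

# Flat DAG: every term a child of the root, genes spread over terms.
flat_ontology <- function(n_terms = 6, genes_per_term = 8, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("F:%02d", seq_len(n_terms))
    terms <- data.frame(id = c("root", ids),
                        name = c("root", ids),
                        namespace = "biological_process")
    edges <- data.frame(term = ids, parent = "root")
    genes <- sprintf("g%03d", 1:200)
    ann <- do.call(rbind, lapply(ids, function(t)
      data.frame(gene = sample(genes, genes_per_term), term = t,
                 evidence = "IDA", source = "dictyBase", qualifier = "")))
    ontology_annotation(terms, edges, ann)
  })
}

# Random DAG for closure-oracle tests.
random_ontology <- function(n_terms = 30, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("R:%02d", seq_len(n_terms))
    depth <- sample(1:4, n_terms, replace = TRUE)
    edges <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
      lower <- ids[depth < depth[i]]
      parents <- if (!length(lower)) "root" else
        sample(lower, sample(1:min(2, length(lower)), 1))
      data.frame(term = ids[i], parent = parents)
    }))
    terms <- data.frame(id = c("root", ids), name = c("root", ids),
                        namespace = "biological_process")
    genes <- sprintf("g%03d", 1:100)
    ann <- do.call(rbind, lapply(ids, function(t)
      data.frame(gene = sample(genes, 5), term = t,
                 evidence = "IDA", source = "dictyBase", qualifier = "")))
    ontology_annotation(terms, edges, ann)
  })
}

# Brute-force transitive reachability over the parent edges (oracle for
# propagation): returns all ancestors of `term` by repeated expansion.
brute_force_ancestors <- function(term, edges) {
  anc <- character(0)
  frontier <- term
  repeat {
    up <- unique(edges$parent[edges$term %in% frontier])
    new <- setdiff(up, anc)
    if (!length(new)) break
    anc <- c(anc, new)
    frontier <- new
  }
  anc
}

# Rasterized disk mask for measurement oracles.
disk_mask <- function(radius, pad = 10) {
  n <- 2 * (radius + pad)
  ctr <- radius + pad
  m <- matrix(0L, n, n)
  for (r in seq_len(n)) {
    span <- radius^2 - (r - ctr)^2
    if (span >= 0) {
      cc <- ceiling(ctr - sqrt(span)):floor(ctr + sqrt(span))
      m[r, cc] <- 1L
    }
  }
  m
}

# Rasterized axis-aligned ellipse with semi-axes (a rows, b cols).
ellipse_mask <- function(a, b, pad = 10) {
  nr <- 2 * (a + pad); ncc <- 2 * (b + pad)
  cr <- a + pad; cc <- b + pad
  m <- matrix(0L, nr, ncc)
  for (r in seq_len(nr)) for (c in seq_len(ncc))
    if (((r - cr) / a)^2 + ((c - cc) / b)^2 <= 1) m[r, c] <- 1L
  m
}
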