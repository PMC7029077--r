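test_that("hypergeometric tail equals exhaustive enumeration on small universes", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      N <- sample(8:14, 1)
      universe <- paste0("g", seq_len(N))
      term <- sample(universe, sample(2:5, 1))
      k <- sample(2:5, 1)
      selected <- sample(universe, k)
      res <- hypergeom_term_test(selected, universe, term)
      # oracle: enumerate every possible selection of size k
      combos <- utils::combn(N, k)
      ovl <- apply(combos, 2, function(ix)
        length(intersect(universe[ix], term)))
      p_brute <- mean(ovl >= res$observed)
      expect_equal(res$p, p_brute, tolerance = 1e-12)
      expect_equal(res$expected, k * length(term) / N)
    }
  })
})

test_that("observing zero members gives p exactly 1", {
  res <- hypergeom_term_test(paste0("g", 1:5), paste0("g", 1:50),
                             paste0("g", 40:45))
  expect_identical(res$p, 1)
  expect_equal(res$observed, 0)
})

test_that("conditional enrichment on a flat DAG equals the unconditional test", {
  onto <- propagate_annotations(flat_ontology(seed = 3))
  universe <- sprintf("g%03d", 1:200)
  selected <- withr::with_seed(8, sample(universe, 30))
  cond <- conditional_go_enrichment(selected, universe, onto, alpha = 0.05)
  uni_ann <- intersect(universe, unique(onto$annotations$gene))
  sel_ann <- intersect(selected, uni_ann)
  sets <- dictydev:::term_gene_sets(onto)
  for (i in seq_len(nrow(cond))) {
    t <- cond$term[i]
    if (t == "root") next     # the root absorbs significant children
    direct <- hypergeom_term_test(sel_ann, uni_ann, sets[[t]])
    expect_equal(cond$p[i], direct$p)
    expect_equal(cond$observed[i], direct$observed)
  }
})

test_that("alpha = 0 disables conditioning entirely", {
  onto <- propagate_annotations(random_ontology(n_terms = 25, seed = 12))
  universe <- sprintf("g%03d", 1:100)
  selected <- withr::with_seed(2, sample(unique(onto$annotations$gene), 15))
  cond0 <- conditional_go_enrichment(selected, universe, onto, alpha = 0)
  uni_ann <- intersect(universe, unique(onto$annotations$gene))
  sel_ann <- intersect(selected, uni_ann)
  sets <- dictydev:::term_gene_sets(onto)
  for (i in seq_len(nrow(cond0))) {
    direct <- hypergeom_term_test(sel_ann, uni_ann, sets[[cond0$term[i]]])
    expect_equal(cond0$p[i], direct$p)
  }
})

test_that("a parent driven only by a significant child is conditioned away", {
  # parent P has no signal of its own: all its selected genes sit in
  # child C; after C tests significant its genes leave P's list
  terms <- data.frame(id = c("root", "P", "C"), name = c("r", "p", "c"),
                      namespace = "biological_process")
  edges <- data.frame(term = c("P", "C"), parent = c("root", "P"))
  universe <- paste0("g", 1:200)
  child_genes <- paste0("g", 1:10)
  parent_extra <- paste0("g", 11:40)
  ann <- rbind(
    data.frame(gene = child_genes, term = "C", evidence = "IDA",
               source = "x", qualifier = ""),
    data.frame(gene = parent_extra, term = "P", evidence = "IDA",
               source = "x", qualifier = ""),
    data.frame(gene = paste0("g", 41:200), term = "root",
               evidence = "IDA", source = "x", qualifier = ""))
  onto <- propagate_annotations(ontology_annotation(terms, edges, ann))
  selected <- paste0("g", 1:8)     # all selected genes are in C
  res <- conditional_go_enrichment(selected, universe, onto, alpha = 0.05)
  res <- setNames(split(res, res$term), res$term)
  expect_true(res$C$significant)
  expect_false(res$P$significant)
  expect_equal(res$P$observed, 0)  # C's genes were removed before testing P
  # brute-force check of the conditioned parent test
  uni_ann <- unique(onto$annotations$gene)
  direct <- hypergeom_term_test(intersect(selected, uni_ann), uni_ann,
                                setdiff(c(child_genes, parent_extra),
                                        child_genes))
  expect_equal(res$P$p, direct$p)
  # conditioning never makes the parent look more enriched
  uncond <- hypergeom_term_test(intersect(selected, uni_ann), uni_ann,
                                c(child_genes, parent_extra))
  expect_gte(res$P$p, uncond$p)
})

test_that("unpropagated input to conditional enrichment is an error", {
  expect_error(conditional_go_enrichment("g1", paste0("g", 1:5),
                                         toy_ontology()), "propagate")
})

test_that("expected-count identity holds for every reported term", {
  onto <- propagate_annotations(random_ontology(n_terms = 20, seed = 5))
  universe <- sprintf("g%03d", 1:100)
  selected <- withr::with_seed(4, sample(unique(onto$annotations$gene), 12))
  res <- conditional_go_enrichment(selected, universe, onto)
  n_sel <- attr(res, "selected_annotated")
  n_uni <- attr(res, "annotated_universe_size")
  # identity is over the *current* (conditioned) term size
  expect_equal(res$expected, n_sel * res$size / n_uni)
  expect_true(all(res$observed <= pmin(res$size, n_sel)))
})

test_that("pathway enrichment adjusts across pathways and finds planted signal", {
  # single pathway: adjusted p equals raw p
  universe <- paste0("g", 1:100)
  pw <- list(pw1 = paste0("g", 1:10))
  one <- kegg_enrichment(paste0("g", 1:5), universe, pw)
  expect_equal(one$padj, one$p)
  # selected = universe: every term fully observed, p = 1
  all_sel <- kegg_enrichment(universe, universe,
                             list(a = paste0("g", 1:10), b = paste0("g", 20:40)))
  expect_true(all(all_sel$p == 1))
  expect_equal(all_sel$observed, all_sel$size)

  # power: planted pathway (odds 10, size 30 in a 10,000-gene universe)
  # detected at FDR 0.05 in at least 95% of simulations
  withr::with_seed(60, {
    big_uni <- sprintf("u%05d", 1:10000)
    hits <- vapply(1:100, function(i) {
      pw_genes <- sample(big_uni, 30)
      w <- ifelse(big_uni %in% pw_genes, 10, 1)
      selected <- sample(big_uni, 1000, prob = w)
      decoys <- lapply(1:9, function(j) sample(big_uni, 30))
      res <- kegg_enrichment(selected, big_uni,
                             c(list(planted = pw_genes),
                               setNames(decoys, paste0("d", 1:9))))
      res$significant[res$pathway == "planted"]
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  })
})

test_that("printed-table arithmetic is reproduced from expected counts", {
  expect_equal(round(upper_tail_from_expected(0.044, 2, 13), 3), 0.001)
  expect_equal(round(upper_tail_from_expected(0.071, 2, 9), 3), 0.002)
  expect_equal(round(upper_tail_from_expected(0.044, 2, 13, "poisson"), 3),
               0.001)
  expect_identical(upper_tail_from_expected(0.5, 0, 10), 1)
})
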