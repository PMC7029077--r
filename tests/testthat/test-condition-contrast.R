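test_that("the condition log2FC on noiseless NB means equals the planted value", {
  # counts constructed exactly at the GLM means: the IRLS fit must recover
  # the condition coefficient essentially exactly
  meta <- data.frame(sample = paste0("s", 1:6),
                     batch = "b1", pair = rep(c("p1", "p2"), each = 3),
                     condition = rep(c("clonal", "clonal", "chimeric"), 2))
  lfc <- c(g1 = 1, g2 = -2, g3 = 0)
  q <- c(g1 = 100, g2 = 400, g3 = 50)
  mu <- t(sapply(names(q), function(g)
    q[g] * 2^(ifelse(meta$condition == "chimeric", lfc[g], 0))))
  counts <- round(mu)
  storage.mode(counts) <- "integer"
  colnames(counts) <- meta$sample
  de <- test_condition_contrast(counts, rep(1, 6), rep(1e-8, 3), meta)
  expect_equal(de$log2FC, unname(lfc[de$gene]), tolerance = 0.02)
})

test_that("Wald test holds its size on null NB data with known dispersion", {
  sim <- simulate_counts(count_sim_spec(
    n_genes = 2000, n_de = 0, dispersion = 0.05, strain_sd = 0, seed = 101))
  sf <- estimate_size_factors(sim$counts)
  de <- test_condition_contrast(sim$counts, sf, rep(0.05, 2000),
                                sim$metadata)
  frac <- mean(de$pvalue[de$tested] < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # BH adjustment is monotone in the raw p ranking
  ord <- order(de$pvalue[de$tested])
  expect_true(all(diff(de$padj[de$tested][ord]) >= -1e-12))
  expect_true(all(de$padj[de$tested] >= de$pvalue[de$tested] - 1e-12))
})

test_that("planted effects of +/-1 log2 units are recovered on average", {
  # balanced planting (half up, half down) so composition bias in the
  # median-of-ratios normalization cancels
  sim <- simulate_counts(count_sim_spec(
    n_genes = 800, n_de = 120, planted_lfc = 1, dispersion = 0.05,
    strain_sd = 0, seed = 55))
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, condition_design(sim$metadata))
  de <- test_condition_contrast(sim$counts, sf, disp$alpha, sim$metadata)
  m <- merge(de, sim$truth)
  expect_equal(mean(m$log2FC[m$true_lfc == 1]), 1, tolerance = 0.1)
  expect_equal(mean(m$log2FC[m$true_lfc == -1]), -1, tolerance = 0.1)
})

test_that("relabelling condition orthogonally to the truth erases the signal", {
  sim <- simulate_counts(count_sim_spec(
    n_genes = 600, n_de = 80, planted_lfc = 1, dispersion = 0.05,
    strain_sd = 0, seed = 19))
  sf <- estimate_size_factors(sim$counts)
  planted <- sim$truth$gene[sim$truth$true_lfc != 0]

  # balanced relabelling: the new "chimeric" group takes its expected
  # share (1/3) from each true condition, so the new contrast is exactly
  # orthogonal to the planted one and planted p-values must be uniform
  meta_bal <- sim$metadata
  chi <- which(meta_bal$condition == "chimeric")
  clo <- which(meta_bal$condition == "clonal")
  new_chi <- withr::with_seed(3, c(sample(chi, 4), sample(clo, 8)))
  meta_bal$condition <- "clonal"
  meta_bal$condition[new_chi] <- "chimeric"
  de_bal <- test_condition_contrast(sim$counts, sf, rep(0.05, 600), meta_bal)
  pv <- de_bal$pvalue[de_bal$tested & de_bal$gene %in% planted]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)

  # and compared with the true labels, a random permutation collapses
  # the number of planted genes called chimera-biased
  de_true <- test_condition_contrast(sim$counts, sf, rep(0.05, 600),
                                     sim$metadata)
  meta_perm <- sim$metadata
  meta_perm$condition <- withr::with_seed(4, sample(meta_perm$condition))
  de_perm <- test_condition_contrast(sim$counts, sf, rep(0.05, 600),
                                     meta_perm)
  hits_true <- sum(de_true$chimera_biased & de_true$gene %in% planted)
  hits_perm <- sum(de_perm$chimera_biased & de_perm$gene %in% planted)
  expect_gt(hits_true, 60)           # nearly all of the 80 planted genes
  expect_lt(hits_perm, 0.2 * hits_true)
})

test_that("the condition contrast matches an established NB GLM fitter", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(count_sim_spec(
    n_genes = 150, n_de = 20, dispersion = 0.05, seed = 33))
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, sf, condition_design(sim$metadata))
  de <- test_condition_contrast(sim$counts, sf, disp$alpha, sim$metadata)

  meta <- sim$metadata
  meta$batch <- factor(meta$batch); meta$pair <- factor(meta$pair)
  meta$condition <- factor(meta$condition, levels = c("clonal", "chimeric"))
  dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts, meta,
                                        ~ batch + pair + condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("condition", "chimeric", "clonal"))
  both <- de$tested & !is.na(res$log2FoldChange)
  # same estimand; dispersion machinery differs, so agreement is close
  # but not exact
  expect_gt(cor(de$log2FC[both], res$log2FoldChange[both]), 0.98)
  expect_lt(median(abs(de$log2FC[both] - res$log2FoldChange[both])), 0.05)
})

test_that("rank-deficient designs are rejected", {
  sim <- simulate_counts(count_sim_spec(n_genes = 10, n_de = 0, seed = 1))
  meta <- sim$metadata
  meta$condition <- "clonal"   # contrast column collinear/absent
  expect_error(suppressWarnings(
    test_condition_contrast(sim$counts, rep(1, nrow(meta)),
                            rep(0.1, 10), meta)))
})
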