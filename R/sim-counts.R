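#' Specification for a clonal/chimeric count-matrix simulation
#'
#' Describes a synthetic RNA-seq experiment that mirrors the paired trio
#' design used to contrast clonal and chimeric aggregates: for every
#' strain pair and every replicate batch there are three libraries, one
#' per clonal parent strain and one for the 1:1 chimera. Counts are
#' negative-binomial with `Var = mu + alpha * mu^2`.
#'
#' The chimeric library's expected (pre-size-factor) count for a gene is
#' the average of the two parental clonal means times `2^lfc`, where
#' `lfc` is the planted chimera effect — chimeric transcriptomes sit
#' between their parents except where an effect is planted.
#'
#' @param n_genes number of genes.
#' @param pairs character vector of strain-pair labels (biological
#'   replicates).
#' @param batches character vector of batch labels (library prep /
#'   sequencing replicates); each pair contributes one trio per batch.
#' @param baseline_mean scale of mean expression; per-gene baselines are
#'   drawn log-normally around this value.
#' @param dispersion NB dispersion `alpha`, scalar or per-gene vector.
#' @param n_de number of genes with a planted chimera effect.
#' @param planted_lfc signed log2 fold change planted in DE genes;
#'   length 1 (alternating sign across DE genes) or length `n_de`.
#' @param size_factor_range range from which per-sample size factors are
#'   drawn log-uniformly.
#' @param batch_sd,pair_sd,strain_sd standard deviations (log2 units) of
#'   per-gene batch, pair and within-pair strain effects.
#' @param seed integer seed; all output is reproducible given the spec.
#'
#' @return An object of class `count_sim_spec`.
#' @seealso [simulate_counts()]
#' @export
count_sim_spec <- function(n_genes = 2000,
                           pairs = c("ab", "cd", "ef", "gh"),
                           batches = c("b1", "b2", "b3"),
                           baseline_mean = 100,
                           dispersion = 0.05,
                           n_de = 100,
                           planted_lfc = 1,
                           size_factor_range = c(0.5, 2),
                           batch_sd = 0.1,
                           pair_sd = 0.2,
                           strain_sd = 0.25,
                           seed = 1L) {
  if (n_de > n_genes) stopf("n_de (%d) exceeds n_genes (%d)", n_de, n_genes)
  if (any(dispersion <= 0)) stopf("dispersion must be > 0")
  if (length(dispersion) != 1 && length(dispersion) != n_genes)
    stopf("dispersion must be scalar or length n_genes")
  if (any(size_factor_range <= 0) || diff(size_factor_range) < 0)
    stopf("size_factor_range must be a positive increasing interval")
  if (!length(planted_lfc) %in% c(1L, max(n_de, 1L)))
    stopf("planted_lfc must have length 1 or n_de")
  spec <- list(n_genes = as.integer(n_genes), pairs = pairs, batches = batches,
               baseline_mean = baseline_mean, dispersion = dispersion,
               n_de = as.integer(n_de), planted_lfc = planted_lfc,
               size_factor_range = size_factor_range, batch_sd = batch_sd,
               pair_sd = pair_sd, strain_sd = strain_sd, seed = as.integer(seed))
  structure(spec, class = "count_sim_spec")
}

#' Simulate a clonal/chimeric count matrix with recorded ground truth
#'
#' Draws NB counts under the trio design described by [count_sim_spec()].
#' Gene-level means combine a log-normal baseline with per-gene batch,
#' pair and strain effects; a chosen subset of genes carries a planted
#' condition (chimeric vs clonal) log2 fold change. Size factors are
#' drawn log-uniformly and recorded, so normalization can be checked
#' against truth.
#'
#' @param spec a [count_sim_spec()].
#' @return A list of class `count_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{metadata}{data frame with `sample`, `batch`, `pair`,
#'       `condition`, `strain`.}
#'     \item{truth}{data frame with `gene`, `true_lfc` (planted condition
#'       log2FC, 0 for null genes), `baseline`.}
#'     \item{size_factors}{named numeric vector of true size factors.}
#'     \item{spec}{the input spec (seed included).}
#'   }
#' @examples
#' sim <- simulate_counts(count_sim_spec(n_genes = 200, n_de = 10, seed = 3))
#' dim(sim$counts)
#' table(sim$metadata$condition)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(derive_seed(spec$seed, "counts"), {
    ng <- spec$n_genes
    genes <- sprintf("gene%05d", seq_len(ng))
    alpha <- rep(spec$dispersion, length.out = ng)

    # sample layout: pair x batch x (clonal X, clonal Y, chimera)
    grid <- expand.grid(member = c("X", "Y", "M"), pair = spec$pairs,
                        batch = spec$batches, stringsAsFactors = FALSE)
    strain <- ifelse(grid$member == "M",
                     paste0(grid$pair, "-mix"),
                     paste0(grid$pair, "-", grid$member))
    meta <- data.frame(
      sample = sprintf("%s_%s_%s", grid$pair, grid$batch,
                       c(X = "cl1", Y = "cl2", M = "chi")[grid$member]),
      batch = grid$batch, pair = grid$pair,
      condition = ifelse(grid$member == "M", "chimeric", "clonal"),
      strain = strain, stringsAsFactors = FALSE)
    ns <- nrow(meta)

    q0 <- spec$baseline_mean * 2^rnorm(ng, 0, 1)        # per-gene baseline
    beta_batch <- matrix(rnorm(ng * length(spec$batches), 0, spec$batch_sd),
                         ng, dimnames = list(genes, spec$batches))
    beta_pair <- matrix(rnorm(ng * length(spec$pairs), 0, spec$pair_sd),
                        ng, dimnames = list(genes, spec$pairs))
    # within-pair strain deviations (X and Y around the pair mean)
    beta_strain <- array(rnorm(ng * length(spec$pairs) * 2, 0, spec$strain_sd),
                         dim = c(ng, length(spec$pairs), 2),
                         dimnames = list(genes, spec$pairs, c("X", "Y")))

    true_lfc <- numeric(ng)
    if (spec$n_de > 0) {
      de_idx <- sample.int(ng, spec$n_de)
      lfc <- if (length(spec$planted_lfc) == 1) {
        spec$planted_lfc * rep_len(c(1, -1), spec$n_de)
      } else spec$planted_lfc
      true_lfc[de_idx] <- lfc
    }

    sf <- exp(runif(ns, log(spec$size_factor_range[1]),
                    log(spec$size_factor_range[2])))
    names(sf) <- meta$sample

    counts <- matrix(0L, ng, ns, dimnames = list(genes, meta$sample))
    for (s in seq_len(ns)) {
      p <- meta$pair[s]
      base <- q0 * 2^(beta_batch[, meta$batch[s]] + beta_pair[, p])
      mu <- if (meta$condition[s] == "chimeric") {
        # chimera mean = average of the two parental clonal means, then
        # the planted chimera effect on top
        0.5 * base * (2^beta_strain[, p, "X"] + 2^beta_strain[, p, "Y"]) *
          2^true_lfc
      } else {
        memb <- if (grepl("-X$", meta$strain[s])) "X" else "Y"
        base * 2^beta_strain[, p, memb]
      }
      counts[, s] <- as.integer(rnbinom(ng, mu = sf[s] * mu,
                                        size = 1 / alpha))
    }

    structure(list(counts = counts, metadata = meta,
                   truth = data.frame(gene = genes, true_lfc = true_lfc,
                                      baseline = q0),
                   size_factors = sf, spec = spec),
              class = "count_sim")
  })
}
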