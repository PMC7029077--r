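#' Specification for a reference developmental time-course simulation
#'
#' Emulates a reference expression series sampled along multicellular
#' development (by default 19 time points with 2 replicate filters, as
#' in the AX4 filter-development series used for staging). A subset of
#' "timing" genes follows smooth log2-mean trajectories over the time
#' index; the rest are flat.
#'
#' @param n_timepoints number of time points (>= 4; spline fitting
#'   downstream needs at least 4 distinct positions).
#' @param n_replicates replicates per time point.
#' @param n_genes total genes.
#' @param n_timing_genes genes with non-constant trajectories.
#' @param trajectory_family `"bump"` (Gaussian bump in log2 space) or
#'   `"logistic"` (sigmoidal rise/fall).
#' @param baseline_mean scale of mean expression.
#' @param amplitude_sd SD of trajectory amplitudes (log2 units).
#' @param noise_dispersion NB dispersion of the counts.
#' @param seed integer seed.
#' @return An object of class `timecourse_sim_spec`.
#' @seealso [simulate_reference_timecourse()]
#' @export
timecourse_sim_spec <- function(n_timepoints = 19,
                                n_replicates = 2,
                                n_genes = 1000,
                                n_timing_genes = 300,
                                trajectory_family = c("bump", "logistic"),
                                baseline_mean = 100,
                                amplitude_sd = 1.5,
                                noise_dispersion = 0.02,
                                seed = 1L) {
  trajectory_family <- match.arg(trajectory_family)
  if (n_timepoints < 4)
    stopf("n_timepoints must be >= 4 (spline fitting needs >= 4 positions)")
  if (n_timing_genes > n_genes) stopf("n_timing_genes exceeds n_genes")
  if (noise_dispersion <= 0) stopf("noise_dispersion must be > 0")
  structure(list(n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 n_genes = as.integer(n_genes),
                 n_timing_genes = as.integer(n_timing_genes),
                 trajectory_family = trajectory_family,
                 baseline_mean = baseline_mean, amplitude_sd = amplitude_sd,
                 noise_dispersion = noise_dispersion, seed = as.integer(seed)),
            class = "timecourse_sim_spec")
}

# log2 mean trajectory over continuous time index t in [1, n_timepoints]
trajectory_log2_mean <- function(base_log2, amp, center, width, family, t) {
  switch(family,
         bump = base_log2 + amp * exp(-(t - center)^2 / (2 * width^2)),
         logistic = base_log2 + amp / (1 + exp(-(t - center) / width)))
}

#' Simulate a reference developmental time course with ground truth
#'
#' Generates NB counts for a time point x replicate grid in which timing
#' genes follow smooth log2-mean trajectories and the remaining genes
#' are constant. The returned object also carries a query-sample
#' generator: a function that draws a fresh sample whose expected
#' expression corresponds to any (possibly fractional) time index `t*`,
#' giving ground truth for staging-recovery experiments.
#'
#' @param spec a [timecourse_sim_spec()].
#' @return A list of class `timecourse_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x (time x replicate) samples,
#'       columns named `tXX_rY`.}
#'     \item{metadata}{data frame with `sample`, `time_index` (1-based hr
#'       index), `replicate`.}
#'     \item{truth}{matrix of log2 mean trajectories, genes x time.}
#'     \item{timing_genes}{character vector of non-flat genes.}
#'     \item{query_sampler}{`function(t_star, seed)` returning a named
#'       count vector drawn at time index `t_star`.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' tc <- simulate_reference_timecourse(
#'   timecourse_sim_spec(n_genes = 100, n_timing_genes = 40, seed = 2))
#' q11 <- tc$query_sampler(11, seed = 9)
#' length(q11)
#' @export
simulate_reference_timecourse <- function(spec) {
  stopifnot(inherits(spec, "timecourse_sim_spec"))
  with_seed(derive_seed(spec$seed, "timecourse"), {
    ng <- spec$n_genes; nt <- spec$n_timepoints; nr <- spec$n_replicates
    genes <- sprintf("gene%05d", seq_len(ng))
    base_log2 <- log2(spec$baseline_mean) + rnorm(ng, 0, 1)
    amp <- numeric(ng); center <- rep(NA_real_, ng); width <- rep(NA_real_, ng)
    timing <- if (spec$n_timing_genes > 0) sample.int(ng, spec$n_timing_genes) else integer(0)
    amp[timing] <- rnorm(length(timing), 0, spec$amplitude_sd)
    center[timing] <- runif(length(timing), 1, nt)
    width[timing] <- runif(length(timing), nt / 10, nt / 3)

    log2_mu_at <- function(t) {
      out <- base_log2
      if (length(timing))
        out[timing] <- trajectory_log2_mean(base_log2[timing], amp[timing],
                                            center[timing], width[timing],
                                            spec$trajectory_family, t)
      out
    }
    truth <- vapply(seq_len(nt), log2_mu_at, numeric(ng))
    dimnames(truth) <- list(genes, sprintf("t%02d", seq_len(nt)))

    meta <- expand.grid(replicate = seq_len(nr), time_index = seq_len(nt))
    meta <- meta[order(meta$time_index, meta$replicate), , drop = FALSE]
    meta$sample <- sprintf("t%02d_r%d", meta$time_index, meta$replicate)
    rownames(meta) <- NULL
    counts <- matrix(0L, ng, nrow(meta), dimnames = list(genes, meta$sample))
    for (s in seq_len(nrow(meta)))
      counts[, s] <- as.integer(rnbinom(ng, mu = 2^truth[, meta$time_index[s]],
                                        size = 1 / spec$noise_dispersion))

    sampler_seed <- derive_seed(spec$seed, "query")
    query_sampler <- function(t_star, seed = sampler_seed,
                              dispersion = spec$noise_dispersion) {
      if (t_star < 1 || t_star > nt)
        stopf("t_star must lie in [1, %d]", nt)
      mu <- 2^log2_mu_at(t_star)
      with_seed(seed, setNames(as.integer(rnbinom(ng, mu = mu,
                                                   size = 1 / dispersion)),
                               genes))
    }

    structure(list(counts = counts,
                   metadata = meta[, c("sample", "time_index", "replicate")],
                   truth = truth, timing_genes = genes[sort(timing)],
                   query_sampler = query_sampler, spec = spec),
              class = "timecourse_sim")
  })
}
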