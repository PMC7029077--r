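#' Median-of-ratios size factors
#'
#' Per-sample normalization constants in the median-of-ratios
#' convention: for each sample, the median across reference genes of
#' the ratio between its count and the gene's geometric mean across
#' samples. Reference genes are those with a nonzero count in every
#' sample (so the geometric mean is positive).
#'
#' @param counts integer matrix, genes x samples, with gene rownames.
#' @return Named numeric vector of positive size factors, one per
#'   sample. A single-sample matrix yields exactly 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' estimate_size_factors(m)  # proportional to 1, 2
#' @export
estimate_size_factors <- function(counts) {
  check_count_matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stopf(paste("no gene has nonzero counts in every sample;",
                "median-of-ratios needs at least one such gene",
                "(consider a pseudo-reference over positive counts)"))
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - log_geo)))
  if (any(sf <= 0)) stopf("non-positive size factor computed")
  sf
}

#' Filter genes by mean normalized count per library
#'
#' Retains genes whose mean normalized count across libraries is
#' strictly greater than `threshold` — "more than `threshold` reads per
#' library" on the common normalized scale. The default of 4 reads
#' reproduces the independent-filtering rule used upstream of the
#' differential-expression test.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors size factors from [estimate_size_factors()].
#' @param threshold minimum mean normalized count (exclusive); >= 0.
#' @return List with `counts` (the retained rows), `kept` (logical per
#'   input gene) and `report` (`n_before`, `n_after`, `threshold`).
#' @export
filter_low_expression <- function(counts, size_factors, threshold = 4) {
  check_count_matrix(counts)
  if (threshold < 0) stopf("threshold must be >= 0")
  norm_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  kept <- norm_mean > threshold
  list(counts = counts[kept, , drop = FALSE],
       kept = setNames(kept, rownames(counts)),
       report = data.frame(n_before = nrow(counts), n_after = sum(kept),
                           threshold = threshold))
}
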