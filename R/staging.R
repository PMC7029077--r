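#' Relative collection time of a chimera between its parent strains
#'
#' For a trio collected at the same visual developmental stage, places
#' the chimera's collection time `C` on the interval spanned by its two
#' parent strains: with `E = min` and `L = max` of the two strain
#' times, the statistic is `(C - E) / (L - E)`. A value of 0 means the
#' chimera was collected with the earlier strain, 1 with the later
#' strain; values outside `[0, 1]` are possible. Reported rounded to 2
#' decimals alongside the raw value.
#'
#' @param strain_x,chimera,strain_y collection times in minutes
#'   (vectorized).
#' @return Data frame: `E`, `L`, `raw`, `value` (rounded to 2
#'   decimals), `defined` (`FALSE`, with `NA` value, when `E == L`).
#' @examples
#' relative_collection_time(332, 292, 302)$value  # -0.33
#' @export
relative_collection_time <- function(strain_x, chimera, strain_y) {
  if (any(c(strain_x, chimera, strain_y) <= 0))
    stopf("collection times must be positive")
  E <- pmin(strain_x, strain_y)
  L <- pmax(strain_x, strain_y)
  defined <- L != E
  raw <- ifelse(defined, (chimera - E) / (L - E), NA_real_)
  data.frame(E = E, L = L, raw = raw, value = round(raw, 2),
             defined = defined)
}

#' Recode time-point labels as consecutive hr indices
#'
#' Reference series are often sampled at uneven intervals; for spline
#' modeling the time axis is the ordinal collection index: the first
#' label becomes 1, the second 2, and so on, regardless of label
#' spacing (so with 19 points labeled "00".."24", "00" -> 1, "11" ->
#' 12, "24" -> 19).
#'
#' @param labels ordered vector of time-point labels.
#' @return Named integer vector of hr indices `1..length(labels)`.
#' @examples
#' labs <- c("00", "01", "02", "03", "04", "05", "06", "07", "08", "09",
#'           "10", "11", "12", "14", "16", "18", "20", "22", "24")
#' recode_timepoints(labs)[c("00", "11", "24")]
#' @export
recode_timepoints <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stopf("duplicate time point labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  setNames(seq_along(labels), labels)
}

#' Distance profile of query samples against a reference time course
#'
#' For every query sample and every reference time point, the mean
#' Euclidean distance (over the reference replicates at that time
#' point) between the transformed expression vectors, computed over a
#' shared gene subset. Both matrices must be on the same
#' (regularized-log) scale.
#'
#' @param query transformed matrix, genes x query samples.
#' @param reference transformed matrix, genes x reference samples.
#' @param ref_meta data frame with `sample` and `time_index` for the
#'   reference columns.
#' @param query_meta optional data frame with `sample`, `condition`,
#'   `pair` for the query columns (carried into the profile for the
#'   spline stage).
#' @param genes optional gene subset; default is the intersection of
#'   rownames.
#' @return An object of class `distance_profile`: list with `distance`
#'   (query samples x time points), `hr` (integer time indices),
#'   `query_meta`, `genes`.
#' @export
reference_distance_profile <- function(query, reference, ref_meta,
                                       query_meta = NULL, genes = NULL) {
  genes <- genes %||% intersect(rownames(query), rownames(reference))
  if (!length(genes)) stopf("query and reference share no genes")
  q <- query[genes, , drop = FALSE]
  r <- reference[genes, , drop = FALSE]
  times <- sort(unique(ref_meta$time_index))
  D <- matrix(NA_real_, ncol(q), length(times),
              dimnames = list(colnames(q), paste0("t", times)))
  for (ti in seq_along(times)) {
    reps <- ref_meta$sample[ref_meta$time_index == times[ti]]
    d_per_rep <- vapply(reps, function(rs)
      sqrt(colSums((q - r[, rs])^2)), numeric(ncol(q)))
    D[, ti] <- rowMeans(matrix(d_per_rep, ncol = length(reps)))
  }
  structure(list(distance = D, hr = as.integer(times),
                 query_meta = query_meta, genes = genes),
            class = "distance_profile")
}
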