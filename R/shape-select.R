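#' Select decorrelated shape parameters
#'
#' Greedy forward selection in the order the candidates are given: a
#' parameter is kept when its absolute Pearson correlation with every
#' already-kept parameter is below `r_max` (default 0.90, the "pairwise
#' correlation of less than 90%" rule). Constant columns have no
#' defined correlation and are excluded with a warning.
#'
#' @param shape_table data frame of per-particle measurements.
#' @param candidates column names to consider, in priority order.
#' @param r_max absolute correlation cap (exclusive).
#' @return Character vector of kept parameter names.
#' @export
select_shape_parameters <- function(shape_table, candidates, r_max = 0.90) {
  if (length(candidates) < 2) stopf("need >= 2 candidate parameters")
  miss <- setdiff(candidates, names(shape_table))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  kept <- character(0)
  for (p in candidates) {
    v <- shape_table[[p]]
    if (sd(v) == 0 || !all(is.finite(v))) {
      warning(sprintf("'%s' is constant or non-finite; excluded", p),
              call. = FALSE)
      next
    }
    r <- vapply(kept, function(q) abs(cor(v, shape_table[[q]])), numeric(1))
    if (all(r < r_max)) kept <- c(kept, p)
  }
  kept
}

#' PCA summary of aggregate shapes
#'
#' Principal components of z-standardized shape parameters. The sign
#' of PC1 is fixed so that the `area` loading (when area is among the
#' parameters; otherwise the first parameter's loading) is
#' non-negative, making "larger" scores mean larger aggregates.
#'
#' @param shape_table data frame of per-particle measurements.
#' @param parameters columns to use (e.g. from
#'   [select_shape_parameters()]).
#' @return List of class `shape_pca`: `scores` (rows match
#'   `shape_table`), `loadings` (orthonormal columns), `explained`
#'   (proportion of variance per component, non-increasing), `sdev`,
#'   `center`, `scale`.
#' @export
shape_pca <- function(shape_table, parameters) {
  if (length(parameters) < 2) stopf("need >= 2 parameters")
  if (nrow(shape_table) < length(parameters))
    stopf("need at least as many rows as parameters")
  X <- as.matrix(shape_table[, parameters, drop = FALSE])
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  if (any(scl == 0)) stopf("constant column(s): %s",
                           paste(parameters[scl == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  anchor <- if ("area" %in% parameters) "area" else parameters[1]
  if (pc$rotation[anchor, 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev,
                 center = ctr, scale = scl),
            class = "shape_pca")
}
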