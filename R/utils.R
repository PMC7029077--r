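# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix (genes x samples)")
  if (any(counts < 0)) stopf("count matrix has negative entries")
  if (any(counts != floor(counts))) stopf("count matrix has non-integer entries")
  if (is.null(rownames(counts))) stopf("count matrix must have gene ids as rownames")
  invisible(counts)
}

check_metadata <- function(counts, meta) {
  need <- c("batch", "pair", "condition")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("sample metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(meta) != ncol(counts))
    stopf("metadata has %d rows but counts has %d samples", nrow(meta), ncol(counts))
  bad <- setdiff(unique(as.character(meta$condition)), c("clonal", "chimeric"))
  if (length(bad))
    stopf("condition must be 'clonal' or 'chimeric'; found: %s", paste(bad, collapse = ", "))
  invisible(meta)
}

# Deterministic per-stream seed derived from a master seed; kept < 2^31 - 1
# so it is always a valid 32-bit integer seed.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream)))
    s <- (s * 69069 + ch) %% 2147483647
  as.integer(s)
}

# Run code with a locally-set RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Design matrix for the batch + pair + condition GLM. Dummy coding with the
# alphabetically first level as reference; condition reference is forced to
# "clonal" so a positive coefficient means chimera-biased up-regulation.
condition_design <- function(meta) {
  meta <- as.data.frame(meta)
  meta$batch <- factor(meta$batch)
  meta$pair <- factor(meta$pair)
  meta$condition <- factor(meta$condition, levels = c("clonal", "chimeric"))
  # single-level batch or pair (e.g. one-batch fixtures) carries no
  # information; drop the term rather than fail in model.matrix
  terms <- c(if (nlevels(meta$batch) > 1) "batch",
             if (nlevels(meta$pair) > 1) "pair",
             "condition")
  mm <- model.matrix(stats::as.formula(paste("~", paste(terms, collapse = " + "))),
                     data = meta)
  attr(mm, "condition_col") <- "conditionchimeric"
  mm
}
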