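#' Read and write pipeline tables and masks
#'
#' Plain-text interchange for every object the pipeline consumes or
#' produces: counts as TSV (genes as rows, header of sample ids) or
#' MatrixMarket, sample metadata as CSV, ontologies as a pair of TSVs
#' (term/parent table and GAF-like assignment table), pathway sets as
#' GMT, DE results as TSV, and label masks as 16-bit grayscale TIFF.
#'
#' @param counts,path,meta,onto,de,mask,masks,pathways see individual
#'   functions.
#' @name dictydev-io
NULL

#' @rdname dictydev-io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dictydev-io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname dictydev-io
#' @export
write_counts_mtx <- function(counts, path) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stopf("MatrixMarket output needs the Matrix package")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".genes"))
  writeLines(colnames(counts), paste0(path, ".samples"))
  invisible(path)
}

#' @rdname dictydev-io
#' @export
write_metadata_csv <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dictydev-io
#' @export
read_metadata_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname dictydev-io
#' @export
write_ontology_tsv <- function(onto, path_terms, path_annotations) {
  parents <- vapply(onto$terms$id, function(id)
    paste(onto$edges$parent[onto$edges$term == id], collapse = "|"),
    character(1))
  terms <- cbind(onto$terms, parents = unname(parents))
  utils::write.table(terms, path_terms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(onto$annotations, path_annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path_terms)
}

#' @rdname dictydev-io
#' @export
read_ontology_tsv <- function(path_terms, path_annotations) {
  terms <- read.delim(path_terms, stringsAsFactors = FALSE)
  ann <- read.delim(path_annotations, stringsAsFactors = FALSE)
  ann$qualifier[is.na(ann$qualifier)] <- ""
  has_par <- !is.na(terms$parents) & terms$parents != ""
  edges <- data.frame(
    term = rep(terms$id[has_par],
               lengths(strsplit(terms$parents[has_par], "|", fixed = TRUE))),
    parent = unlist(strsplit(terms$parents[has_par], "|", fixed = TRUE)))
  ontology_annotation(terms[, c("id", "name", "namespace")], edges, ann)
}

#' @rdname dictydev-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1))
}

#' @rdname dictydev-io
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dictydev-io
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535) stopf("more than 65535 labels")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname dictydev-io
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  m <- round(img * 65535)
  storage.mode(m) <- "integer"
  m
}
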