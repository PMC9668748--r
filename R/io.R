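#' Write an expression or count matrix as TSV
#'
#' Genes in rows; first column `gene_id`, remaining columns the sample ids.
#'
#' @param mat genes x samples matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with a `gene_id` first column.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write / read counts in MatrixMarket format
#'
#' Sparse interchange alternative to TSV: `<stem>.mtx` plus `<stem>.rows` and
#' `<stem>.cols` holding gene and sample ids (one per line) and
#' `<stem>.lengths` holding per-gene effective lengths.
#'
#' @param cm a [count_matrix()].
#' @param stem path stem (no extension).
#' @export
write_counts_mm <- function(cm, stem) {
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  paste0(stem, ".mtx"))
  writeLines(rownames(cm$counts), paste0(stem, ".rows"))
  writeLines(colnames(cm$counts), paste0(stem, ".cols"))
  utils::write.table(
    data.frame(gene_id = names(cm$effective_length),
               effective_length = unname(cm$effective_length)),
    paste0(stem, ".lengths"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_counts_mm
#' @export
read_counts_mm <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".rows"))
  colnames(m) <- readLines(paste0(stem, ".cols"))
  len <- utils::read.delim(paste0(stem, ".lengths"), stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(len$effective_length, len$gene_id))
}

#' Write / read a sample metadata table
#'
#' @param meta data.frame with at least sample_id, subject_id, region,
#'   diagnosis columns.
#' @param path TSV file.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# check that metadata rows align 1:1 with matrix columns
check_alignment <- function(expr, meta) {
  if (!identical(colnames(expr), meta$sample_id))
    stop("metadata rows must align 1:1 with expression columns")
  if (anyDuplicated(paste(meta$subject_id, meta$region)))
    stop("at most one sample per (subject, region) is allowed")
  invisible(TRUE)
}
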