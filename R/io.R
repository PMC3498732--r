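#' Read / write tab-delimited expression matrices and metadata
#'
#' Expression tables have the gene id in the first column and one column
#' per sample; metadata tables carry the sample annotation columns.
#'
#' @param path file path.
#' @name nearzero-io
NULL

#' @rdname nearzero-io
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d[[1]]
  storage.mode(mat) <- "double"
  check_expression_matrix(mat)
  mat
}

#' @rdname nearzero-io
#' @param mat genes x samples matrix.
#' @param id_column name of the gene-id column (default `"gene_id"`).
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_column
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname nearzero-io
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_sample_metadata(meta)
  meta
}

#' @rdname nearzero-io
#' @param x a data.frame to write as TSV.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname nearzero-io
#' @export
read_orf_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}
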