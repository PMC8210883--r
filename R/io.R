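#' Read a gene x cell expression matrix from TSV
#'
#' Dialect: tab-separated, UTF-8, no quoting; header row holds cell ids,
#' first column holds gene ids.
#' @param path file path.
#' @return numeric matrix with gene rownames and cell colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write a gene x cell expression matrix to TSV
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @param id_col name of the first (gene id) column.
#' @export
write_expression_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list: one id per line, '#' comments and blanks ignored
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
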