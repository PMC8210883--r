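#' Remove cells with poorly detected housekeeping genes
#'
#' A cell is removed when its mean E-value over the housekeeping genes found
#' in the matrix is strictly below `threshold` (default 1). Housekeeping ids
#' absent from the matrix are ignored, not treated as zero: housekeeping
#' catalogs routinely list genes the quantification did not include.
#'
#' @param evalues an `evalues` object with `E` computed.
#' @param housekeeping character vector of housekeeping gene ids.
#' @param threshold removal threshold on the mean E-value (strict `<`).
#' @return object of class `qc_report` with `removed_cell_ids`,
#'   `retained_cell_ids` and `cell_stats` (per-cell housekeeping mean E).
#' @export
filter_cells_by_housekeeping <- function(evalues, housekeeping,
                                         threshold = 1) {
  stopifnot(inherits(evalues, "evalues"), !is.null(evalues$E))
  hk <- intersect(as.character(housekeeping), rownames(evalues$E))
  if (!length(hk)) stop("no housekeeping gene overlaps the matrix")
  mean_e <- colMeans(evalues$E[hk, , drop = FALSE])
  removed <- names(mean_e)[mean_e < threshold]
  structure(list(
    removed_cell_ids = removed,
    retained_cell_ids = setdiff(colnames(evalues$E), removed),
    removed_gene_ids = character(0),
    retained_gene_ids = rownames(evalues$E),
    cell_stats = data.frame(cell_id = names(mean_e),
                            housekeeping_mean_e = unname(mean_e),
                            row.names = NULL),
    n_housekeeping_used = length(hk),
    threshold = threshold
  ), class = "qc_report")
}

#' Keep genes detected in enough cells of some condition
#'
#' A gene is detected in a cell when its TPM is > 0. The gene is retained
#' when, in at least one condition, the detected fraction strictly exceeds
#' `fraction` (default 0.3). Spike-in rows are always retained. Run this on
#' QC-retained cells only (cell filter first), so detection fractions are
#' not diluted by discarded low-quality cells.
#'
#' @param tpm gene x cell TPM matrix restricted to QC-retained cells.
#' @param annotation data.frame with `cell_id`, `condition` covering the
#'   matrix columns.
#' @param fraction detection-fraction threshold (strict `>`).
#' @param spikein_ids spike-in gene ids exempt from the filter.
#' @return `qc_report` with gene partitions and `gene_stats` (per-gene
#'   per-condition detection fractions).
#' @export
filter_genes_by_detection <- function(tpm, annotation, fraction = 0.3,
                                      spikein_ids = character(0)) {
  tpm <- .check_tpm(tpm)
  annotation <- .check_annotation(annotation, colnames(tpm))
  cond <- annotation$condition
  tab <- table(cond)
  if (any(tab == 0L)) stop("condition with 0 cells: ",
                           paste(names(tab)[tab == 0L], collapse = ", "))
  detected <- tpm > 0
  frac <- vapply(names(tab), function(cc)
    rowMeans(detected[, cond == cc, drop = FALSE]), numeric(nrow(tpm)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(tpm),
                                         dimnames = list(rownames(tpm),
                                                         names(tab)))
  keep <- apply(frac, 1L, max) > fraction
  keep[rownames(tpm) %in% spikein_ids] <- TRUE
  structure(list(
    removed_cell_ids = character(0),
    retained_cell_ids = colnames(tpm),
    removed_gene_ids = rownames(tpm)[!keep],
    retained_gene_ids = rownames(tpm)[keep],
    gene_stats = as.data.frame(frac),
    fraction = fraction
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", length(x$retained_cell_ids), "cells retained (",
      length(x$removed_cell_ids), "removed );",
      length(x$retained_gene_ids), "genes retained (",
      length(x$removed_gene_ids), "removed )\n")
  invisible(x)
}
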