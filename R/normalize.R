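#' Describe the spike-in records of an expression matrix
#'
#' @param spikein_ids gene identifiers of the spike-in rows.
#' @param designed_concentrations optional relative concentrations (fold
#'   units, one per spike-in); must be positive when given.
#' @param anchor_id identifier of the anchor spike-in. If `NULL`, the anchor
#'   is chosen when normalizing as the spike-in with the largest mean TPM
#'   across the cells of the matrix being normalized (the "highest expressed"
#'   spike-in).
#' @return object of class `spikein_set`.
#' @export
spikein_set <- function(spikein_ids, designed_concentrations = NULL,
                        anchor_id = NULL) {
  spikein_ids <- as.character(spikein_ids)
  if (!length(spikein_ids)) stop("need at least one spike-in id")
  if (anyDuplicated(spikein_ids)) stop("spike-in ids must be unique")
  if (!is.null(designed_concentrations)) {
    if (length(designed_concentrations) != length(spikein_ids))
      stop("designed_concentrations must match spikein_ids in length")
    if (any(designed_concentrations <= 0))
      stop("designed_concentrations must be > 0")
  }
  if (!is.null(anchor_id) && !anchor_id %in% spikein_ids)
    stop("anchor_id must be one of spikein_ids")
  structure(list(spikein_ids = spikein_ids,
                 designed_concentrations = designed_concentrations,
                 anchor_id = anchor_id),
            class = "spikein_set")
}

# internal: resolve the anchor spike-in for a TPM matrix
.resolve_anchor <- function(tpm, spikeins) {
  ids <- intersect(spikeins$spikein_ids, rownames(tpm))
  if (!length(ids)) stop("no spike-in row present in the matrix")
  if (!is.null(spikeins$anchor_id)) {
    if (!spikeins$anchor_id %in% rownames(tpm))
      stop("anchor spike-in '", spikeins$anchor_id, "' absent from matrix")
    return(spikeins$anchor_id)
  }
  means <- rowMeans(tpm[ids, , drop = FALSE])
  ids[which.max(means)] # which.max ties to the first id
}

.check_tpm <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("TPM matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(tpm))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(tpm))) stop("cell ids must be unique")
  if (any(tpm < 0)) stop("TPM values must be >= 0")
  tpm
}

#' Normalize TPM values to the anchor spike-in
#'
#' For gene j in cell k the normalized value is
#' `N_jk = TPM_jk / (TPM_sk / mean_i(TPM_si))`
#' where s is the anchor spike-in and the mean runs over the M cells of the
#' matrix. A cell whose endogenous content doubles (spike-in TPM halving)
#' therefore has its N values doubled: N is proportional to absolute
#' per-cell abundance on the scale set by the constant spike-in amount.
#' Spike-in rows are retained in the output; the anchor's own N row equals
#' `mean_i(TPM_si)` in every cell.
#'
#' @param tpm gene x cell TPM matrix (endogenous genes + spike-ins).
#' @param spikeins a [spikein_set()].
#' @return object of class `evalues` with element `N` (same shape as `tpm`),
#'   `anchor_id`, and `E = NULL` until [compute_evalues()] is applied.
#' @export
normalize_to_spikein <- function(tpm, spikeins) {
  tpm <- .check_tpm(tpm)
  anchor <- .resolve_anchor(tpm, spikeins)
  anchor_tpm <- tpm[anchor, ]
  bad <- colnames(tpm)[anchor_tpm <= 0]
  if (length(bad))
    stop("anchor spike-in TPM is 0 in cells (remove them in QC first): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ...")
  size_factor <- anchor_tpm / mean(anchor_tpm)
  n <- sweep(tpm, 2L, size_factor, "/")
  structure(list(N = n, E = NULL, capture_scale = NULL, anchor_id = anchor,
                 spikein_ids = intersect(spikeins$spikein_ids, rownames(tpm))),
            class = "evalues")
}

#' Convert normalized expression to E-values
#'
#' `E_jk = log2(N_jk / capture_scale + 1)`. The divisor (default 10) reflects
#' that single-cell capture complexity is roughly 10% of bulk RNA-seq, so E
#' approximates a log2 bulk-equivalent expression level.
#'
#' @param evalues an `evalues` object from [normalize_to_spikein()].
#' @param capture_scale positive divisor, default 10.
#' @return the same object with `E` filled in.
#' @export
compute_evalues <- function(evalues, capture_scale = 10) {
  stopifnot(inherits(evalues, "evalues"))
  if (!is.numeric(capture_scale) || length(capture_scale) != 1L ||
      capture_scale <= 0)
    stop("capture_scale must be a single positive number")
  evalues$E <- log2(evalues$N / capture_scale + 1)
  evalues$capture_scale <- capture_scale
  evalues
}

#' @export
print.evalues <- function(x, ...) {
  cat("Spike-in-normalized expression:", nrow(x$N), "genes x", ncol(x$N),
      "cells; anchor =", x$anchor_id, "\n")
  if (is.null(x$E)) cat("E-values not yet computed\n")
  else cat("E-values computed with capture_scale =", x$capture_scale, "\n")
  invisible(x)
}

#' Per-cell relative transcriptome abundance
#'
#' Estimates each cell's global mRNA content relative to untreated cells.
#' With `method = "read_ratio"` the statistic is the ratio of reads mapped to
#' endogenous mRNAs over reads mapped to spike-ins; with `method = "top_tpm"`
#' it is the summed TPM of the `top_n` highest-expressed endogenous genes
#' over the anchor spike-in TPM. Either way the log2 ratio is centered so
#' that the median over control cells is exactly 0.
#'
#' @param annotation data.frame with `cell_id` and `condition` columns.
#' @param method `"read_ratio"` or `"top_tpm"`.
#' @param reads for `"read_ratio"`: data.frame with columns `cell_id`,
#'   `endogenous_reads`, `spikein_reads`.
#' @param tpm,spikeins for `"top_tpm"`: TPM matrix and [spikein_set()].
#' @param top_n number of top endogenous genes summed (default 5000; capped
#'   at the number of endogenous genes). Per-cell ranking ties break by gene
#'   id order for determinism.
#' @param control label of the control condition (default `"control"`).
#' @return numeric vector of per-cell log2 relative abundance, named by cell,
#'   with attribute `method`.
#' @export
relative_transcriptome_abundance <- function(annotation,
                                             method = c("read_ratio",
                                                        "top_tpm"),
                                             reads = NULL, tpm = NULL,
                                             spikeins = NULL, top_n = 5000L,
                                             control = "control") {
  method <- match.arg(method)
  annotation <- .check_annotation(annotation)
  if (method == "read_ratio") {
    stopifnot(is.data.frame(reads),
              all(c("cell_id", "endogenous_reads", "spikein_reads") %in%
                    names(reads)))
    reads <- reads[match(annotation$cell_id, reads$cell_id), , drop = FALSE]
    if (anyNA(reads$cell_id))
      stop("read counts missing for some annotated cells")
    if (any(reads$spikein_reads <= 0))
      stop("spike-in read count is 0 for cells: ",
           paste(head(reads$cell_id[reads$spikein_reads <= 0], 5L),
                 collapse = ", "))
    ratio <- reads$endogenous_reads / reads$spikein_reads
    cells <- reads$cell_id
  } else {
    tpm <- .check_tpm(tpm)
    anchor <- .resolve_anchor(tpm, spikeins)
    annotation <- .check_annotation(annotation, colnames(tpm))
    endo <- setdiff(rownames(tpm), spikeins$spikein_ids)
    if (!length(endo)) stop("no endogenous genes in matrix")
    anchor_tpm <- tpm[anchor, ]
    if (any(anchor_tpm <= 0))
      stop("anchor spike-in TPM is 0 for cells: ",
           paste(head(colnames(tpm)[anchor_tpm <= 0], 5L), collapse = ", "))
    k <- min(as.integer(top_n), length(endo))
    endo_mat <- tpm[endo[order(endo)], , drop = FALSE] # id order breaks ties
    top_sum <- apply(endo_mat, 2L, function(v)
      sum(v[order(-v)[seq_len(k)]]))
    ratio <- top_sum / anchor_tpm
    cells <- colnames(tpm)
  }
  is_control <- annotation$condition[match(cells, annotation$cell_id)] ==
    control
  if (!any(is_control)) stop("no control cells present")
  if (any(ratio <= 0)) stop("non-positive abundance ratio encountered")
  lr <- log2(ratio)
  out <- lr - median(lr[is_control])
  names(out) <- cells
  attr(out, "method") <- method
  out
}
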