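#' Filter seed genes to those expressed and variable across a panel
#'
#' A seed gene survives when (i) its expressed-call mask is TRUE in strictly
#' more than `expr_fraction` of the panel samples and (ii) the spread of its
#' log2 expression, measured as the difference between the 90th and 10th
#' percentiles, strictly exceeds `log2(range_fold)`. The second criterion
#' removes constitutively or lineage-specifically expressed genes that
#' cannot carry co-expression signal.
#'
#' @param panel list with `values` (genes x samples log2 expression) and
#'   `mask` (same shape, logical expressed calls) — see
#'   [simulate_cell_line_panel()] for the layout.
#' @param seed_genes character vector of candidate gene ids.
#' @param expr_fraction expressed-fraction threshold (default 0.5, strict).
#' @param range_fold linear fold spread required between the 90th and 10th
#'   percentile (default 3, strict on the log2 scale).
#' @return character vector of surviving gene ids.
#' @export
filter_expressed_variable_genes <- function(panel, seed_genes,
                                            expr_fraction = 0.5,
                                            range_fold = 3) {
  .check_panel(panel)
  genes <- intersect(as.character(seed_genes), rownames(panel$values))
  if (!length(genes)) stop("no seed gene present in the panel")
  v <- panel$values[genes, , drop = FALSE]
  m <- panel$mask[genes, , drop = FALSE]
  expr_ok <- rowMeans(m) > expr_fraction
  qr <- apply(v, 1L, function(x)
    diff(quantile(x, c(0.1, 0.9), names = FALSE, type = 7)))
  range_ok <- qr > log2(range_fold)
  genes[expr_ok & range_ok]
}

.check_panel <- function(panel) {
  stopifnot(is.list(panel), !is.null(panel$values), !is.null(panel$mask))
  if (!identical(dim(panel$values), dim(panel$mask)))
    stop("panel mask must have the same shape as the values")
  if (is.null(rownames(panel$values)) || is.null(colnames(panel$values)))
    stop("panel values need gene rownames and sample colnames")
  invisible(panel)
}

#' Iteratively refine a seed geneset into a coherent co-expression module
#'
#' Starting from the filtered seed genes, each iteration (a) median-centers
#' every gene across samples, `M_jk = x_jk - median_k(x_jk)`, (b) summarizes
#' each sample by the module score `S_k = median_j(M_jk)` over the current
#' genes, (c) computes the Spearman correlation of every current gene with
#' S across samples, and (d) removes genes with correlation < `rho_min`.
#' Iteration stops at a fixed point (no gene removed); since the set
#' strictly shrinks otherwise, at most `length(genes)` iterations can occur
#' (`max_iter` is a safety cap only).
#'
#' At the fixed point every retained gene correlates with the module score
#' at >= `rho_min`, i.e. the genes are mutually positively co-expressed
#' through their shared score.
#'
#' By default each gene's correlation is taken against the leave-one-out
#' score (the median over the *other* current genes). With few genes, a
#' gene's own contribution to the median correlates it with the score even
#' when it is independent of every other gene, and the pruning then retains
#' arbitrary genes; the leave-one-out score removes that bias. At the scale
#' of a large panel (hundreds of genes, a thousand samples) the two
#' variants coincide within sampling noise; `exclude_self = FALSE` gives
#' the literal all-gene score.
#'
#' @param panel panel list (`values`, `mask`).
#' @param genes character vector of (already filtered) gene ids.
#' @param rho_min Spearman threshold below which a gene is dropped
#'   (default 0.1).
#' @param max_iter safety cap on iterations (default 100).
#' @param exclude_self correlate each gene with the leave-one-out score
#'   (default TRUE, see Details).
#' @return object of class `module_result`: `seed_genes`, `retained`,
#'   `trace` (data.frame iteration, n_genes, n_removed), `index`
#'   (per-sample S at the fixed point), `rho` (final per-gene Spearman, as
#'   used for the retention decision).
#' @export
iterative_module_refinement <- function(panel, genes, rho_min = 0.1,
                                        max_iter = 100L,
                                        exclude_self = TRUE) {
  .check_panel(panel)
  genes <- intersect(as.character(genes), rownames(panel$values))
  if (length(genes) < 2L) stop("need at least 2 genes after filtering")
  seed_genes <- genes
  centered <- panel$values[genes, , drop = FALSE] -
    apply(panel$values[genes, , drop = FALSE], 1L, median)
  trace <- data.frame(iteration = integer(0), n_genes = integer(0),
                      n_removed = integer(0))
  rho <- NULL
  for (it in seq_len(max_iter)) {
    cur <- centered[genes, , drop = FALSE]
    if (exclude_self) {
      rho <- vapply(seq_along(genes), function(j) {
        s_loo <- apply(cur[-j, , drop = FALSE], 2L, median)
        cor(cur[j, ], s_loo, method = "spearman")
      }, numeric(1))
      names(rho) <- genes
    } else {
      s <- apply(cur, 2L, median)
      rho <- apply(cur, 1L, function(x) cor(x, s, method = "spearman"))
    }
    drop <- names(rho)[is.na(rho) | rho < rho_min]
    trace <- rbind(trace, data.frame(iteration = it,
                                     n_genes = length(genes),
                                     n_removed = length(drop)))
    if (!length(drop)) break
    genes <- setdiff(genes, drop)
    if (length(genes) < 2L)
      stop("module collapsed below 2 genes at iteration ", it,
           " (started with ", length(seed_genes), ")")
  }
  structure(list(seed_genes = seed_genes, retained = genes, trace = trace,
                 index = apply(centered[genes, , drop = FALSE], 2L, median),
                 rho = rho[genes], rho_min = rho_min),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat("Coherent module:", length(x$retained), "of", length(x$seed_genes),
      "seed genes retained in", nrow(x$trace), "iteration(s)\n")
  invisible(x)
}

#' Drug-response index of each sample from a gene module
#'
#' `index_k = median_j(x_jk - median_k(x_jk))` over the module genes: the
#' median, across the module, of per-gene median-centered log2 expression.
#' Higher values mean higher relative module expression, associated with
#' worse drug response.
#'
#' @param panel panel list (`values`, `mask`).
#' @param module_genes character vector of module gene ids.
#' @return named numeric vector, one index per sample.
#' @export
compute_response_index <- function(panel, module_genes) {
  .check_panel(panel)
  module_genes <- as.character(module_genes)
  if (!length(module_genes)) stop("empty module")
  missing <- setdiff(module_genes, rownames(panel$values))
  if (length(missing))
    stop("module genes absent from panel: ",
         paste(head(missing, 10L), collapse = ", "))
  v <- panel$values[module_genes, , drop = FALSE]
  centered <- v - apply(v, 1L, median)
  apply(centered, 2L, median)
}

#' Evaluate a response index against an outcome
#'
#' For a continuous IC50 outcome, samples are grouped into `n_groups` index
#' quantile groups (default tertiles) and the IC50 values of the top versus
#' bottom group are compared by a two-sided Wilcoxon rank-sum test; the ROC
#' AUC uses the index as a score for the above-median-IC50 (resistant)
#' class. For a binary outcome (logical or two-level factor; TRUE / the
#' second level = responder), the index is compared between responders and
#' non-responders, and the AUC scores the non-responder class — higher index
#' predicting worse response in both cases.
#'
#' @param index named numeric vector of per-sample index values.
#' @param outcome numeric IC50 vector or logical/two-level responder labels,
#'   aligned with `index` (matched by names when both are named).
#' @param n_groups quantile groups for the continuous comparison (default 3).
#' @return list: `p_value`, `auc`, `type` ("ic50" or "responder"), `groups`
#'   (for the continuous case, the index group of each sample).
#' @export
evaluate_index_outcome <- function(index, outcome, n_groups = 3L) {
  stopifnot(is.numeric(index))
  if (!is.null(names(index)) && !is.null(names(outcome)))
    outcome <- outcome[names(index)]
  if (length(outcome) != length(index))
    stop("index and outcome lengths differ")
  if (length(index) < 10L) stop("need at least 10 samples")

  if (is.numeric(outcome)) {
    grp <- .equal_freq_bins(index, n_groups)
    top <- outcome[grp == max(grp)]
    bottom <- outcome[grp == 1L]
    if (!length(top) || !length(bottom)) stop("empty index group")
    w <- wilcoxon_ranksum(top, bottom)
    resistant <- outcome > median(outcome)
    if (!any(resistant) || all(resistant))
      stop("IC50 dichotomization produced one empty class")
    list(p_value = w$p_value, auc = roc_auc(index, resistant),
         type = "ic50", groups = grp)
  } else {
    responder <- if (is.logical(outcome)) outcome
                 else as.integer(as.factor(outcome)) == 2L
    if (!any(responder) || all(responder))
      stop("one outcome class is empty")
    w <- wilcoxon_ranksum(index[responder], index[!responder])
    list(p_value = w$p_value, auc = roc_auc(index, !responder),
         type = "responder", groups = NULL)
  }
}

#' Restrict a module to genes expressed in a biological context
#'
#' Keeps the module genes whose expressed-call fraction within the context
#' samples strictly exceeds `expr_fraction`. Used to port a cell-line-panel
#' module to, e.g., a tissue-specific patient cohort where only genes
#' expressed in that lineage are informative.
#'
#' @param module_genes character vector of module gene ids.
#' @param mask logical genes x samples expressed-call matrix covering the
#'   module genes.
#' @param context character vector of column names (or logical/integer
#'   column index) defining the context samples; default all samples.
#' @param expr_fraction threshold (default 0.5, strict `>`).
#' @return character vector of retained gene ids (error when empty).
#' @export
restrict_geneset_to_context <- function(module_genes, mask, context = NULL,
                                        expr_fraction = 0.5) {
  module_genes <- as.character(module_genes)
  missing <- setdiff(module_genes, rownames(mask))
  if (length(missing))
    stop("mask lacks module genes: ", paste(head(missing, 10L),
                                            collapse = ", "))
  sub <- mask[module_genes, , drop = FALSE]
  if (!is.null(context)) sub <- sub[, context, drop = FALSE]
  if (!ncol(sub)) stop("empty context")
  keep <- rowMeans(sub) > expr_fraction
  if (!any(keep)) stop("no module gene expressed in the context")
  module_genes[keep]
}
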