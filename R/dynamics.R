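#' Per-gene log2 fold change of each condition versus control
#'
#' Condition-level expression is the mean E-value across the condition's
#' cells; since E is log2-scaled, the difference of means is a log2 fold
#' change.
#'
#' @param evalues an `evalues` object with `E` computed.
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param control control condition label.
#' @return genes x conditions matrix of log2 fold changes (control column
#'   excluded).
#' @export
condition_fold_changes <- function(evalues, annotation, control = "control") {
  stopifnot(inherits(evalues, "evalues"), !is.null(evalues$E))
  annotation <- .check_annotation(annotation, colnames(evalues$E))
  cond <- annotation$condition
  if (!any(cond == control)) stop("no control cells present")
  conds <- setdiff(unique(cond), control)
  if (!length(conds)) stop("no non-control condition present")
  ctrl <- rowMeans(evalues$E[, cond == control, drop = FALSE])
  fc <- vapply(conds, function(cc)
    rowMeans(evalues$E[, cond == cc, drop = FALSE]) - ctrl,
    numeric(nrow(evalues$E)))
  if (is.null(dim(fc)))
    fc <- matrix(fc, nrow = nrow(evalues$E),
                 dimnames = list(rownames(evalues$E), conds))
  fc
}

#' Assign drug-responsive genes to the three regulatory clusters
#'
#' With t = log2(`fold`):
#' cluster I — down at celecoxib-16h (FC <= -t) and up after combination
#' (FC >= t); cluster II — down at celecoxib-16h and no dynamic change after
#' combination (|FC| < t); cluster III — up after combination and no dynamic
#' change at celecoxib-16h. Everything else is `none`. "No dynamic change"
#' is formalized as |FC| < t.
#'
#' @param fc genes x conditions fold-change matrix from
#'   [condition_fold_changes()].
#' @param fold fold threshold (default 1.5).
#' @param cele_col,combo_col column names of the celecoxib-16h and
#'   combination-16h conditions.
#' @return data.frame gene_id, cluster (factor I/II/III/none), the two FCs.
#' @export
assign_regulatory_clusters <- function(fc, fold = 1.5, cele_col = "CELE16",
                                       combo_col = "COMBO16") {
  fc <- as.matrix(fc)
  missing <- setdiff(c(cele_col, combo_col), colnames(fc))
  if (length(missing))
    stop("fold-change matrix lacks condition(s): ",
         paste(missing, collapse = ", "))
  t <- log2(fold)
  cele <- fc[, cele_col]
  combo <- fc[, combo_col]
  cluster <- rep("none", nrow(fc))
  cluster[cele <= -t & combo >= t] <- "I"
  cluster[cele <= -t & abs(combo) < t] <- "II"
  cluster[abs(cele) < t & combo >= t] <- "III"
  data.frame(gene_id = rownames(fc),
             cluster = factor(cluster, levels = c("I", "II", "III", "none")),
             fc_cele16 = unname(cele), fc_combo16 = unname(combo),
             row.names = NULL)
}

#' Control-relative geneset expression score per cell
#'
#' For each geneset gene j, `M_jk = E_jk / mean_control(E_j)`; the per-cell
#' geneset score is the mean of M over the geneset. By construction the
#' score averages exactly 1 over control cells. Genes whose control mean is
#' 0 are dropped with a warning (their ratio is undefined).
#'
#' @param evalues an `evalues` object with `E` computed.
#' @param geneset character vector of gene ids (or a named list entry).
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param control control condition label.
#' @return list: `score` (named per-cell vector), `M` (genes x cells),
#'   `genes_used`.
#' @export
geneset_relative_expression <- function(evalues, geneset, annotation,
                                        control = "control") {
  stopifnot(inherits(evalues, "evalues"), !is.null(evalues$E))
  annotation <- .check_annotation(annotation, colnames(evalues$E))
  cond <- annotation$condition
  if (!any(cond == control)) stop("no control cells present")
  genes <- intersect(as.character(geneset), rownames(evalues$E))
  if (!length(genes)) stop("no geneset gene present in the matrix")
  e <- evalues$E[genes, , drop = FALSE]
  ctrl_mean <- rowMeans(e[, cond == control, drop = FALSE])
  zero <- ctrl_mean == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " geneset gene(s) with control mean 0")
    e <- e[!zero, , drop = FALSE]
    ctrl_mean <- ctrl_mean[!zero]
  }
  if (!nrow(e)) stop("empty effective geneset after dropping zero-mean genes")
  m <- e / ctrl_mean
  list(score = colMeans(m), M = m, genes_used = rownames(e))
}

#' Wilcoxon rank-sum comparisons of per-cell values between groups
#'
#' @param values named numeric vector (per-cell score or abundance).
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param comparisons list of length-2 character vectors
#'   `c(group, reference)`; default: every non-control condition vs control.
#' @param control control label used for the default comparisons.
#' @return data.frame group, reference, n values per side, two-sided p.
#' @export
compare_groups_wilcoxon <- function(values, annotation, comparisons = NULL,
                                    control = "control") {
  if (is.null(names(values))) stop("values must be named by cell id")
  annotation <- .check_annotation(annotation, names(values))
  cond <- setNames(annotation$condition, annotation$cell_id)
  if (is.null(comparisons)) {
    others <- setdiff(unique(cond), control)
    comparisons <- lapply(others, function(g) c(g, control))
  }
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    x <- values[names(cond)[cond == cmp[[1L]]]]
    y <- values[names(cond)[cond == cmp[[2L]]]]
    if (length(x) < 2L || length(y) < 2L)
      stop("group with fewer than 2 values in comparison ",
           paste(cmp, collapse = " vs "))
    w <- wilcoxon_ranksum(x, y)
    data.frame(group = cmp[[1L]], reference = cmp[[2L]],
               n_group = length(x), n_reference = length(y),
               statistic = w$statistic, p_value = w$p_value,
               method = w$method)
  })
  do.call(rbind, rows)
}
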