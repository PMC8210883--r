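#' Detect genes with high intercellular expression variance
#'
#' Within one treatment condition, each analyzed gene's coefficient of
#' variation (CV = sd/mean of E-values across the condition's cells) is
#' compared against genes expressed at a similar level: genes are placed in
#' `n_bins` equal-frequency bins by mean E-value and a gene is flagged when
#' its log10(CV) exceeds its bin's mean log10(CV) by more than
#' `fold` x the bin's standard deviation of log10(CV) (an upper-tail
#' z-score rule). Only genes with mean E-value > `min_mean` are analyzed.
#'
#' The flagging criterion admits a second reading in which the gene's
#' log10(CV) itself (not its deviation from the bin mean) is compared to
#' `fold` x the bin sd; set `rule = "absolute"` for that sensitivity
#' analysis. The default `"deviation"` rule is the one that targets genes
#' more variable than their expression-matched peers.
#'
#' Bins that end up with fewer than 3 genes are merged into their left
#' neighbor (the first bin merges rightwards) with a warning, since a
#' standard deviation over 1-2 genes is meaningless.
#'
#' @param evalues an `evalues` object with `E` computed.
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param condition single condition label to analyze.
#' @param n_bins number of mean-expression bins (default 100).
#' @param fold multiple of the bin sd a gene must exceed (default 2).
#' @param min_mean mean E-value gate for inclusion (default 1, strict `>`).
#' @param rule `"deviation"` (default) or `"absolute"`, see Details.
#' @return object of class `highvar_report`: `flagged` (gene ids),
#'   `gene_stats` (mean E, CV, log10 CV, bin), `bin_stats` (per-bin center,
#'   mean and sd of log10 CV), `condition`.
#' @export
high_variance_genes <- function(evalues, annotation, condition,
                                n_bins = 100L, fold = 2, min_mean = 1,
                                rule = c("deviation", "absolute")) {
  stopifnot(inherits(evalues, "evalues"), !is.null(evalues$E))
  rule <- match.arg(rule)
  annotation <- .check_annotation(annotation, colnames(evalues$E))
  cells <- annotation$cell_id[annotation$condition == condition]
  if (length(cells) < 2L)
    stop("condition '", condition, "' has fewer than 2 cells")
  e <- evalues$E[, cells, drop = FALSE]
  mean_e <- rowMeans(e)
  keep <- mean_e > min_mean
  if (!any(keep)) stop("no gene passes the min_mean gate")
  e <- e[keep, , drop = FALSE]
  mean_e <- mean_e[keep]
  cv <- apply(e, 1L, sd) / mean_e
  ok <- cv > 0 # constant genes carry no variance signal
  e <- e[ok, , drop = FALSE]
  mean_e <- mean_e[ok]
  cv <- cv[ok]
  lcv <- log10(cv)

  bin <- .equal_freq_bins(mean_e, n_bins)
  # merge undersized bins leftwards (bin 1 merges rightwards)
  n_merged <- 0L
  repeat {
    tab <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(tab)[tab < 3L]
    if (!length(small)) break
    b <- as.integer(small[[1L]])
    ids <- sort(unique(bin))
    pos <- match(b, ids)
    target <- if (pos > 1L) ids[pos - 1L] else ids[pos + 1L]
    if (is.na(target)) break # single bin left; nothing to merge into
    bin[bin == b] <- target
    n_merged <- n_merged + 1L
  }
  if (n_merged > 0L)
    warning("merged ", n_merged,
            " undersized expression bin(s) into their neighbors")

  bin_mean <- tapply(lcv, bin, mean)
  bin_sd <- tapply(lcv, bin, sd)
  bm <- bin_mean[as.character(bin)]
  bs <- bin_sd[as.character(bin)]
  flagged_mask <- if (rule == "deviation") (lcv - bm) > fold * bs
                  else lcv > fold * bs

  structure(list(
    flagged = names(mean_e)[flagged_mask],
    gene_stats = data.frame(gene_id = names(mean_e), mean_e = unname(mean_e),
                            cv = unname(cv), log10_cv = unname(lcv),
                            bin = bin, row.names = NULL),
    bin_stats = data.frame(bin = as.integer(names(bin_mean)),
                           center_mean_e = as.numeric(
                             tapply(mean_e, bin, median)),
                           mean_log10_cv = as.numeric(bin_mean),
                           sd_log10_cv = as.numeric(bin_sd), row.names = NULL),
    condition = condition, n_bins = n_bins, fold = fold,
    min_mean = min_mean, rule = rule
  ), class = "highvar_report")
}

#' @export
print.highvar_report <- function(x, ...) {
  cat("High-variance genes in '", x$condition, "': ", length(x$flagged),
      " of ", nrow(x$gene_stats), " analyzed (rule = ", x$rule, ")\n",
      sep = "")
  invisible(x)
}
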