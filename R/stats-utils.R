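#' Area under the ROC curve of a score for a binary outcome
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counted half.
#'
#' @param score numeric score, higher predicting the positive class.
#' @param positive logical (or coercible) indicator of the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, positive) {
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive), !anyNA(score), !anyNA(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be non-empty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both groups have at most `exact_max`
#' observations and the pooled values are tie-free; otherwise the normal
#' approximation with tie correction (no continuity correction, so two
#' identical groups give p = 1 exactly).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max largest group size for the exact branch (default 20).
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 20L) {
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(pwilcox(u, n1, n2), pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    list(statistic = u, p_value = min(1, p), method = "exact")
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                                 method = "normal_tie_corrected"))
    z <- (u - mu) / sqrt(sigma2)
    list(statistic = u, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal_tie_corrected")
  }
}

# internal: equal-frequency bin ids (1..n_bins) by a numeric key,
# ties broken by order for determinism
.equal_freq_bins <- function(key, n_bins) {
  n <- length(key)
  n_bins <- max(1L, min(as.integer(n_bins), n))
  r <- rank(key, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

# internal: validate a condition annotation data.frame
.check_annotation <- function(annotation, cells = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("cell_id", "condition") %in% names(annotation)))
  if (anyDuplicated(annotation$cell_id))
    stop("duplicated cell_id in annotation")
  annotation$cell_id <- as.character(annotation$cell_id)
  annotation$condition <- as.character(annotation$condition)
  if (!is.null(cells)) {
    missing <- setdiff(cells, annotation$cell_id)
    if (length(missing))
      stop("cells absent from annotation: ",
           paste(head(missing, 5L), collapse = ", "))
    annotation <- annotation[match(cells, annotation$cell_id), , drop = FALSE]
  }
  annotation
}
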