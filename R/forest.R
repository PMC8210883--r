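#' Fit a bagged classification forest
#'
#' A self-contained random forest (CART trees, Gini splits, bootstrap
#' aggregation) with out-of-bag (OOB) error estimates and permutation
#' importance (mean decrease in accuracy, MDA). It backs the cell-state
#' classifier; no external forest package is required.
#'
#' Determinism: all randomness uses R's RNG, so `set.seed()` before the call
#' (or the `seed` arguments of the higher-level wrappers) fixes the forest.
#' Tied best splits resolve to the first feature examined, and leaf
#' majorities tie to the lowest class index, so a fitted forest is a pure
#' function of data, parameters and RNG state.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y factor (or coercible) of class labels, length `nrow(x)`.
#' @param ntree number of trees.
#' @param mtry features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node minimum samples per child node; default 1 (grow to purity).
#' @param importance compute permutation importance (MDA) per feature.
#' @return object of class `spikestate_rf` with elements `forest` (opaque),
#'   `levels`, `features`, `oob_votes` (samples x classes), `oob_error`
#'   (overall and per class), and `importance` (MDA per feature, or NULL).
#' @export
rf_fit <- function(x, y, ntree = 200L, mtry = NULL, min_node = 1L,
                   importance = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (anyNA(x)) stop("x contains missing values")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))

  fit <- .rf_grow(x, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                  as.integer(mtry), as.integer(min_node), isTRUE(importance))

  oob_votes <- fit$oob_votes
  dimnames(oob_votes) <- list(rownames(x), levels(y))
  seen <- rowSums(oob_votes) > 0
  oob_pred <- levels(y)[max.col(oob_votes, ties.method = "first")]
  per_class <- vapply(levels(y), function(lv) {
    idx <- seen & y == lv
    if (!any(idx)) return(NA_real_)
    mean(oob_pred[idx] != lv)
  }, numeric(1))

  imp <- NULL
  if (isTRUE(importance)) {
    imp <- as.numeric(fit$importance)
    names(imp) <- colnames(x)
  }

  structure(list(
    forest = fit,
    levels = levels(y),
    features = colnames(x),
    oob_votes = oob_votes,
    oob_error = list(overall = mean(oob_pred[seen] != as.character(y)[seen]),
                     per_class = per_class),
    importance = imp,
    ntree = as.integer(ntree), mtry = as.integer(mtry)
  ), class = "spikestate_rf")
}

#' Predict class-vote fractions from a fitted forest
#'
#' @param object a `spikestate_rf` fit.
#' @param newdata numeric matrix with the same feature columns as training.
#' @param type `"prob"` for vote fractions (rows sum to 1 exactly since each
#'   tree casts one vote) or `"class"` for the argmax label (ties to the
#'   first class in `object$levels`).
#' @param ... unused.
#' @export
predict.spikestate_rf <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$features)) {
    if (is.null(colnames(newdata))) {
      if (ncol(newdata) != length(object$features))
        stop("newdata has ", ncol(newdata), " columns; model expects ",
             length(object$features))
    } else {
      missing <- setdiff(object$features, colnames(newdata))
      if (length(missing))
        stop("newdata lacks model features: ",
             paste(head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) ", ...")
      newdata <- newdata[, object$features, drop = FALSE]
    }
  }
  votes <- .rf_votes(object$forest, newdata)
  prob <- votes / object$forest$ntree
  dimnames(prob) <- list(rownames(newdata), object$levels)
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.spikestate_rf <- function(x, ...) {
  cat("Bagged classification forest:", x$ntree, "trees, mtry =", x$mtry, "\n")
  cat("Classes:", paste(x$levels, collapse = ", "), "\n")
  cat(sprintf("OOB error: %.3f\n", x$oob_error$overall))
  invisible(x)
}
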