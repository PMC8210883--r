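#' Select drug-responsive genes and control-normalize their expression
#'
#' A gene qualifies when the absolute difference between its mean E-value in
#' some non-control condition and its mean E-value in control cells is at
#' least `log2(fold)` (inclusive). Since E-values are log2-scaled, this is a
#' `fold`-change criterion on the E scale. The returned matrix holds, for the
#' selected genes, E-values minus the per-gene control mean — the
#' control-normalized features used by PCA and the forest.
#'
#' @param evalues an `evalues` object with `E` computed.
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param fold fold-change threshold (default 1.5).
#' @param control control condition label.
#' @return list with `genes` (selected ids) and `matrix` (selected genes x
#'   all cells, control-normalized E-values).
#' @export
select_differential_genes <- function(evalues, annotation, fold = 1.5,
                                      control = "control") {
  stopifnot(inherits(evalues, "evalues"), !is.null(evalues$E))
  annotation <- .check_annotation(annotation, colnames(evalues$E))
  cond <- annotation$condition
  if (!any(cond == control)) stop("no control cells present")
  e <- evalues$E
  ctrl_mean <- rowMeans(e[, cond == control, drop = FALSE])
  treat <- setdiff(unique(cond), control)
  if (!length(treat)) stop("no non-control condition present")
  hit <- rep(FALSE, nrow(e))
  for (cc in treat) {
    m <- rowMeans(e[, cond == cc, drop = FALSE])
    # inclusive threshold; epsilon guards the exact-boundary case against
    # floating-point noise in the means
    hit <- hit | abs(m - ctrl_mean) >= log2(fold) - 1e-9
  }
  list(genes = rownames(e)[hit],
       matrix = e[hit, , drop = FALSE] - ctrl_mean[hit])
}

#' Principal component analysis of cells with deterministic sign orientation
#'
#' Cells (columns of the control-normalized gene matrix) are projected onto
#' principal components of the gene-feature space. Because PC signs are
#' arbitrary, they are oriented against reference centroids so that
#' downstream PC-threshold gates are reproducible: the control-condition
#' centroid gets PC2 > 0 and the repression-reference-condition centroid
#' gets PC1 > 0 and PC3 > 0. Components whose reference centroid sits at
#' exactly 0, and components beyond PC3, keep prcomp's sign.
#'
#' @param mat genes x cells numeric matrix (control-normalized E-values).
#' @param annotation data.frame with `cell_id`, `condition` (for
#'   orientation); pass `NULL` to skip orientation.
#' @param control,repression_ref condition labels anchoring the signs.
#' @param n_components number of PCs to return (default 10, capped by rank).
#' @return object of class `pca_result`: `scores` (cells x PCs),
#'   `var_explained` (fractions, non-increasing), `signs`.
#' @export
run_pca <- function(mat, annotation = NULL, control = "control",
                    repression_ref = "CELE16", n_components = 10L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("need at least 3 cells for PCA")
  if (nrow(mat) < 3L) stop("need at least 3 genes for PCA")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(as.integer(n_components), ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  signs <- rep(1, k)
  if (!is.null(annotation)) {
    annotation <- .check_annotation(annotation, colnames(mat))
    orient <- function(pc_idx, cond_label) {
      cells <- annotation$condition == cond_label
      if (!any(cells) || pc_idx > k) return(1)
      ctr <- mean(scores[cells, pc_idx])
      if (ctr < 0) -1 else 1
    }
    signs[1L] <- orient(1L, repression_ref)
    if (k >= 2L) signs[2L] <- orient(2L, control)
    if (k >= 3L) signs[3L] <- orient(3L, repression_ref)
    scores <- sweep(scores, 2L, signs, "*")
  }

  structure(list(scores = scores, var_explained = ve[seq_len(k)],
                 signs = signs),
            class = "pca_result")
}

#' Per-condition out-of-bag error of a condition-label forest
#'
#' Fits one forest with each treatment condition as its own class and
#' reports the OOB misclassification rate per condition. Conditions whose
#' cells have unique, homogeneous signatures get low OOB error; conditions
#' mixing several transcriptional states get high error.
#'
#' @param mat genes x cells control-normalized matrix.
#' @param annotation data.frame with `cell_id`, `condition`.
#' @param ntree trees (default 600).
#' @param seed RNG seed.
#' @return list with `per_condition` error rates, `overall`, and `fit`.
#' @export
oob_condition_error <- function(mat, annotation, ntree = 600L,
                                seed = .default_seed) {
  mat <- as.matrix(mat)
  annotation <- .check_annotation(annotation, colnames(mat))
  tab <- table(annotation$condition)
  if (length(tab) < 2L) stop("need at least 2 conditions")
  if (any(tab < 5L))
    stop("condition(s) with fewer than 5 cells: ",
         paste(names(tab)[tab < 5L], collapse = ", "))
  set.seed(seed)
  fit <- rf_fit(t(mat), factor(annotation$condition), ntree = ntree)
  list(per_condition = fit$oob_error$per_class,
       overall = fit$oob_error$overall, fit = fit)
}

#' Train the three-state cell classifier
#'
#' Cells carrying the three state labels are split, stratified within each
#' state, into a 2/3 training and 1/3 test set. A forest is fitted on the
#' training cells with permutation importance, and one-vs-rest ROC AUC per
#' state is computed on the held-out cells from the forest's vote fractions.
#' Genes with mean decrease in accuracy (MDA) > 0 are the contributing
#' classifier genes.
#'
#' @param mat genes x cells control-normalized matrix (training features).
#' @param states named character/factor of state labels for a subset of the
#'   columns of `mat` (names = cell ids); must contain exactly the three
#'   states `repression`, `amplification`, `control_like`, each with >= 6
#'   cells.
#' @param ntree trees (default 200).
#' @param train_fraction fraction per state used for training (default 2/3).
#' @param cv_folds retained as a diagnostic parameter (stratified k-fold OOB
#'   style check is already inherent to bagging); recorded in the model.
#' @param seed RNG seed.
#' @return object of class `state_model`: the forest fit, `feature_genes`,
#'   `mda`, `auc` (named per state, from the held-out third), `train_cells`,
#'   `test_cells`, `seed`.
#' @export
train_state_classifier <- function(mat, states, ntree = 200L,
                                   train_fraction = 2 / 3, cv_folds = 5L,
                                   seed = .default_seed) {
  mat <- as.matrix(mat)
  states <- setNames(as.character(states), names(states))
  if (is.null(names(states))) stop("states must be named by cell id")
  missing <- setdiff(names(states), colnames(mat))
  if (length(missing)) stop("state-labelled cells absent from matrix: ",
                            paste(head(missing, 5L), collapse = ", "))
  bad <- setdiff(unique(states), .states)
  if (length(bad)) stop("unknown state labels: ", paste(bad, collapse = ", "))
  tab <- table(factor(states, levels = .states))
  if (any(tab < 6L))
    stop("each state needs >= 6 cells; short: ",
         paste(names(tab)[tab < 6L], collapse = ", "))

  set.seed(seed)
  train_cells <- unlist(lapply(.states, function(s) {
    pool <- names(states)[states == s]
    sample(pool, size = round(length(pool) * train_fraction))
  }), use.names = FALSE)
  test_cells <- setdiff(names(states), train_cells)

  y_train <- factor(states[train_cells], levels = .states)
  fit <- rf_fit(t(mat[, train_cells, drop = FALSE]), y_train,
                ntree = ntree, importance = TRUE)

  prob <- predict(fit, t(mat[, test_cells, drop = FALSE]), type = "prob")
  y_test <- states[test_cells]
  auc <- vapply(.states, function(s)
    roc_auc(prob[, s], y_test == s), numeric(1))

  structure(list(fit = fit, feature_genes = rownames(mat),
                 mda = fit$importance,
                 contributing_genes = names(fit$importance)[
                   fit$importance > 0],
                 auc = auc, train_cells = sort(train_cells),
                 test_cells = sort(test_cells), ntree = as.integer(ntree),
                 cv_folds = as.integer(cv_folds), seed = seed),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("Three-state cell classifier (", x$ntree, "trees )\n")
  cat("Held-out one-vs-rest AUC:",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat(length(x$contributing_genes), "genes with MDA > 0\n")
  invisible(x)
}

#' Classify cells into the three transcriptional states
#'
#' Applies a trained state model to every cell. The three state
#' "P-values" are the forest's vote fractions; they are non-negative and
#' sum to exactly 1 per cell. The decided state is the largest P-value,
#' ties broken in the fixed order repression, amplification, control-like.
#'
#' @param model a `state_model`.
#' @param mat genes x cells matrix covering the model's feature genes.
#' @param annotation optional annotation data.frame to augment; if given,
#'   columns `p_repression`, `p_amplification`, `p_control_like`,
#'   `decided_state` are added/overwritten.
#' @return data.frame with cell_id, the three P-values and `decided_state`
#'   (merged into `annotation` when provided).
#' @export
classify_cells <- function(model, mat, annotation = NULL) {
  stopifnot(inherits(model, "state_model"))
  mat <- as.matrix(mat)
  missing <- setdiff(model$feature_genes, rownames(mat))
  if (length(missing))
    stop("matrix lacks model feature genes: ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  prob <- predict(model$fit, t(mat[model$feature_genes, , drop = FALSE]),
                  type = "prob")
  prob <- prob[, .states, drop = FALSE]
  decided <- .states[max.col(prob, ties.method = "first")]
  out <- data.frame(cell_id = colnames(mat),
                    p_repression = prob[, "repression"],
                    p_amplification = prob[, "amplification"],
                    p_control_like = prob[, "control_like"],
                    decided_state = decided, row.names = NULL)
  if (!is.null(annotation)) {
    annotation <- .check_annotation(annotation, colnames(mat))
    out <- cbind(annotation[setdiff(names(annotation), names(out)[-1L])],
                 out[match(annotation$cell_id, out$cell_id), -1L,
                     drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Default PC-threshold gates for training-set selection
#'
#' Predicate strings over oriented PC scores defining, per state, the region
#' of the PCA map from which training cells are drawn without using
#' condition labels. The constants assume the sign orientation of
#' [run_pca()] and a score spread comparable to the reference analysis;
#' tune them (or supply quantile-based gates) for data on another scale.
#' @return named list of predicate strings.
#' @export
default_state_gates <- function() {
  list(control_like = "PC2 > 15",
       repression = "PC1 > 15 & PC2 < 0 & PC3 > 5",
       amplification = "PC1 < -15 & PC2 < 0")
}

#' Label-blind training-set selection from PCA gates
#'
#' Cells satisfying a state's gate predicate form that state's pool,
#' regardless of their condition labels; `n_per_group` cells are then
#' sampled without replacement from each pool. A cell matching several
#' gates is assigned to the first matching state (in the order of `gates`)
#' with a warning — well-chosen gates are disjoint.
#'
#' @param pca a `pca_result`.
#' @param gates named list of predicate strings over `PC1..PCn` (default
#'   [default_state_gates()]); names are state labels.
#' @param n_per_group cells sampled per state pool (default 25).
#' @param seed RNG seed.
#' @param allow_small if TRUE, a pool smaller than `n_per_group` contributes
#'   all its cells instead of erroring.
#' @return named character vector: selected cell ids -> state label.
#' @export
pca_gate_training_selection <- function(pca, gates = default_state_gates(),
                                        n_per_group = 25L,
                                        seed = .default_seed,
                                        allow_small = FALSE) {
  stopifnot(inherits(pca, "pca_result"), length(gates) >= 1L,
            !is.null(names(gates)))
  env <- as.data.frame(pca$scores)
  assigned <- rep(NA_character_, nrow(env))
  for (state in names(gates)) {
    hit <- eval(parse(text = gates[[state]]), envir = env)
    if (!is.logical(hit) || length(hit) != nrow(env))
      stop("gate for '", state, "' is not a per-cell predicate")
    clash <- hit & !is.na(assigned)
    if (any(clash))
      warning(sum(clash), " cell(s) match several gates; kept in '",
              assigned[which(clash)[1L]], "'")
    assigned[hit & is.na(assigned)] <- state
  }
  set.seed(seed)
  out <- character(0)
  for (state in names(gates)) {
    pool <- rownames(pca$scores)[!is.na(assigned) & assigned == state]
    if (length(pool) < n_per_group && !allow_small)
      stop("gate pool for '", state, "' has ", length(pool),
           " cells (< n_per_group = ", n_per_group, ")")
    take <- if (length(pool) <= n_per_group) pool
            else sample(pool, n_per_group)
    out <- c(out, setNames(rep(state, length(take)), take))
  }
  out
}

#' Consistency of gate-selected training against a reference classification
#'
#' Repeatedly (default 200 times) draws a gate-based training set, trains a
#' forest on it, classifies all cells, and records the fraction of cells
#' whose decided state matches `reference_states`. Reports the median
#' fraction and an equal-tail confidence interval over replicates.
#' Replicates whose gate pools are too small are skipped with a warning;
#' more than 50% skipped is an error.
#'
#' @param mat genes x cells control-normalized matrix.
#' @param reference_states named character vector, cell id -> state, from
#'   the label-trained classifier.
#' @param pca a `pca_result` on the same cells (gates are evaluated on it).
#' @param gates named list of gate predicates (default
#'   [default_state_gates()]).
#' @param reps replicates (default 200).
#' @param ci_level equal-tail interval level (default 0.90).
#' @param n_per_group training cells per state per replicate (default 25).
#' @param ntree trees per replicate forest (default 200).
#' @param seed RNG seed.
#' @return list: `median`, `ci` (length 2), `fractions` (per replicate),
#'   `n_skipped`.
#' @export
classification_consistency <- function(mat, reference_states, pca,
                                       gates = default_state_gates(),
                                       reps = 200L, ci_level = 0.90,
                                       n_per_group = 25L, ntree = 200L,
                                       seed = .default_seed) {
  mat <- as.matrix(mat)
  stopifnot(reps >= 2L, inherits(pca, "pca_result"))
  if (is.null(names(reference_states)))
    stop("reference_states must be named by cell id")
  cells <- colnames(mat)
  ref <- reference_states[cells]
  if (anyNA(ref)) stop("reference_states must cover every cell in mat")

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  fractions <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sel <- tryCatch(
      pca_gate_training_selection(pca, gates, n_per_group,
                                  seed = rep_seeds[r]),
      error = function(e) NULL)
    if (is.null(sel) || length(unique(sel)) < length(gates)) {
      warning("replicate ", r, " skipped: gate pool too small")
      next
    }
    set.seed(rep_seeds[r])
    fit <- rf_fit(t(mat[, names(sel), drop = FALSE]),
                  factor(sel, levels = names(gates)), ntree = ntree)
    pred <- predict(fit, t(mat), type = "class")
    fractions[r] <- mean(as.character(pred) == ref)
  }
  n_skipped <- sum(is.na(fractions))
  if (n_skipped > reps / 2)
    stop("more than half of the replicates were skipped (", n_skipped, "/",
         reps, ")")
  f <- fractions[!is.na(fractions)]
  alpha <- (1 - ci_level) / 2
  list(median = median(f),
       ci = unname(quantile(f, c(alpha, 1 - alpha))),
       fractions = fractions, n_skipped = n_skipped)
}
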