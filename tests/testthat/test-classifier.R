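test_that("differential gene selection uses an inclusive log2 threshold", {
  e <- rbind(FLAT = rep(2, 8),
             EDGE = c(rep(2, 4), rep(2 + log2(1.5), 4)),
             BELOW = c(rep(2, 4), rep(2 + log2(1.4), 4)))
  colnames(e) <- paste0("c", 1:8)
  ann <- make_annotation(colnames(e), rep(c("control", "CELE16"), each = 4))
  sel <- select_differential_genes(evalues_from_e(e), ann, fold = 1.5)
  expect_setequal(sel$genes, "EDGE")
  # returned matrix is E minus the control mean per gene
  expect_equal(unname(sel$matrix["EDGE", ]),
               c(rep(0, 4), rep(log2(1.5), 4)))
  expect_error(select_differential_genes(
    evalues_from_e(e), make_annotation(colnames(e), rep("CELE16", 8))),
    "control")
})

test_that("PCA: rank-1 identity, duplicate symmetry, sign orientation", {
  set.seed(1)
  loading <- rnorm(10)
  scores1 <- rnorm(6)
  m <- outer(loading, scores1)
  dimnames(m) <- list(paste0("g", 1:10), paste0("c", 1:6))
  p <- run_pca(m, n_components = 3L)
  expect_equal(p$var_explained[[1L]], 1, tolerance = 1e-10)

  m2 <- cbind(m, c7 = m[, 3])
  p2 <- run_pca(m2, n_components = 2L)
  expect_equal(p2$scores["c7", ], p2$scores["c3", ])

  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  pca <- run_pca(sel$matrix, sim$annotation)
  tc <- sim$truth$cells
  expect_gt(mean(pca$scores[tc$true_state == "repression", 1]), 0)
  expect_gt(mean(pca$scores[tc$true_state == "control_like", 2]), 0)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_error(run_pca(m[, 1:2]), "3 cells")
})

test_that("three planted states separate on PC1-2 (silhouette > 0.3)", {
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  pca <- run_pca(sel$matrix, sim$annotation)
  xy <- pca$scores[, 1:2]
  lab <- sim$truth$cells$true_state
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.3)
})

test_that("OOB condition errors: separation, chance level, preconditions", {
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  oob <- oob_condition_error(sel$matrix, sim$annotation, ntree = 300,
                             seed = 1)
  expect_true(all(oob$per_condition < 0.1)) # pure, well-separated states

  set.seed(42)
  ann_perm <- sim$annotation
  ann_perm$condition <- sample(ann_perm$condition)
  oob_p <- oob_condition_error(sel$matrix, ann_perm, ntree = 300, seed = 1)
  expect_lt(abs(oob_p$overall - (1 - 1 / 3)), 0.1)

  one <- sim$annotation; one$condition <- "control"
  expect_error(oob_condition_error(sel$matrix, one), "2 conditions")
  few <- sim$annotation; few$condition[1:3] <- "tiny"
  few$condition[-(1:3)] <- "control"
  expect_error(oob_condition_error(sel$matrix, few), "fewer than 5")
})

test_that("state classifier: training contract and probability algebra", {
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  states <- state_labels(sim$annotation)
  model <- train_state_classifier(sel$matrix, states, seed = 7)
  # stratified 2/3 split
  expect_equal(length(model$train_cells), round(2 / 3 * 50) * 3)
  expect_length(intersect(model$train_cells, model$test_cells), 0L)
  expect_true(all(model$auc > 0.9))

  res <- classify_cells(model, sel$matrix, sim$annotation)
  psum <- res$p_repression + res$p_amplification + res$p_control_like
  expect_true(all(abs(psum - 1) < 1e-9))
  expect_true(all(res$decided_state %in%
                    c("repression", "amplification", "control_like")))
  # decided state is the argmax of the triple
  pm <- as.matrix(res[c("p_repression", "p_amplification",
                        "p_control_like")])
  expect_equal(res$decided_state,
               c("repression", "amplification",
                 "control_like")[max.col(pm, ties.method = "first")])
  # a duplicate of a confidently classified training cell keeps its state
  strong <- res$cell_id[res$p_repression > 0.9][1L]
  dup <- sel$matrix[, c(strong, strong), drop = FALSE]
  colnames(dup) <- c("dup1", "dup2")
  res_dup <- classify_cells(model, dup)
  expect_equal(unique(res_dup$decided_state), "repression")

  expect_error(classify_cells(model, sel$matrix[-1, ]),
               model$feature_genes[[1L]])
  expect_error(train_state_classifier(sel$matrix, states[1:60]), "6 cells")
})

test_that("shuffled labels drive test AUC to chance", {
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  states <- state_labels(sim$annotation)
  aucs <- vapply(1:3, function(s) {
    set.seed(s)
    shuffled <- setNames(sample(unname(states)), names(states))
    mean(train_state_classifier(sel$matrix, shuffled, seed = s)$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("MDA importance tracks real signal and vanishes under the null", {
  # in this world every selected gene is state-informative (the global
  # scale shifts all genes), so importance is checked against a
  # label-shuffled null rather than between planted and background genes
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  states <- state_labels(sim$annotation)
  model <- train_state_classifier(sel$matrix, states, seed = 11)
  expect_gt(mean(model$mda > 0), 0.1) # redundant features dilute per-gene MDA
  expect_gt(mean(model$mda), 0)
  set.seed(11)
  shuffled <- setNames(sample(unname(states)), names(states))
  null_model <- train_state_classifier(sel$matrix, shuffled, seed = 11)
  expect_gt(sum(model$mda), 10 * abs(sum(null_model$mda)))
  expect_gt(max(model$mda), 3 * max(null_model$mda))
})

test_that("PCA gates assign pools label-blind and sample reproducibly", {
  scores <- rbind(a = c(20, -5, 6), b = c(5, 20, 0), c = c(-20, -5, 0),
                  d = c(0, 0, 0))
  colnames(scores) <- paste0("PC", 1:3)
  pca <- structure(list(scores = scores, var_explained = c(.5, .3, .2),
                        signs = c(1, 1, 1)), class = "pca_result")
  sel <- pca_gate_training_selection(pca, n_per_group = 1L, seed = 1)
  expect_equal(unname(sel[["a"]]), "repression")   # PC1>15 & PC2<0 & PC3>5
  expect_equal(unname(sel[["b"]]), "control_like") # PC2>15
  expect_equal(unname(sel[["c"]]), "amplification")
  expect_false("d" %in% names(sel))                # matches no gate
  expect_error(pca_gate_training_selection(pca, n_per_group = 2L),
               "n_per_group")
  sel_all <- pca_gate_training_selection(pca, n_per_group = 2L,
                                         allow_small = TRUE)
  expect_length(sel_all, 3L)
  expect_identical(pca_gate_training_selection(pca, n_per_group = 1L,
                                               seed = 9),
                   pca_gate_training_selection(pca, n_per_group = 1L,
                                               seed = 9))
})

test_that("gate-based retraining reproduces the reference classification", {
  sim <- default_three_state()
  sel <- select_differential_genes(sim$evalues, sim$annotation)
  model <- train_state_classifier(sel$matrix, state_labels(sim$annotation),
                                  seed = 3)
  res <- classify_cells(model, sel$matrix)
  ref <- setNames(res$decided_state, res$cell_id)
  pca <- run_pca(sel$matrix, sim$annotation)
  gates <- list(repression = "PC1 > 15",
                amplification = "PC1 < -15 & PC2 < -2",
                control_like = "PC1 < 10 & PC2 > 2")
  cons <- classification_consistency(sel$matrix, ref, pca, gates,
                                     reps = 30, seed = 3)
  expect_gt(cons$median, 0.9)
  expect_true(cons$ci[1] <= cons$median && cons$median <= cons$ci[2])

  # chance-level oracle: randomized reference
  set.seed(5)
  ref_rand <- setNames(sample(c("repression", "amplification",
                                "control_like"), length(ref),
                              replace = TRUE), names(ref))
  cons_rand <- classification_consistency(sel$matrix, ref_rand, pca, gates,
                                          reps = 10, seed = 5)
  expect_lt(abs(cons_rand$median - 1 / 3), 0.1)
})
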