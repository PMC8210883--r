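make_panel <- function(values) {
  list(values = values,
       mask = matrix(TRUE, nrow(values), ncol(values),
                     dimnames = dimnames(values)))
}

test_that("expression/variability filter applies strict thresholds", {
  n <- 20L
  v <- rbind(OK = seq(4, 4 + 2.0, length.out = n),     # p90-p10 = 1.6 > log2 3
             NARROW = seq(4, 4 + 1.0, length.out = n), # 0.8 < log2 3
             CONST = rep(4, n),
             HALF = seq(4, 4 + 2.0, length.out = n))
  colnames(v) <- paste0("s", seq_len(n))
  panel <- make_panel(v)
  panel$mask["HALF", ] <- rep(c(TRUE, FALSE), n / 2) # exactly 50% expressed
  kept <- filter_expressed_variable_genes(panel, rownames(v))
  expect_setequal(kept, "OK")
  expect_error(filter_expressed_variable_genes(panel, "MISSING"), "seed")
})

test_that("module refinement: trivial coherence and fixed-point oracle", {
  n <- 30L
  row <- sin(seq_len(n))
  v <- matrix(rep(row, each = 4), 4, n,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:n)))
  panel <- make_panel(v)
  mod <- iterative_module_refinement(panel, rownames(v))
  expect_equal(nrow(mod$trace), 1L) # one iteration, nothing removed
  expect_setequal(mod$retained, rownames(v))

  # independent oracle: recompute every leave-one-out Spearman at the
  # reported fixed point and check the stopping condition
  pan <- simulate_cell_line_panel(synth_config(seed = 21L))
  mod2 <- iterative_module_refinement(
    pan$panel, filter_expressed_variable_genes(pan$panel, pan$seed_genes))
  centered <- pan$panel$values[mod2$retained, , drop = FALSE] -
    apply(pan$panel$values[mod2$retained, , drop = FALSE], 1, median)
  rho_check <- vapply(seq_along(mod2$retained), function(j) {
    s <- apply(centered[-j, , drop = FALSE], 2, median)
    cor(centered[j, ], s, method = "spearman")
  }, numeric(1))
  expect_true(all(rho_check >= mod2$rho_min))
  expect_equal(unname(mod2$rho), rho_check)
  # trace is monotone non-increasing in gene count
  expect_true(all(diff(mod2$trace$n_genes) <= 0))
})

test_that("refinement keeps the planted module and prunes decoys", {
  pan <- simulate_cell_line_panel(synth_config(seed = 22L))
  mod <- iterative_module_refinement(
    pan$panel, filter_expressed_variable_genes(pan$panel, pan$seed_genes))
  truth <- pan$truth$genes
  module <- truth$gene_id[truth$true_module_member]
  decoys <- truth$gene_id[!truth$true_module_member]
  expect_gte(mean(module %in% mod$retained), 0.9)
  expect_gte(mean(!decoys %in% mod$retained), 0.9)
})

test_that("refinement does not hallucinate coherence from independent genes", {
  set.seed(31)
  v <- matrix(rnorm(40 * 300), 40, 300,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%03d", 1:300)))
  mod <- tryCatch(iterative_module_refinement(make_panel(v), rownames(v)),
                  error = function(e) e)
  survivors <- if (inherits(mod, "error")) 0L else length(mod$retained)
  expect_lte(survivors, 4L) # empty/tiny or collapse error
})

test_that("response index: centering identities and invariances", {
  # 9 background samples spread around each gene's center m_g, plus one
  # sample exactly at the medians and one exactly 1 log2 unit above them;
  # 11 samples total keep every per-gene median at m_g
  m_g <- c(g1 = 5, g2 = 6, g3 = 7, g4 = 4, g5 = 8)
  v <- t(vapply(m_g, function(m) m + c(-4:4, 0, 1), numeric(11)))
  colnames(v) <- c(paste0("s", 1:9), "at_median", "probe")
  panel <- make_panel(v)
  idx <- compute_response_index(panel, rownames(v))
  expect_equal(unname(idx[["at_median"]]), 0)
  expect_equal(unname(idx[["probe"]]), 1)
  # gene order is irrelevant; per-gene constants cancel
  expect_equal(compute_response_index(panel, rev(rownames(v))), idx)
  v4 <- v + c(1, -2, 0.5, 3, -1)
  expect_equal(compute_response_index(make_panel(v4), rownames(v)), idx)
  expect_error(compute_response_index(panel, character(0)), "empty")
  expect_error(compute_response_index(panel, "nope"), "absent")
})

test_that("index evaluation: perfect ranking, nulls, grouping", {
  idx <- setNames(seq(0, 1, length.out = 30), paste0("s", 1:30))
  ic50 <- 2^idx # deterministic monotone link
  ev <- evaluate_index_outcome(idx, ic50)
  expect_equal(ev$auc, 1)
  expect_equal(ev$type, "ic50")
  expect_lt(ev$p_value, 0.01)

  responder <- idx < 0.5 # low index responds
  ev2 <- evaluate_index_outcome(idx, responder)
  expect_equal(ev2$auc, 1) # AUC scores the non-responder class
  expect_error(evaluate_index_outcome(idx[1:5], ic50[1:5]), "10")
  expect_error(evaluate_index_outcome(idx, rep(TRUE, 30)), "empty")
})

test_that("context restriction filters by expressed fraction in context", {
  mask <- rbind(A = rep(c(TRUE, FALSE), c(8, 2)),   # 80% in context
                B = rep(c(TRUE, FALSE), c(5, 5)),   # exactly 50%
                C = rep(TRUE, 10))
  colnames(mask) <- paste0("s", 1:10)
  kept <- restrict_geneset_to_context(c("A", "B", "C"), mask)
  expect_setequal(kept, c("A", "C"))
  # context = all samples reproduces the expression half of the seed filter
  pan <- simulate_cell_line_panel(synth_config(seed = 23L))
  via_context <- restrict_geneset_to_context(pan$seed_genes,
                                             pan$panel$mask)
  loose <- filter_expressed_variable_genes(pan$panel, pan$seed_genes,
                                           range_fold = 1e-9)
  expect_setequal(via_context, loose)
  expect_error(restrict_geneset_to_context("A", mask,
                                           context = character(0)),
               "context")
  mask["A", ] <- FALSE
  expect_error(restrict_geneset_to_context("A", mask), "expressed")
})
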