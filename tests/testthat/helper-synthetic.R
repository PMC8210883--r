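# Shared fixtures, all generated in code. Expensive simulations are memoised
# per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default six-condition experiment plus its normalized E-values
default_sim <- function() cached("default_sim", {
  sim <- simulate_single_cell_experiment(synth_config(seed = 101L))
  sim$evalues <- compute_evalues(normalize_to_spikein(sim$tpm, sim$spikeins))
  sim
})

# three pure-state conditions, 50 cells each (the classifier's stated world)
three_state_sim <- function(seed = 101L) {
  sim <- simulate_single_cell_experiment(synth_config(
    cells_per_condition = c(control = 50L, CELE16 = 50L, COMBO16 = 50L),
    seed = seed))
  sim$evalues <- compute_evalues(normalize_to_spikein(sim$tpm, sim$spikeins))
  sim
}

default_three_state <- function() cached("three_state", three_state_sim())

# condition -> representative state for classifier training
state_labels <- function(annotation) {
  map <- c(control = "control_like", CELE16 = "repression",
           COMBO16 = "amplification")
  hit <- annotation$condition %in% names(map)
  setNames(unname(map[annotation$condition[hit]]), annotation$cell_id[hit])
}

# build an evalues object directly from an E matrix (for arithmetic tests)
evalues_from_e <- function(e, capture_scale = 10) {
  structure(list(N = (2^e - 1) * capture_scale, E = e,
                 capture_scale = capture_scale, anchor_id = NA_character_,
                 spikein_ids = character(0)),
            class = "evalues")
}

# minimal annotation for a set of cells
make_annotation <- function(cells, conditions) {
  data.frame(cell_id = cells, condition = conditions,
             stringsAsFactors = FALSE)
}

# a vector with exact mean m and sd s over n cells (n even)
exact_mean_sd <- function(m, s, n) {
  stopifnot(n %% 2 == 0)
  m + s * rep(c(-1, 1), n / 2)
}

# brute-force two-sided Wilcoxon p by enumerating all rank splits
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  u_all <- apply(splits, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean_u <- length(x) * length(y) / 2
  mean(abs(u_all - mean_u) >= abs(u_obs - mean_u) - 1e-9)
}
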