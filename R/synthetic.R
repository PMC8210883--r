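#' Configuration for the synthetic-data generators
#'
#' Defaults encode the stated world the pipeline assumes: a six-condition
#' drug-treatment design (control; paclitaxel 16 h / 48 h; celecoxib 2 h /
#' 16 h; combination 16 h) with a few hundred cells, three spike-in RNAs at
#' fixed absolute amounts per cell, state-dependent global mRNA-content
#' scaling (repression 0.45x, amplification 1.5x, control-like 1x),
#' three planted regulatory gene clusters with 2-fold absolute effects, a
#' small set of extra-variable (cell-cycle-like) genes, and — for the
#' cell-line panel — one positively co-expressed gene module whose latent
#' activity is monotonically linked to paclitaxel IC50 and responder status.
#'
#' @param n_genes endogenous genes.
#' @param n_spikeins spike-in records (default 3).
#' @param spikein_design relative concentration of each spike-in (fold
#'   units, first = highest by default).
#' @param spikein_amount total spike-in molecules as a fraction of the
#'   control-cell endogenous molecule budget (constant per cell).
#' @param cells_per_condition named integer vector, condition -> cell count.
#' @param state_scaling named multipliers of global mRNA content per state.
#' @param state_mixture named list: condition -> probability vector over
#'   states (how conditions decompose into transcriptional states).
#' @param de_effects named fold-change magnitudes per cluster (I, II, III);
#'   cluster I genes move down `1/fold` in repression and up `fold` in
#'   amplification, cluster II only down in repression, cluster III only up
#'   in amplification — all on the absolute (spike-in-anchored) scale.
#' @param cluster_sizes named gene counts per planted cluster.
#' @param n_housekeeping stably, highly expressed genes used by QC.
#' @param n_highvar_genes cell-cycle-like genes whose expression toggles
#'   between a low and a high state across cells within every condition.
#' @param highvar_fold fold separation between the high and low state of
#'   those genes (mean-preserving two-state mixture, on-fraction 1/2).
#' @param cell_scale_sd_log2 sd (log2) of per-cell global-content
#'   heterogeneity around the state scale.
#' @param noise_cv multiplicative log-normal measurement noise CV.
#' @param dropout_rate overall expected zero fraction among endogenous
#'   gene-cell entries. Per-gene dropout follows the standard
#'   logistic-in-log-expression decay (highly expressed genes are almost
#'   never missed, weak genes often are); applied after scaling.
#' @param read_depth sequencing depth for the per-cell read-count pair.
#' @param n_lowquality_cells extra low-quality cells planted for QC tests.
#' @param lowquality_capture capture efficiency of low-quality cells.
#' @param n_cell_lines samples in the cell-line panel.
#' @param module_size planted coherent-module genes in the panel.
#' @param n_decoy_genes independent decoy genes in the panel.
#' @param ic50_link_strength correlation target between the module latent
#'   factor and log-IC50 (and, scaled, the patient responder separation).
#' @param mask_expressed_rate marginal TRUE rate of the expressed-call mask.
#' @param panel_noise_sd residual sd of panel log2 expression.
#' @param n_patients patient-cohort size.
#' @param responder_fraction fraction of responders in the cohort.
#' @param seed integer RNG seed; identical seed gives identical output.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L,
                         n_spikeins = 3L,
                         spikein_design = c(1, 0.2, 0.05),
                         spikein_amount = 0.05,
                         cells_per_condition = c(control = 57L, PAC16 = 58L,
                                                 PAC48 = 65L, CELE2 = 66L,
                                                 CELE16 = 67L, COMBO16 = 59L),
                         state_scaling = c(control_like = 1,
                                           repression = 0.45,
                                           amplification = 1.5),
                         state_mixture = list(
                           control = c(control_like = 1),
                           PAC16 = c(repression = 0.55,
                                     amplification = 0.04,
                                     control_like = 0.41),
                           PAC48 = c(repression = 0.47,
                                     control_like = 0.53),
                           CELE2 = c(control_like = 1),
                           CELE16 = c(repression = 1),
                           COMBO16 = c(amplification = 1)),
                         de_effects = c(I = 2, II = 2, III = 2),
                         cluster_sizes = c(I = 290L, II = 590L, III = 320L),
                         n_housekeeping = 50L,
                         n_highvar_genes = 16L,
                         highvar_fold = 16,
                         cell_scale_sd_log2 = 0,
                         noise_cv = 0.25,
                         dropout_rate = 0.3,
                         read_depth = 1e6,
                         n_lowquality_cells = 0L,
                         lowquality_capture = 0.001,
                         n_cell_lines = 300L,
                         module_size = 20L,
                         n_decoy_genes = 20L,
                         ic50_link_strength = 0.8,
                         mask_expressed_rate = 0.95,
                         panel_noise_sd = 0.7,
                         n_patients = 100L,
                         responder_fraction = 0.3,
                         seed = 20210617L) {
  cfg <- list(n_genes = n_genes, n_spikeins = n_spikeins,
              spikein_design = spikein_design,
              spikein_amount = spikein_amount,
              cells_per_condition = cells_per_condition,
              state_scaling = state_scaling, state_mixture = state_mixture,
              de_effects = de_effects, cluster_sizes = cluster_sizes,
              n_housekeeping = n_housekeeping,
              n_highvar_genes = n_highvar_genes,
              highvar_fold = highvar_fold,
              cell_scale_sd_log2 = cell_scale_sd_log2,
              noise_cv = noise_cv, dropout_rate = dropout_rate,
              read_depth = read_depth,
              n_lowquality_cells = n_lowquality_cells,
              lowquality_capture = lowquality_capture,
              n_cell_lines = n_cell_lines, module_size = module_size,
              n_decoy_genes = n_decoy_genes,
              ic50_link_strength = ic50_link_strength,
              mask_expressed_rate = mask_expressed_rate,
              panel_noise_sd = panel_noise_sd, n_patients = n_patients,
              responder_fraction = responder_fraction, seed = seed)
  .validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

.cfg_fail <- function(field, why) {
  stop("invalid configuration field '", field, "': ", why, call. = FALSE)
}

.validate_synth_config <- function(cfg) {
  count_fields <- c("n_genes", "n_spikeins", "n_housekeeping",
                    "n_cell_lines", "module_size", "n_patients")
  for (f in count_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      .cfg_fail(f, "must be a positive integer")
  for (f in c("n_highvar_genes", "n_lowquality_cells", "n_decoy_genes"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      .cfg_fail(f, "must be a non-negative integer")
  if (length(cfg$spikein_design) != cfg$n_spikeins)
    .cfg_fail("spikein_design", "length must equal n_spikeins")
  if (any(cfg$spikein_design <= 0))
    .cfg_fail("spikein_design", "concentrations must be > 0")
  for (f in c("spikein_amount", "noise_cv",
              "read_depth", "lowquality_capture", "panel_noise_sd"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      .cfg_fail(f, "must be a single positive number")
  if (cfg$cell_scale_sd_log2 < 0)
    .cfg_fail("cell_scale_sd_log2", "must be >= 0")
  if (!is.numeric(cfg$highvar_fold) || cfg$highvar_fold < 1)
    .cfg_fail("highvar_fold", "must be >= 1")
  for (f in c("dropout_rate", "responder_fraction", "mask_expressed_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      .cfg_fail(f, "must be a probability in [0, 1]")
  if (abs(cfg$ic50_link_strength) > 1)
    .cfg_fail("ic50_link_strength", "must be a correlation in [-1, 1]")
  if (is.null(names(cfg$cells_per_condition)) ||
      any(cfg$cells_per_condition < 1))
    .cfg_fail("cells_per_condition", "must be named counts > 0")
  if (any(cfg$state_scaling <= 0))
    .cfg_fail("state_scaling", "multipliers must be > 0")
  missing_states <- setdiff(names(cfg$state_scaling), .states)
  if (length(missing_states))
    .cfg_fail("state_scaling", paste("unknown state",
                                     paste(missing_states, collapse = ", ")))
  for (cc in names(cfg$cells_per_condition)) {
    mix <- cfg$state_mixture[[cc]]
    if (is.null(mix))
      .cfg_fail("state_mixture", paste("no mixture for condition", cc))
    if (abs(sum(mix) - 1) > 1e-8)
      .cfg_fail("state_mixture", paste("probabilities for", cc,
                                       "do not sum to 1"))
    if (length(setdiff(names(mix), names(cfg$state_scaling))))
      .cfg_fail("state_mixture", paste("unknown state in", cc))
  }
  if (any(cfg$de_effects < 1))
    .cfg_fail("de_effects", "fold magnitudes must be >= 1")
  if (!all(c("I", "II", "III") %in% names(cfg$cluster_sizes)))
    .cfg_fail("cluster_sizes", "needs entries I, II, III")
  n_special <- cfg$n_housekeeping + sum(cfg$cluster_sizes) +
    cfg$n_highvar_genes
  if (n_special > cfg$n_genes)
    .cfg_fail("n_genes", paste("must cover housekeeping + clusters +",
                               "high-variance genes (need >=", n_special,
                               ")"))
  if (cfg$module_size < 2)
    .cfg_fail("module_size", "must be >= 2")
  if (cfg$n_patients < 10)
    .cfg_fail("n_patients", "must be >= 10 (rank tests unstable below)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    .cfg_fail("seed", "must be a single integer")
  invisible(cfg)
}

# internal: per-gene absolute expression multiplier for each state.
# DE clusters get their planted folds; the remaining genes share a common
# multiplier solved so total endogenous content equals the state scale,
# making the planted global scale exact by construction.
.state_multipliers <- function(weights, cluster, cfg) {
  mult <- matrix(1, nrow = length(weights), ncol = length(.states),
                 dimnames = list(names(weights), .states))
  f <- cfg$de_effects
  mult[cluster == "I", "repression"] <- 1 / f[["I"]]
  mult[cluster == "I", "amplification"] <- f[["I"]]
  mult[cluster == "II", "repression"] <- 1 / f[["II"]]
  mult[cluster == "III", "amplification"] <- f[["III"]]
  w_total <- sum(weights)
  for (s in .states) {
    de <- cluster != "none"
    budget <- cfg$state_scaling[[s]] * w_total
    de_mass <- sum(weights[de] * mult[de, s])
    bg_mass <- w_total - sum(weights[de])
    b <- (budget - de_mass) / bg_mass
    if (b <= 0)
      stop("state '", s, "' scale is too extreme for the planted clusters")
    mult[!de, s] <- b
  }
  mult
}

#' Simulate a spike-in-anchored single-cell drug-treatment experiment
#'
#' Molecule-level simulation: every cell receives the same absolute amount
#' of each spike-in; endogenous molecule totals are the product of the
#' cell's state scale, per-cell heterogeneity and per-gene state
#' multipliers. TPM is then the molecular composition times 1e6, so
#' spike-in TPM automatically anti-correlates with cellular mRNA content —
#' the physical premise of spike-in normalization. Measurement noise is
#' multiplicative log-normal (mean 1); dropout zeroes endogenous entries
#' after scaling.
#'
#' @param config a [synth_config()].
#' @return list with `tpm` (genes+spike-ins x cells, columns summing to
#'   1e6), `reads` (data.frame cell_id, endogenous_reads, spikein_reads),
#'   `annotation` (cell_id, condition), `spikeins` ([spikein_set()]),
#'   `genesets` (housekeeping and planted cluster/high-variance gene lists),
#'   and `truth` (`cells` and `genes` data.frames).
#' @export
simulate_single_cell_experiment <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  spike_ids <- paste0("SPIKE", seq_len(cfg$n_spikeins))

  # gene roles: housekeeping, cluster I/II/III, high-variance, background
  role <- rep("none", cfg$n_genes)
  idx <- 1L
  take <- function(n) {
    out <- seq.int(idx, length.out = n)
    idx <<- idx + n
    out
  }
  hk_idx <- take(cfg$n_housekeeping)
  cl1_idx <- take(cfg$cluster_sizes[["I"]])
  cl2_idx <- take(cfg$cluster_sizes[["II"]])
  cl3_idx <- take(cfg$cluster_sizes[["III"]])
  hv_idx <- if (cfg$n_highvar_genes > 0) take(cfg$n_highvar_genes)
            else integer(0)
  cluster <- rep("none", cfg$n_genes)
  cluster[cl1_idx] <- "I"
  cluster[cl2_idx] <- "II"
  cluster[cl3_idx] <- "III"

  # baseline molecular weights: log-normal across genes; housekeeping
  # genes pinned high and stable so the QC gate separates cleanly
  weights <- 2^rnorm(cfg$n_genes, mean = 0, sd = 1.5)
  weights[hk_idx] <- 4
  # cell-cycle-like genes are well expressed, as their real counterparts are;
  # this also keeps them in mean-expression bins where the CV-mean trend is
  # flat enough for the binned criterion to see their excess variance
  weights[hv_idx] <- 2^runif(length(hv_idx), 0.5, 3)
  names(weights) <- gene_ids

  mult <- .state_multipliers(weights, cluster, cfg)

  # cells: condition labels, then states drawn from the condition mixture
  conds <- rep(names(cfg$cells_per_condition), cfg$cells_per_condition)
  n_main <- length(conds)
  n_lowq <- cfg$n_lowquality_cells
  if (n_lowq > 0) # spread planted low-quality cells across conditions
    conds <- c(conds, rep_len(names(cfg$cells_per_condition), n_lowq))
  n_cells <- length(conds)
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))
  state <- vapply(conds, function(cc) {
    mix <- cfg$state_mixture[[cc]]
    sample(names(mix), 1L, prob = mix)
  }, character(1))
  lowq <- c(rep(FALSE, n_main), rep(TRUE, n_lowq))

  size <- 2^rnorm(n_cells, mean = 0, sd = cfg$cell_scale_sd_log2)
  capture <- ifelse(lowq, cfg$lowquality_capture, 1)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))

  # detection failure decays logistically with baseline expression
  # (slope 4 per log2 unit, a steep Smart-seq2-like detection curve that
  # concentrates zeros in the weak tail the detection filter later drops);
  # the intercept is solved so the marginal zero fraction over endogenous
  # gene-cell entries equals dropout_rate, while highly expressed
  # (e.g. housekeeping) genes are essentially never missed
  lw <- log2(weights) - median(log2(weights))
  a <- uniroot(function(a) mean(plogis(a - 4 * lw)) - cfg$dropout_rate,
               c(-60, 60))$root
  p_drop <- plogis(a - 4 * lw)

  # high-variance genes toggle between a low and a high state across cells
  # (cell-cycle-phase-like), mean-preserving at fold separation highvar_fold
  h <- cfg$highvar_fold
  hv_lo <- 2 / (1 + h)
  hv_hi <- 2 * h / (1 + h)

  spike_mol <- cfg$spikein_design / sum(cfg$spikein_design) *
    cfg$spikein_amount * sum(weights)

  tpm <- matrix(0, nrow = cfg$n_genes + cfg$n_spikeins, ncol = n_cells,
                dimnames = list(c(gene_ids, spike_ids), cell_ids))
  endo_rows <- seq_len(cfg$n_genes)
  spike_rows <- cfg$n_genes + seq_len(cfg$n_spikeins)
  for (k in seq_len(n_cells)) {
    expected <- weights * mult[, state[[k]]] * size[[k]] * capture[[k]]
    if (length(hv_idx))
      expected[hv_idx] <- expected[hv_idx] *
        ifelse(runif(length(hv_idx)) < 0.5, hv_hi, hv_lo)
    noise <- exp(rnorm(cfg$n_genes, -sdlog^2 / 2, sdlog))
    mol <- expected * noise
    mol[runif(cfg$n_genes) < p_drop] <- 0
    smol <- spike_mol * exp(rnorm(cfg$n_spikeins, -sdlog^2 / 2, sdlog))
    total <- sum(mol) + sum(smol)
    tpm[endo_rows, k] <- mol / total * 1e6
    tpm[spike_rows, k] <- smol / total * 1e6
  }

  endo_frac <- colSums(tpm[endo_rows, , drop = FALSE]) / 1e6
  endo_reads <- rbinom(n_cells, size = as.integer(cfg$read_depth),
                       prob = endo_frac)
  reads <- data.frame(cell_id = cell_ids, endogenous_reads = endo_reads,
                      spikein_reads = as.integer(cfg$read_depth) - endo_reads)

  annotation <- data.frame(cell_id = cell_ids, condition = conds,
                           row.names = NULL)
  truth_cells <- data.frame(
    cell_id = cell_ids, condition = conds, true_state = unname(state),
    true_state_scale = unname(cfg$state_scaling[state]),
    true_cell_scale = unname(cfg$state_scaling[state] * size * capture),
    low_quality = lowq, row.names = NULL)
  truth_genes <- data.frame(
    gene_id = gene_ids, true_cluster = cluster,
    true_highvar = seq_len(cfg$n_genes) %in% hv_idx,
    housekeeping = seq_len(cfg$n_genes) %in% hk_idx, row.names = NULL)

  list(tpm = tpm, reads = reads, annotation = annotation,
       spikeins = spikein_set(spike_ids,
                              designed_concentrations = cfg$spikein_design,
                              anchor_id = spike_ids[
                                which.max(cfg$spikein_design)]),
       genesets = list(housekeeping = gene_ids[hk_idx],
                       cluster_I = gene_ids[cl1_idx],
                       cluster_II = gene_ids[cl2_idx],
                       cluster_III = gene_ids[cl3_idx],
                       highvar = gene_ids[hv_idx]),
       truth = list(cells = truth_cells, genes = truth_genes),
       config = cfg)
}

#' Simulate a cell-line expression panel with a planted coherent module
#'
#' Module genes share one latent factor z (per sample), giving positive
#' pairwise correlation; decoy genes are independent. log-IC50 is linked to
#' z at correlation `ic50_link_strength`, so higher module expression means
#' higher IC50 (worse drug response).
#'
#' @param config a [synth_config()].
#' @return list with `panel` (list `values` genes x samples log2
#'   expression, `mask` logical expressed calls), `ic50` (named vector),
#'   `seed_genes` (module + decoys, the candidate geneset), and `truth`
#'   (data.frame gene_id, true_module_member; plus `latent` per sample).
#' @export
simulate_cell_line_panel <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)

  n <- cfg$n_cell_lines
  mod_ids <- sprintf("MOD%03d", seq_len(cfg$module_size))
  dec_ids <- if (cfg$n_decoy_genes > 0)
    sprintf("DEC%03d", seq_len(cfg$n_decoy_genes)) else character(0)
  ids <- c(mod_ids, dec_ids)
  samples <- sprintf("line%04d", seq_len(n))

  z <- rnorm(n)
  mu <- rnorm(length(ids), mean = 6, sd = 1)
  values <- matrix(NA_real_, length(ids), n, dimnames = list(ids, samples))
  for (g in seq_along(ids)) {
    if (g <= cfg$module_size)
      values[g, ] <- mu[g] + z + rnorm(n, sd = cfg$panel_noise_sd)
    else
      values[g, ] <- mu[g] + rnorm(n, sd = sqrt(1 + cfg$panel_noise_sd^2))
  }
  mask <- matrix(runif(length(values)) < cfg$mask_expressed_rate,
                 nrow = nrow(values), dimnames = dimnames(values))

  r <- cfg$ic50_link_strength
  log_ic50 <- r * z + sqrt(max(0, 1 - r^2)) * rnorm(n)
  ic50 <- setNames(10^(0.5 * log_ic50) * 0.01, samples) # micromolar-ish

  list(panel = list(values = values, mask = mask),
       ic50 = ic50,
       seed_genes = ids,
       truth = list(genes = data.frame(gene_id = ids,
                                       true_module_member =
                                         ids %in% mod_ids,
                                       row.names = NULL),
                    latent = setNames(z, samples)),
       config = cfg)
}

#' Simulate a patient cohort with responder labels
#'
#' Uses the same module/decoy gene vocabulary as the cell-line panel.
#' Responders have a stochastically lower module latent factor (shift
#' `2 * ic50_link_strength` standard deviations), so lower module
#' expression predicts response.
#'
#' @param config a [synth_config()].
#' @return list with `expression` (genes x patients log2 matrix), `mask`
#'   (all TRUE; microarray cohorts are analyzed without per-gene calls),
#'   `responder` (named logical), and `truth` (`latent` per patient).
#' @export
simulate_patient_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (cfg$n_patients < 10)
    stop("n_patients must be >= 10 (rank tests unstable below)")
  set.seed(cfg$seed + 2L)

  n <- cfg$n_patients
  mod_ids <- sprintf("MOD%03d", seq_len(cfg$module_size))
  dec_ids <- if (cfg$n_decoy_genes > 0)
    sprintf("DEC%03d", seq_len(cfg$n_decoy_genes)) else character(0)
  ids <- c(mod_ids, dec_ids)
  patients <- sprintf("patient%03d", seq_len(n))

  responder <- runif(n) < cfg$responder_fraction
  # guarantee both classes for rank tests at small n
  if (!any(responder)) responder[1L] <- TRUE
  if (all(responder)) responder[1L] <- FALSE
  shift <- 2 * cfg$ic50_link_strength
  z <- rnorm(n) - shift * responder
  mu <- rnorm(length(ids), mean = 6, sd = 1)
  values <- matrix(NA_real_, length(ids), n, dimnames = list(ids, patients))
  for (g in seq_along(ids)) {
    if (g <= cfg$module_size)
      values[g, ] <- mu[g] + z + rnorm(n, sd = cfg$panel_noise_sd)
    else
      values[g, ] <- mu[g] + rnorm(n, sd = sqrt(1 + cfg$panel_noise_sd^2))
  }
  mask <- matrix(TRUE, nrow(values), ncol(values),
                 dimnames = dimnames(values))
  list(expression = values, mask = mask,
       responder = setNames(responder, patients),
       truth = list(latent = setNames(z, patients)),
       config = cfg)
}
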