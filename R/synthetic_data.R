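#' Configuration for the synthetic interaction study generator
#'
#' Bundles and validates the parameters of [simulate_interaction_study()].
#' Intensities follow a log-normal model: each gene draws a baseline
#' log2-level shared by the two populations, planted partners receive an
#' additive log2 effect on their own side, and replicate arrays add
#' Gaussian log2 noise. Presence calls are thresholded on the linear scale
#' and can be corrupted at a fixed flip rate.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_pairs Database size; the generator draws every pair on disjoint
#'   gene sets, so `2 * n_pairs <= n_genes` is required.
#' @param n_planted Number of true interactions (<= `n_pairs`).
#' @param n_replicates Replicate arrays per population (>= 1; >= 2 needed by
#'   the replicate-based gate).
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2-intensity
#'   distribution (defaults 7 and 1, i.e. linear levels around 128).
#' @param effect_log2 Additive log2 boost given to planted partners on their
#'   own side (default 5, a 32-fold contrast).
#' @param noise_log2_sd Replicate noise on the log2 scale (default 0.5).
#' @param presence_threshold Linear intensity above which a call is `P`
#'   (default 50).
#' @param call_flip_rate Probability of flipping each presence call
#'   (default 0).
#' @param seed Integer RNG seed; every draw derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200, n_pairs = 40, n_planted = 20,
                              n_replicates = 3,
                              baseline_log2_mean = 7, baseline_log2_sd = 1,
                              effect_log2 = 5, noise_log2_sd = 0.5,
                              presence_threshold = 50, call_flip_rate = 0,
                              seed = 1) {
  cfg <- list(n_genes = n_genes, n_pairs = n_pairs, n_planted = n_planted,
              n_replicates = n_replicates,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              effect_log2 = effect_log2, noise_log2_sd = noise_log2_sd,
              presence_threshold = presence_threshold,
              call_flip_rate = call_flip_rate, seed = seed)
  for (nm in c("n_genes", "n_pairs", "n_planted", "n_replicates", "seed")) {
    if (!is_count(cfg[[nm]])) stopf("%s must be a single integer", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (cfg$n_genes < 10L) stopf("n_genes must be >= 10")
  if (cfg$n_pairs < 1L) stopf("n_pairs must be >= 1")
  if (cfg$n_planted < 0L || cfg$n_planted > cfg$n_pairs) {
    stopf("n_planted must lie in [0, n_pairs]")
  }
  if (2L * cfg$n_pairs > cfg$n_genes) {
    stopf(paste("infeasible config: %d pairs on disjoint genes need %d",
                "distinct genes but n_genes = %d"),
          cfg$n_pairs, 2L * cfg$n_pairs, cfg$n_genes)
  }
  if (cfg$n_replicates < 1L) stopf("n_replicates must be >= 1")
  for (nm in c("baseline_log2_sd", "noise_log2_sd")) {
    if (!is_number(cfg[[nm]]) || cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  }
  if (!is_number(cfg$presence_threshold) || cfg$presence_threshold < 0) {
    stopf("presence_threshold must be >= 0")
  }
  if (!is_number(cfg$call_flip_rate) || cfg$call_flip_rate < 0 ||
      cfg$call_flip_rate >= 1) {
    stopf("call_flip_rate must lie in [0, 1)")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a population/stroma study with planted interactions
#'
#' Generates a pair of expression profiles, a pair database and the exact
#' ground truth, so the whole gate-and-match pipeline can be exercised and
#' scored without any external data. For each *planted* pair, the
#' population-side partner is boosted by `effect_log2` in the population
#' (and left at baseline in the stroma, making it differentially expressed
#' against the stromal reference) while the stroma-side partner is boosted
#' in the stroma. *Decoy* pairs are made non-matching by construction: one
#' randomly chosen partner is forced far below the presence threshold in
#' both profiles, so decoys fail the matcher's presence conditions
#' deterministically and the truth labels are exact.
#'
#' All randomness derives from `config$seed`; the generator uses R's default
#' Mersenne-Twister stream, so a fixed seed reproduces the study bit-for-bit
#' across platforms.
#'
#' @param config A [simulation_config()].
#' @return An `interaction_simulation` list: `pop` and `stroma`
#'   ([population_profile()]s), `db` ([pair_db()]), `truth` (list with
#'   `planted` and `decoys` tibbles) and `config`.
#' @seealso [evaluate_recovery()]
#' @export
simulate_interaction_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- as.character(100000L + seq_len(n))
  symbols <- sprintf("G%04d", seq_len(n))

  base <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  perm <- sample.int(n)
  pop_partner <- perm[seq_len(config$n_planted)]
  str_partner <- perm[config$n_planted + seq_len(config$n_planted)]
  n_decoy <- config$n_pairs - config$n_planted
  decoy_a <- perm[2L * config$n_planted + seq_len(n_decoy)]
  decoy_b <- perm[2L * config$n_planted + n_decoy + seq_len(n_decoy)]
  forced_side <- sample(c("a", "b"), n_decoy, replace = TRUE)
  forced <- ifelse(forced_side == "a", decoy_a, decoy_b)

  mu_pop <- base
  mu_str <- base
  mu_pop[pop_partner] <- mu_pop[pop_partner] + config$effect_log2
  mu_str[str_partner] <- mu_str[str_partner] + config$effect_log2
  low <- pmin(base[forced], log2(max(config$presence_threshold, 1))) - 3
  mu_pop[forced] <- low
  mu_str[forced] <- low

  draw <- function(mu) {
    k <- config$n_replicates
    x <- mu + matrix(stats::rnorm(n * k, 0, config$noise_log2_sd), n, k)
    2^x
  }
  int_pop <- draw(mu_pop)
  int_str <- draw(mu_str)
  calls_of <- function(intensity) {
    calls <- ifelse(intensity > config$presence_threshold, "P", "A")
    if (config$call_flip_rate > 0) {
      flip <- matrix(stats::runif(length(calls)) < config$call_flip_rate,
                     nrow(calls), ncol(calls))
      calls[flip] <- ifelse(calls[flip] == "P", "A", "P")
    }
    calls
  }
  pop <- population_profile("simPopulation", genes, symbols, int_pop,
                            calls = calls_of(int_pop))
  stroma <- population_profile("simStroma", genes, symbols, int_str,
                               calls = calls_of(int_str))

  gene_a <- c(pop_partner, decoy_a)
  gene_b <- c(str_partner, decoy_b)
  db <- pair_db(tibble::tibble(
    pair_id = sprintf("SIM%03d", seq_len(config$n_pairs)),
    gene_a = genes[gene_a], symbol_a = symbols[gene_a], role_a = "receptor",
    gene_b = genes[gene_b], symbol_b = symbols[gene_b], role_b = "ligand",
    source = "synthetic"))
  truth <- list(
    planted = tibble::tibble(
      pop_gene = genes[pop_partner], stroma_gene = genes[str_partner],
      direction = "pop_receptor__stroma_ligand"),
    decoys = tibble::tibble(
      gene_a = genes[decoy_a], gene_b = genes[decoy_b],
      forced_absent = genes[forced]))
  structure(list(pop = pop, stroma = stroma, db = db, truth = truth,
                 config = config),
            class = "interaction_simulation")
}

#' Run the full gate-and-match pipeline on a simulation and score it
#'
#' Gates the simulated population against the simulated stroma (the stroma
#' doubles as the differential-expression reference, exactly as a stromal
#' feeder line does in the real screen), matches the gated list against the
#' simulated pair database, and compares the recovered unordered pairs with
#' the planted truth.
#'
#' @param sim An `interaction_simulation`.
#' @param alpha Gate significance threshold (default 0.01).
#' @param test Gate test, see [differential_genes()].
#' @return List with `recall` (planted pairs recovered / planted), `fdp`
#'   (false discovery proportion among predictions, 0 when nothing is
#'   predicted), `n_predicted`, the matched `table` and the `gate`.
#' @export
evaluate_recovery <- function(sim, alpha = 0.01,
                              test = c("welch_t", "moderated_t")) {
  stopifnot(inherits(sim, "interaction_simulation"))
  test <- match.arg(test)
  gate <- differential_genes(sim$pop, sim$stroma, alpha = alpha, test = test)
  tbl <- match_interactions(gate, sim$pop, sim$stroma, sim$db)
  predicted <- unique(unordered_pair_key(
    canonical_key(tbl$pop_gene, tbl$pop_symbol),
    canonical_key(tbl$stroma_gene, tbl$stroma_symbol)))
  planted <- unordered_pair_key(sim$truth$planted$pop_gene,
                                sim$truth$planted$stroma_gene)
  tp <- sum(predicted %in% planted)
  list(recall = if (length(planted)) tp / length(planted) else NA_real_,
       fdp = if (length(predicted)) 1 - tp / length(predicted) else 0,
       n_predicted = length(predicted), table = tbl, gate = gate)
}

#' Write a simulated study to a directory
#'
#' Writes `population.tsv` and `stroma.tsv` (expression format),
#' `pairs.tsv` (pair-table format), `truth.json` and `config.json`, so a
#' simulated study can be consumed by the command-line interface like any
#' real data set.
#'
#' @param sim An `interaction_simulation`.
#' @param dir Output directory (created if needed).
#' @param header_lines Optional `#` comment lines for the TSV files.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, header_lines = character()) {
  stopifnot(inherits(sim, "interaction_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$pop, file.path(dir, "population.tsv"),
                         header_lines)
  write_expression_table(sim$stroma, file.path(dir, "stroma.tsv"),
                         header_lines)
  write_pair_table(sim$db, file.path(dir, "pairs.tsv"), header_lines)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.interaction_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<interaction_simulation> %d genes x %d replicates, ",
                     "%d pairs (%d planted), seed %d\n"),
              cfg$n_genes, cfg$n_replicates, cfg$n_pairs, cfg$n_planted,
              cfg$seed))
  invisible(x)
}
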