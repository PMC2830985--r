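# Shared fixture loaders and independent oracles for the test suite.

ext_path <- function(...) {
  p <- system.file("extdata", ..., package = "stromatch")
  if (!nzchar(p)) stop("fixture not found: ", paste(..., sep = "/"))
  p
}

table_keys <- c("lthsc", "mpp", "lmpp", "clp", "gmp", "prob", "preb",
                "matureb")
table_labels <- c(lthsc = "LT-HSC", mpp = "MPP", lmpp = "LMPP", clp = "CLP",
                  gmp = "GMP", prob = "proB", preb = "preB",
                  matureb = "matureB")

global_pair_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- read_pair_table(ext_path("pairs_tables.tsv"))
    db
  }
})

load_table_fixture <- function(key) {
  list(
    pop = read_population_profile(
      ext_path("tables", sprintf("pop_%s.tsv", key)), table_labels[[key]]),
    op9 = read_population_profile(
      ext_path("tables", sprintf("stroma_op9_%s.tsv", key)), "OP9"),
    nih3t3 = read_population_profile(
      ext_path("tables", sprintf("comp_nih3t3_%s.tsv", key)), "NIH3T3"),
    mc3t3 = read_population_profile(
      ext_path("tables", sprintf("comp_mc3t3_%s.tsv", key)), "MC3T3"),
    expected = read_interaction_table(
      ext_path("tables", sprintf("expected_%s.tsv", key))))
}

match_table_fixture <- function(key, comparators = TRUE) {
  fx <- load_table_fixture(key)
  tbl <- match_interactions(NULL, fx$pop, fx$op9, global_pair_db())
  if (comparators) tbl <- annotate_comparators(tbl, list(fx$nih3t3, fx$mc3t3))
  list(table = tbl, fixture = fx)
}

all_matched_tables <- function() {
  lapply(table_keys, function(k) match_table_fixture(k, comparators = FALSE)$table)
}

# Simple gene-level profile builder for toy cases.
toy_profile <- function(name, genes, intensities, present = NULL,
                        replicates = NULL) {
  mat <- if (is.null(replicates)) matrix(intensities, ncol = 1L) else replicates
  calls <- matrix("A", nrow(mat), ncol(mat))
  pres <- if (is.null(present)) rep(TRUE, length(genes)) else present
  calls[pres, 1L] <- "P"
  population_profile(name, genes = genes, intensities = mat, calls = calls)
}

# A hand-built differential gate carrying an explicit gene list (tests may
# need gates that no statistical rule would produce).
explicit_gate <- function(genes, symbols = genes) {
  x <- tibble::tibble(gene = as.character(genes),
                      symbol = as.character(symbols),
                      p_value = 0, log2_fold_change = 1,
                      direction = "up_in_population")
  structure(x, class = c("de_gene_list", class(x)),
            population = "toy", reference = "toyref", alpha = 0.01)
}

# Independent reference for the matcher: an explicit double loop over
# database records and side assignments, written against the raw columns.
brute_force_match <- function(gate_keys, pop, stroma, db) {
  rec <- as.data.frame(db)
  rec$key_a <- ifelse(nzchar(rec$gene_a), rec$gene_a, tolower(rec$symbol_a))
  rec$key_b <- ifelse(nzchar(rec$gene_b), rec$gene_b, tolower(rec$symbol_b))
  pop_df <- as.data.frame(pop[, c("gene", "symbol", "key", "mean_intensity",
                                  "present")])
  str_df <- as.data.frame(stroma[, c("gene", "symbol", "key",
                                     "mean_intensity", "present")])
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    for (assignment in 1:2) {
      if (assignment == 1L) {
        pk <- rec$key_a[i]; sk <- rec$key_b[i]
        pr <- rec$role_a[i]; sr <- rec$role_b[i]
      } else {
        pk <- rec$key_b[i]; sk <- rec$key_a[i]
        pr <- rec$role_b[i]; sr <- rec$role_a[i]
      }
      pi <- match(pk, pop_df$key); si <- match(sk, str_df$key)
      if (is.na(pi) || is.na(si)) next
      if (!pop_df$present[pi] || !str_df$present[si]) next
      if (!pk %in% gate_keys) next
      dir <- if (pr == "receptor" && sr == "ligand") {
        "pop_receptor__stroma_ligand"
      } else if (pr == "ligand" && sr == "receptor") {
        "pop_ligand__stroma_receptor"
      } else "adhesion_pair"
      rows[[length(rows) + 1L]] <- data.frame(
        pop_gene = pop_df$gene[pi], stroma_gene = str_df$gene[si],
        pop_intensity = pop_df$mean_intensity[pi],
        stroma_intensity = str_df$mean_intensity[si],
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pop_gene = character(), stroma_gene = character(),
                      pop_intensity = numeric(), stroma_intensity = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("pop_gene", "stroma_gene", "direction")]), ]
  out[order(out$pop_gene, out$stroma_gene, out$direction), , drop = FALSE]
}

# Random matcher instance: profiles with random presence plus a random gate.
random_match_instance <- function(seed, max_genes = 50, max_pairs = 25) {
  set.seed(seed)
  n <- sample(10:max_genes, 1L)
  genes <- as.character(seq(5000, length.out = n))
  syms <- sprintf("R%03d", seq_len(n))
  mk_profile <- function(name) {
    toy_profile(name, genes, intensities = round(stats::runif(n, 0, 2000), 1),
                present = stats::runif(n) < 0.7)
  }
  pop <- mk_profile("rndPop"); stroma <- mk_profile("rndStroma")
  n_pairs <- sample(1:max_pairs, 1L)
  a <- sample(n, n_pairs, replace = TRUE)
  b <- sample(n, n_pairs, replace = TRUE)
  ok <- a != b
  keep <- ok & !duplicated(paste(pmin(a, b), pmax(a, b)))
  a <- a[keep]; b <- b[keep]
  roles <- c("receptor", "ligand", "adhesion", "unknown")
  role_a <- sample(roles, length(a), replace = TRUE)
  role_b <- sample(roles, length(a), replace = TRUE)
  role_b[role_a == "receptor" & role_b == "receptor"] <- "ligand"
  db <- pair_db(tibble::tibble(
    gene_a = genes[a], symbol_a = syms[a], role_a = role_a,
    gene_b = genes[b], symbol_b = syms[b], role_b = role_b))
  gated <- sample(genes, size = stats::rbinom(1L, n, 0.5))
  list(pop = pop, stroma = stroma, db = db,
       gate = explicit_gate(gated), gate_keys = gated)
}

matcher_vs_oracle_identical <- function(inst) {
  got <- match_interactions(inst$gate, inst$pop, inst$stroma, inst$db)
  got_df <- as.data.frame(got[, c("pop_gene", "stroma_gene", "pop_intensity",
                                  "stroma_intensity", "direction")])
  got_df <- got_df[order(got_df$pop_gene, got_df$stroma_gene,
                         got_df$direction), , drop = FALSE]
  ref <- brute_force_match(inst$gate_keys, inst$pop, inst$stroma, inst$db)
  rownames(got_df) <- NULL; rownames(ref) <- NULL
  identical(dim(got_df), dim(ref)) && identical(names(got_df), names(ref)) &&
    isTRUE(all.equal(got_df, ref, check.attributes = FALSE))
}
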