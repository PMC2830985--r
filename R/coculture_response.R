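#' Stromal response genes after co-culture
#'
#' The co-culture differential filter: compares the expression profile of a
#' stroma incubated in contact with hematopoietic cells against the parallel
#' control culture and retains genes that (i) reach an expression level
#' above `min_level` in at least one of the two conditions, (ii) change at
#' least `min_fold`-fold in either direction (linear scale, denominators
#' floored at 1.0) and, (iii) when both profiles carry replicates, pass the
#' two-sample test of [differential_genes()] at `alpha`. With
#' single-replicate profiles the p-value clause is skipped with a notice and
#' the marker value 1.0 is recorded.
#'
#' The level threshold is applied to the *maximum* of the two conditions so
#' that genes induced from near zero - e.g. chemokines switched on by
#' contact with progenitors - are kept.
#'
#' @param cocultured,control [population_profile()]s of the stroma with and
#'   without hematopoietic contact.
#' @param min_level Expression level that must be exceeded (default 100).
#' @param min_fold Minimum linear fold change (default 5).
#' @param alpha Significance threshold for the replicate test (default
#'   0.05).
#' @param test Passed to [differential_genes()] when replicates exist.
#' @return A `de_gene_list` with `direction` coded as `"induced"` /
#'   `"repressed"` in the co-culture.
#' @export
response_genes <- function(cocultured, control, min_level = 100,
                           min_fold = 5, alpha = 0.05,
                           test = c("welch_t", "moderated_t")) {
  test <- match.arg(test)
  stopifnot(inherits(cocultured, "population_profile"),
            inherits(control, "population_profile"),
            is_number(min_level), min_level >= 0,
            is_number(min_fold), min_fold >= 1,
            is_number(alpha), alpha > 0, alpha <= 1)
  keys <- intersect(cocultured$key, control$key)
  a <- profile_lookup(cocultured, keys)
  b <- profile_lookup(control, keys)
  level_ok <- pmax(a, b) > min_level
  af <- pmax(a, 1); bf <- pmax(b, 1)
  fold_ok <- pmax(af / bf, bf / af) >= min_fold
  keep <- level_ok & fold_ok
  p <- rep(1.0, length(keys))
  have_reps <- attr(cocultured, "n_replicates") >= 2L &&
    attr(control, "n_replicates") >= 2L
  if (have_reps) {
    de <- differential_genes(cocultured, control, alpha = 1, test = test)
    dk <- canonical_key(de$gene, de$symbol)
    p <- de$p_value[match(keys, dk)]
    p[is.na(p)] <- 1.0
    keep <- keep & p < alpha
  } else {
    message("single-replicate profile(s): p-value clause of the response ",
            "filter skipped")
  }
  out <- tibble::tibble(
    gene = cocultured$gene[match(keys, cocultured$key)][keep],
    symbol = cocultured$symbol[match(keys, cocultured$key)][keep],
    p_value = p[keep],
    log2_fold_change = log2(af / bf)[keep],
    direction = ifelse(af[keep] >= bf[keep], "induced", "repressed"))
  out <- new_de_gene_list(out, attr(cocultured, "population"),
                          attr(control, "population"), alpha,
                          test = if (have_reps) test else "fold_change")
  attr(out, "min_level") <- min_level
  attr(out, "min_fold") <- min_fold
  out
}

#' Relative qPCR quantification by the 2^ddCt method
#'
#' Computes, for each gene of interest (G.O.I.), the threshold-cycle
#' difference of differences against a reference gene (HPRT by default)
#'
#' \deqn{\Delta\Delta C_T = (C_{T,GOI(control)} - C_{T,ref(control)}) -
#'       (C_{T,GOI(sample)} - C_{T,ref(sample)})}
#'
#' and the fold change \eqn{2^{\Delta\Delta C_T}} of the sample relative to
#' the control. Each G.O.I. cycle value is paired with the reference-gene
#' cycle measured in its own culture (the standard reading of the
#' normalisation). All arguments are vectorised over genes.
#'
#' @param ct_goi_sample,ct_ref_sample Threshold cycles of the gene of
#'   interest and the reference gene in the sample (e.g. co-cultured) cells.
#' @param ct_goi_control,ct_ref_control The same in the control cells.
#' @param gene Gene label(s).
#' @param reference_gene Reference gene label (default `"HPRT"`).
#' @return A `ddct_result` tibble with the input cycles, `ddct` and
#'   `fold_change`. All-equal cycles give exactly fold 1; swapping sample
#'   and control inverts the fold.
#' @export
ddct_fold_change <- function(ct_goi_sample, ct_ref_sample,
                             ct_goi_control, ct_ref_control,
                             gene = "GOI", reference_gene = "HPRT") {
  cts <- list(ct_goi_sample = ct_goi_sample, ct_ref_sample = ct_ref_sample,
              ct_goi_control = ct_goi_control, ct_ref_control = ct_ref_control)
  for (nm in names(cts)) {
    v <- cts[[nm]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stopf("%s must be finite numeric threshold cycles", nm)
    }
  }
  n <- max(lengths(cts))
  ddct <- (ct_goi_control - ct_ref_control) - (ct_goi_sample - ct_ref_sample)
  out <- tibble::tibble(
    gene = rep_len(as.character(gene), n),
    reference_gene = rep_len(as.character(reference_gene), n),
    ct_goi_sample = rep_len(ct_goi_sample, n),
    ct_ref_sample = rep_len(ct_ref_sample, n),
    ct_goi_control = rep_len(ct_goi_control, n),
    ct_ref_control = rep_len(ct_ref_control, n),
    ddct = rep_len(ddct, n),
    fold_change = rep_len(2^ddct, n))
  class(out) <- c("ddct_result", class(out))
  out
}

#' Batch ddCt quantification from a CSV of threshold cycles
#'
#' Reads a comma-separated file with columns `gene`, `ct_goi_sample`,
#' `ct_ref_sample`, `ct_goi_control`, `ct_ref_control` and applies
#' [ddct_fold_change()] row-wise.
#'
#' @param path Path to the CSV file.
#' @param reference_gene Reference gene label (default `"HPRT"`).
#' @return A `ddct_result` tibble.
#' @export
read_ct_table <- function(path, reference_gene = "HPRT") {
  if (!file.exists(path)) stopf("Ct table not found: %s", path)
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  required <- c("gene", "ct_goi_sample", "ct_ref_sample",
                "ct_goi_control", "ct_ref_control")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stopf("Ct table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  ddct_fold_change(x$ct_goi_sample, x$ct_ref_sample,
                   x$ct_goi_control, x$ct_ref_control,
                   gene = x$gene, reference_gene = reference_gene)
}
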