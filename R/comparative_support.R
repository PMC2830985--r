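#' Nominate stromal factors that distinguish a supportive stroma
#'
#' The supportive-versus-non-supportive screen: given expression profiles of
#' a stroma that supports the target population's development (e.g. OP9) and
#' one that does not (e.g. NIH3T3), plus the interaction table matched for
#' the target population, every stroma-side gene of the table is tested for
#' (i) expression in the supportive stroma of at least `min_intensity` and
#' (ii) a supportive/non-supportive linear fold change of at least
#' `min_fold` (the non-supportive intensity is floored at 1.0, so a factor
#' the non-supportive cell does not express at all yields a large finite
#' fold rather than a presence dichotomy). Each nominated factor carries the
#' cognate population-side partners from the table as its receptor evidence.
#'
#' The default thresholds (5-fold, level 100) are deliberately conservative:
#' they capture factors expressed by the supportive stroma at an order of
#' magnitude difference, while a shared cytokine expressed ~2-fold higher is
#' not nominated - the screen finds supportive-stroma-distinguishing
#' factors, not every growth factor in the system.
#'
#' @param supportive,nonsupportive [population_profile()]s of the two
#'   stromal cells.
#' @param target_table An `interaction_table` matched for the target
#'   population against the supportive stroma.
#' @param min_fold Minimum supportive/non-supportive fold change, >= 1.
#' @param min_intensity Minimum supportive-stroma intensity, >= 0.
#' @return A `candidate_factors` tibble ranked by descending fold change
#'   (ties broken by symbol): `rank`, `ligand_gene`, `ligand_symbol`,
#'   `supportive_intensity`, `nonsupportive_intensity`, `fold_change`,
#'   `n_receptors` and list-column `receptors` (tibbles of `gene`, `symbol`,
#'   `intensity` on the target population).
#' @export
nominate_candidates <- function(supportive, nonsupportive, target_table,
                                min_fold = 5, min_intensity = 100) {
  stopifnot(inherits(supportive, "population_profile"),
            inherits(nonsupportive, "population_profile"),
            inherits(target_table, "interaction_table"),
            is_number(min_fold), min_fold >= 1,
            is_number(min_intensity), min_intensity >= 0)
  empty <- tibble::tibble(
    rank = integer(), ligand_gene = character(), ligand_symbol = character(),
    supportive_intensity = numeric(), nonsupportive_intensity = numeric(),
    fold_change = numeric(), n_receptors = integer(), receptors = list())
  if (nrow(target_table) == 0L) {
    warnf("empty target interaction table: no candidates to screen")
    return(new_candidate_factors(empty, supportive, nonsupportive,
                                 min_fold, min_intensity))
  }
  keys <- canonical_key(target_table$stroma_gene, target_table$stroma_symbol)
  idx <- !duplicated(keys)
  genes <- tibble::tibble(key = keys[idx],
                          gene = target_table$stroma_gene[idx],
                          symbol = target_table$stroma_symbol[idx])
  sup <- profile_lookup(supportive, genes$key)
  non <- profile_lookup(nonsupportive, genes$key)
  sup[is.na(sup)] <- 0
  non[is.na(non)] <- 0
  fold <- sup / pmax(non, 1)
  keep <- sup >= min_intensity & fold >= min_fold
  receptors_of <- function(key) {
    hit <- keys == key
    r <- tibble::tibble(gene = target_table$pop_gene[hit],
                        symbol = target_table$pop_symbol[hit],
                        intensity = target_table$pop_intensity[hit])
    r <- r[!duplicated(r$gene), ]
    r[ci_order(r$symbol), ]
  }
  out <- tibble::tibble(
    ligand_gene = genes$gene[keep], ligand_symbol = genes$symbol[keep],
    supportive_intensity = sup[keep], nonsupportive_intensity = non[keep],
    fold_change = fold[keep],
    receptors = lapply(genes$key[keep], receptors_of))
  out$n_receptors <- vapply(out$receptors, nrow, 0L)
  out <- out[out$n_receptors > 0L, ]
  out <- out[order(-out$fold_change, tolower(out$ligand_symbol),
                   method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "ligand_gene", "ligand_symbol",
                 "supportive_intensity", "nonsupportive_intensity",
                 "fold_change", "n_receptors", "receptors")]
  new_candidate_factors(out, supportive, nonsupportive,
                        min_fold, min_intensity)
}

new_candidate_factors <- function(x, supportive, nonsupportive,
                                  min_fold, min_intensity) {
  attr(x, "supportive") <- attr(supportive, "population")
  attr(x, "nonsupportive") <- attr(nonsupportive, "population")
  attr(x, "min_fold") <- min_fold
  attr(x, "min_intensity") <- min_intensity
  class(x) <- c("candidate_factors", class(x))
  x
}

#' Write nominated candidate factors as TSV
#'
#' Receptor evidence is flattened to `symbol(intensity)` entries joined with
#' `";"`.
#'
#' @param x A `candidate_factors` tibble.
#' @param path Output path.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_candidates <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "candidate_factors"))
  body <- x[, setdiff(names(x), "receptors")]
  body$receptors <- vapply(x$receptors, function(r) {
    paste(sprintf("%s(%s)", r$symbol, format(r$intensity, trim = TRUE)),
          collapse = ";")
  }, "")
  write_tsv_with_header(body, path, header_lines)
}

#' @export
print.candidate_factors <- function(x, ...) {
  cat(sprintf(
    "<candidate_factors> %s vs %s (fold >= %s, level >= %s): %d nominated\n",
    attr(x, "supportive") %||% "?", attr(x, "nonsupportive") %||% "?",
    format(attr(x, "min_fold")), format(attr(x, "min_intensity")), nrow(x)))
  NextMethod()
}
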