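#' Default hematopoietic developmental series
#'
#' The ordered population labels used by [classify_pairs()]: long-term stem
#' cells through multipotent and lymphoid-primed progenitors to mature
#' B cells. The lineage is branched in vivo (GMP sits on the myeloid branch);
#' for ubiquity classification it is treated as a flat series, and the
#' transition report is only meaningful along a user-declared linear path.
#'
#' @return Character vector of population labels.
#' @export
hematopoietic_series <- function() {
  c("LT-HSC", "MPP", "LMPP", "CLP", "GMP", "proB", "preB", "matureB")
}

#' Classify matched pairs as ubiquitous or stage-restricted
#'
#' Takes one interaction table per population of a developmental series and
#' records, for every unordered gene pair, the set of populations in which
#' it was detected. A pair is `ubiquitous` when it occurs at every stage of
#' the series and `restricted` otherwise. Pairs are keyed unordered and
#' direction-collapsed: the question is whether the two partners can talk at
#' a stage, not which cell carries the receptor there.
#'
#' @param tables List of `interaction_table`s whose population labels each
#'   occur exactly once in `series`.
#' @param series Ordered population labels (default
#'   [hematopoietic_series()]).
#' @return A `pair_stage_map` tibble with columns `gene_a`, `gene_b`,
#'   `symbol_a`, `symbol_b`, `n_populations`, `populations` (comma-joined in
#'   series order) and `class`.
#' @export
classify_pairs <- function(tables, series = hematopoietic_series()) {
  stopifnot(is.list(tables), length(tables) >= 1L, is.character(series))
  labels <- vapply(tables, function(t) {
    stopifnot(inherits(t, "interaction_table"))
    as.character(attr(t, "population"))
  }, "")
  bad <- setdiff(labels, series)
  if (length(bad)) {
    stopf("table population label(s) not in series: %s",
          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(labels)) {
    stopf("duplicated population label in tables: %s",
          labels[duplicated(labels)][1L])
  }
  per <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    ka <- canonical_key(t$pop_gene, t$pop_symbol)
    kb <- canonical_key(t$stroma_gene, t$stroma_symbol)
    flip <- ka > kb
    tibble::tibble(
      gene_a = ifelse(flip, t$stroma_gene, t$pop_gene),
      gene_b = ifelse(flip, t$pop_gene, t$stroma_gene),
      symbol_a = ifelse(flip, t$stroma_symbol, t$pop_symbol),
      symbol_b = ifelse(flip, t$pop_symbol, t$stroma_symbol),
      population = labels[i])
  })
  all <- do.call(rbind, per)
  all <- all[!duplicated(all[, c("gene_a", "gene_b", "population")]), ]
  key <- paste(all$gene_a, all$gene_b, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  rows <- lapply(groups, function(idx) {
    pops <- series[series %in% all$population[idx]]
    first <- idx[1L]
    tibble::tibble(
      gene_a = all$gene_a[first], gene_b = all$gene_b[first],
      symbol_a = all$symbol_a[first], symbol_b = all$symbol_b[first],
      n_populations = length(pops),
      populations = paste(pops, collapse = ","),
      class = if (setequal(pops, series)) "ubiquitous" else "restricted")
  })
  out <- do.call(rbind, rows)
  out <- out[ci_order(out$symbol_a, out$symbol_b), ]
  attr(out, "series") <- series
  class(out) <- c("pair_stage_map", class(out))
  out
}

#' Gains and losses of interaction pairs along a series
#'
#' For each adjacent pair of populations in the map's series, lists the
#' interaction pairs gained and lost at that transition. The bookkeeping is
#' conservative: `n_gained - n_lost` always equals the difference in pair
#' counts between the two stages.
#'
#' @param map A `pair_stage_map` from [classify_pairs()] whose series has
#'   length >= 2 (use a linear path; transitions across lineage branches are
#'   only as meaningful as the declared order).
#' @return A tibble with columns `from`, `to`, `n_gained`, `n_lost` and
#'   list-columns `gained`/`lost` of `symbol_a~symbol_b` pair labels.
#' @export
stage_transition_report <- function(map) {
  stopifnot(inherits(map, "pair_stage_map"))
  series <- attr(map, "series")
  if (length(series) < 2L) stopf("transition report needs a series of >= 2 stages")
  pair_label <- paste(map$symbol_a, map$symbol_b, sep = "~")
  pops <- strsplit(map$populations, ",", fixed = TRUE)
  members <- lapply(series, function(s) {
    sort(pair_label[vapply(pops, function(p) s %in% p, NA)])
  })
  names(members) <- series
  out <- lapply(seq_len(length(series) - 1L), function(i) {
    a <- members[[i]]; b <- members[[i + 1L]]
    tibble::tibble(
      from = series[i], to = series[i + 1L],
      n_gained = length(setdiff(b, a)), n_lost = length(setdiff(a, b)),
      gained = list(setdiff(b, a)), lost = list(setdiff(a, b)))
  })
  do.call(rbind, out)
}

#' Write a pair stage map as TSV
#' @param map A `pair_stage_map`.
#' @param path Output path.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_stage_map <- function(map, path, header_lines = character()) {
  stopifnot(inherits(map, "pair_stage_map"))
  body <- map[, c("gene_a", "gene_b", "symbol_a", "symbol_b",
                  "n_populations", "populations", "class")]
  write_tsv_with_header(
    body, path,
    c(header_lines,
      sprintf("# series: %s", paste(attr(map, "series"), collapse = ","))))
}

#' @export
print.pair_stage_map <- function(x, ...) {
  cat(sprintf("<pair_stage_map> %d pair(s) over series %s (%d ubiquitous)\n",
              nrow(x), paste(attr(x, "series"), collapse = " > "),
              sum(x$class == "ubiquitous")))
  NextMethod()
}
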