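#' Match a gated population against a stromal profile
#'
#' The core screen: enumerates every database pair that connects the two
#' cell populations. A row is emitted for a pair and an assignment of its
#' partners to sides when the population-side gene (i) passed the
#' differential gate and (ii) carries a presence call in the population
#' profile, while the stroma-side gene (iii) is present in the stromal
#' profile. Both assignments of the partners to the two sides are tested, so
#' a ligand can surface on either cell (two-way communication). The stromal
#' side is taken as-is (presence only, no gate), mirroring a screen in which
#' per-population differential gene lists are matched against the full
#' stromal expression state.
#'
#' The `direction` of a row is derived from the pair's role annotations
#' (`pop_receptor__stroma_ligand`, `pop_ligand__stroma_receptor`) and falls
#' back to `adhesion_pair` when roles do not identify a receptor-ligand
#' orientation. Pairs that match under both assignments (autocrine
#' candidates: both partners expressed on both sides) are emitted twice and
#' flagged `autocrine = TRUE` rather than suppressed - excluding factors the
#' population makes for itself is the gate's job, not the matcher's.
#'
#' @param gate A `de_gene_list` restricting the population side, or `NULL`
#'   for presence-only matching (every present population gene passes).
#' @param pop,stroma [population_profile()]s.
#' @param db A [pair_db()].
#' @return An `interaction_table`: a tibble with columns `pop_gene`,
#'   `pop_symbol`, `pop_intensity`, `stroma_gene`, `stroma_symbol`,
#'   `stroma_intensity`, `direction`, `autocrine`, rows unique on
#'   (`pop_gene`, `stroma_gene`, `direction`) and deterministically ordered
#'   by stroma symbol then population symbol.
#' @seealso [annotate_comparators()], [write_interaction_table()]
#' @export
match_interactions <- function(gate, pop, stroma, db) {
  stopifnot(inherits(pop, "population_profile"),
            inherits(stroma, "population_profile"),
            inherits(db, "pair_db"))
  if (!is.null(gate) && !inherits(gate, "de_gene_list")) {
    stopf("'gate' must be a de_gene_list or NULL")
  }
  rec <- db$records
  if (nrow(rec) == 0L) {
    warnf("empty pair database: no interactions can be matched")
  }
  if (is.null(gate)) {
    gated <- pop$key[pop$present]
  } else {
    gkeys <- canonical_key(gate$gene, gate$symbol)
    orphan <- setdiff(gkeys, pop$key)
    if (length(orphan)) {
      message(sprintf(
        "%d gated gene(s) missing from population profile '%s'; skipped: %s",
        length(orphan), attr(pop, "population"),
        paste(utils::head(orphan, 5L), collapse = ", ")))
    }
    gated <- intersect(gkeys, pop$key)
  }
  pop_ok <- pop$key[pop$present & pop$key %in% gated]
  str_ok <- stroma$key[stroma$present]

  emit <- function(pop_key, str_key, pop_sym_db, str_sym_db,
                   pop_role, str_role) {
    ok <- pop_key %in% pop_ok & str_key %in% str_ok
    tibble::tibble(
      pop_key = pop_key[ok], stroma_key = str_key[ok],
      pop_symbol_db = pop_sym_db[ok], stroma_symbol_db = str_sym_db[ok],
      pop_role = pop_role[ok], stroma_role = str_role[ok],
      pass = which(ok))
  }
  fwd <- emit(rec$key_a, rec$key_b, rec$symbol_a, rec$symbol_b,
              rec$role_a, rec$role_b)
  rev <- emit(rec$key_b, rec$key_a, rec$symbol_b, rec$symbol_a,
              rec$role_b, rec$role_a)
  both <- intersect(fwd$pass, rev$pass)
  fwd$autocrine <- fwd$pass %in% both
  rev$autocrine <- rev$pass %in% both
  rows <- rbind(fwd, rev)

  sym_or <- function(profile, keys, fallback) {
    s <- profile_lookup(profile, keys, "symbol")
    ifelse(is.na(s) | !nzchar(s), fallback, s)
  }
  out <- tibble::tibble(
    pop_gene = profile_lookup(pop, rows$pop_key, "gene"),
    pop_symbol = sym_or(pop, rows$pop_key, rows$pop_symbol_db),
    pop_intensity = profile_lookup(pop, rows$pop_key),
    stroma_gene = profile_lookup(stroma, rows$stroma_key, "gene"),
    stroma_symbol = sym_or(stroma, rows$stroma_key, rows$stroma_symbol_db),
    stroma_intensity = profile_lookup(stroma, rows$stroma_key),
    direction = pair_direction(rows$pop_role, rows$stroma_role),
    autocrine = rows$autocrine)
  out <- out[!duplicated(out[, c("pop_gene", "stroma_gene", "direction")]), ]
  new_interaction_table(out, attr(pop, "population"),
                        attr(stroma, "population"))
}

pair_direction <- function(pop_role, stroma_role) {
  out <- rep("adhesion_pair", length(pop_role))
  out[pop_role == "receptor" & stroma_role == "ligand"] <-
    "pop_receptor__stroma_ligand"
  out[pop_role == "ligand" & stroma_role == "receptor"] <-
    "pop_ligand__stroma_receptor"
  out
}

new_interaction_table <- function(x, population, stroma,
                                  comparators = character()) {
  x <- x[ci_order(x$stroma_symbol, x$pop_symbol, x$direction), ]
  attr(x, "population") <- population
  attr(x, "stroma") <- stroma
  attr(x, "comparators") <- comparators
  class(x) <- c("interaction_table", setdiff(class(x), "interaction_table"))
  x
}

#' Attach comparator-cell intensities to an interaction table
#'
#' Adds, for each comparator profile, one column holding the comparator's
#' mean intensity of the row's stroma-side gene (e.g. the same gene measured
#' in NIH3T3 fibroblasts or MC3T3 osteoblasts). Genes absent from a
#' comparator are recorded as `NA`; the row set is never changed.
#'
#' @param table An `interaction_table`.
#' @param comparators A list of [population_profile()]s with unique
#'   population labels (used as column names).
#' @return The table with one extra numeric column per comparator.
#' @export
annotate_comparators <- function(table, comparators) {
  stopifnot(inherits(table, "interaction_table"))
  if (inherits(comparators, "population_profile")) {
    comparators <- list(comparators)
  }
  labels <- vapply(comparators, attr, "", "population")
  if (anyDuplicated(labels)) {
    stopf("comparator labels must be unique (duplicated: %s)",
          labels[duplicated(labels)][1L])
  }
  keys <- canonical_key(table$stroma_gene, table$stroma_symbol)
  for (i in seq_along(comparators)) {
    table[[labels[i]]] <- profile_lookup(comparators[[i]], keys)
  }
  attr(table, "comparators") <- union(attr(table, "comparators"), labels)
  table
}

#' Write an interaction table as TSV
#'
#' The file starts with `# population:` and `# stroma:` comment lines so the
#' labels survive a round-trip through [read_interaction_table()]; identical
#' inputs always produce byte-identical files.
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @param header_lines Additional `#` comment lines placed above the labels.
#' @export
write_interaction_table <- function(table, path, header_lines = character()) {
  stopifnot(inherits(table, "interaction_table"))
  hdr <- c(header_lines,
           sprintf("# population: %s", attr(table, "population")),
           sprintf("# stroma: %s", attr(table, "stroma")))
  body <- table
  class(body) <- setdiff(class(body), "interaction_table")
  write_tsv_with_header(body, path, hdr)
}

#' Read an interaction table written by [write_interaction_table()]
#' @param path Path to the TSV file.
#' @return An `interaction_table`; columns after `autocrine` are treated as
#'   comparator intensities.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stopf("interaction table not found: %s", path)
  fields <- read_header_fields(path)
  x <- read_tsv_quiet(path, col_types = readr::cols(
    pop_gene = "c", pop_symbol = "c", pop_intensity = "d",
    stroma_gene = "c", stroma_symbol = "c", stroma_intensity = "d",
    direction = "c", autocrine = "l", .default = "d"))
  required <- c("pop_gene", "pop_symbol", "pop_intensity", "stroma_gene",
                "stroma_symbol", "stroma_intensity", "direction", "autocrine")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stopf("interaction table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  new_interaction_table(tibble::as_tibble(x),
                        unname(fields["population"]) %|NA|% NA_character_,
                        unname(fields["stroma"]) %|NA|% NA_character_,
                        comparators = setdiff(names(x), required))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %s vs stroma %s: %d matched pair row(s)\n",
              attr(x, "population") %||% "?", attr(x, "stroma") %||% "?",
              nrow(x)))
  NextMethod()
}
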