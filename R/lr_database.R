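#' Receptor-ligand pair databases
#'
#' A `pair_db` holds a curated table of receptor-ligand (or adhesion-partner)
#' gene pairs, the reference against which expression profiles of two cell
#' populations are matched. Pairs are stored in file order as written, but
#' are deduplicated on the *unordered* pair of canonical gene keys: the same
#' two partners listed in either orientation count as one pair. Direction
#' semantics (which side carries the receptor) are applied at match time from
#' the `role_a`/`role_b` annotations, not at storage time.
#'
#' The canonical key for a gene is its numeric locus-link/Entrez identifier
#' when given; rows without one fall back to the case-folded gene symbol
#' (reported via a message, since symbol keys are weaker identifiers).
#'
#' @param records A data frame with columns `gene_a`, `gene_b` (identifiers),
#'   and optionally `pair_id`, `symbol_a`, `symbol_b`, `role_a`, `role_b`
#'   (one of `"receptor"`, `"ligand"`, `"adhesion"`, `"unknown"`) and
#'   `source`.
#' @return A `pair_db` object: the validated records plus a gene-key index.
#' @seealso [read_pair_table()], [pairs_for_gene()]
#' @export
pair_db <- function(records) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  defaults <- list(pair_id = sprintf("pair%04d", seq_len(max(n, 0L))),
                   symbol_a = "", symbol_b = "",
                   role_a = "unknown", role_b = "unknown", source = "")
  for (col in names(defaults)) {
    if (!col %in% names(records)) records[[col]] <- defaults[[col]][seq_len(n)]
    records[[col]] <- as.character(records[[col]])
    records[[col]][is.na(records[[col]])] <- defaults[[col]][1L]
  }
  for (col in c("gene_a", "gene_b")) {
    if (!col %in% names(records)) records[[col]] <- ""
    records[[col]] <- as.character(records[[col]])
    records[[col]][is.na(records[[col]])] <- ""
  }
  records <- records[, c("pair_id", "gene_a", "symbol_a", "role_a",
                         "gene_b", "symbol_b", "role_b", "source")]
  validate_pair_db(new_pair_db(records))
}

new_pair_db <- function(records) {
  records$key_a <- canonical_key(records$gene_a, records$symbol_a)
  records$key_b <- canonical_key(records$gene_b, records$symbol_b)
  structure(list(records = records, index = build_pair_index(records)),
            class = "pair_db")
}

build_pair_index <- function(records) {
  keys <- c(records$key_a, records$key_b)
  rows <- rep(seq_len(nrow(records)), 2L)
  split(rows, keys)
}

unordered_pair_key <- function(key_a, key_b) {
  paste(pmin(key_a, key_b), pmax(key_a, key_b), sep = "\r")
}

#' Validate a pair database
#'
#' Checks every record (non-empty, distinct partners; consistent role
#' annotations), collapses duplicate unordered pairs with a warning, and
#' rebuilds the gene index. Validation is idempotent: a validated database
#' passes through unchanged.
#'
#' @param db A `pair_db`.
#' @param rows Optional original file line numbers used in error messages.
#' @return The validated `pair_db`.
#' @export
validate_pair_db <- function(db, rows = NULL) {
  stopifnot(inherits(db, "pair_db"))
  rec <- db$records
  rows <- rows %||% seq_len(nrow(rec))
  roles <- c("receptor", "ligand", "adhesion", "unknown")
  for (side in c("a", "b")) {
    role <- tolower(rec[[paste0("role_", side)]])
    bad <- !role %in% roles
    if (any(bad)) {
      stopf("invalid role '%s' in row %d (allowed: %s)",
            role[which(bad)[1]], rows[which(bad)[1]],
            paste(roles, collapse = ", "))
    }
    rec[[paste0("role_", side)]] <- role
  }
  empty <- !nzchar(rec$key_a) | !nzchar(rec$key_b)
  if (any(empty)) {
    stopf("row %d: empty gene identifier (no gene id and no symbol)",
          rows[which(empty)[1]])
  }
  selfpair <- rec$key_a == rec$key_b
  if (any(selfpair)) {
    stopf("row %d: gene_a and gene_b are the same gene ('%s')",
          rows[which(selfpair)[1]], rec$key_a[which(selfpair)[1]])
  }
  both_receptor <- rec$role_a == "receptor" & rec$role_b == "receptor"
  if (any(both_receptor)) {
    stopf("row %d: both partners annotated as receptors",
          rows[which(both_receptor)[1]])
  }
  dup <- duplicated(unordered_pair_key(rec$key_a, rec$key_b))
  if (any(dup)) {
    warnf("collapsing %d duplicate unordered pair(s) (first kept): %s",
          sum(dup),
          paste(utils::head(paste(rec$symbol_a[dup], rec$symbol_b[dup],
                                  sep = "-"), 5L), collapse = ", "))
    rec <- rec[!dup, ]
  }
  structure(list(records = rec, index = build_pair_index(rec)),
            class = "pair_db")
}

#' Read a receptor-ligand pair table
#'
#' Reads a tab-separated pair table (UTF-8, header row, `#` comment lines
#' ignored) into a validated [pair_db()]. At minimum the file must name the
#' two gene-identifier columns (`gene_a`/`gene_b`, or `symbol_a`/`symbol_b`
#' as fallback keys); `pair_id`, roles and `source` are optional.
#'
#' @param path Path to the TSV file.
#' @return A `pair_db`.
#' @examples
#' pairs <- read_pair_table(
#'   system.file("extdata", "pairs_prob_table.tsv", package = "stromatch"))
#' pairs
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stopf("pair table not found: %s", path)
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  has <- function(col) col %in% names(x)
  for (side in c("a", "b")) {
    if (!has(paste0("gene_", side)) && !has(paste0("symbol_", side))) {
      stopf("pair table %s is missing required column 'gene_%s' (or 'symbol_%s')",
            path, side, side)
    }
  }
  if (nrow(x) == 0L) {
    return(pair_db(tibble::tibble(gene_a = character(), gene_b = character())))
  }
  downgraded <- 0L
  for (side in c("a", "b")) {
    g <- paste0("gene_", side)
    s <- paste0("symbol_", side)
    if (!has(g)) x[[g]] <- ""
    if (!has(s)) x[[s]] <- ""
    miss <- !nzchar(trimws(x[[g]] %|NA|% "")) & nzchar(trimws(x[[s]] %|NA|% ""))
    downgraded <- downgraded + sum(miss)
  }
  if (downgraded > 0L) {
    message(sprintf(
      "%d gene field(s) in %s lack an identifier; using case-folded symbol as key",
      downgraded, basename(path)))
  }
  db <- pair_db(x)
  db
}

`%|NA|%` <- function(x, repl) { x[is.na(x)] <- repl; x }

#' Write a pair database back to TSV
#'
#' The written file round-trips through [read_pair_table()] with identical
#' records.
#'
#' @param db A `pair_db`.
#' @param path Output path.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_pair_table <- function(db, path, header_lines = character()) {
  stopifnot(inherits(db, "pair_db"))
  out <- db$records[, c("pair_id", "gene_a", "symbol_a", "role_a",
                        "gene_b", "symbol_b", "role_b", "source")]
  write_tsv_with_header(out, path, header_lines)
}

#' Look up the pairs containing a gene
#'
#' Returns every record whose canonical key on either side equals the query.
#' A query that is not a canonical key is also tried against the stored gene
#' symbols (case-insensitively), so databases keyed on locus-link identifiers
#' can still be queried by symbol. An unknown gene yields an empty result,
#' never an error.
#'
#' @param db A `pair_db`.
#' @param gene Gene identifier or symbol.
#' @return A tibble of matching pair records (possibly empty).
#' @export
pairs_for_gene <- function(db, gene) {
  stopifnot(inherits(db, "pair_db"), length(gene) == 1L)
  key <- trimws(as.character(gene))
  rows <- db$index[[key]]
  if (is.null(rows)) {
    # symbol fallback: resolve the query to canonical keys via symbols
    rec <- db$records
    hit <- tolower(key) == tolower(rec$symbol_a) |
           tolower(key) == tolower(rec$symbol_b) |
           tolower(key) == rec$key_a | tolower(key) == rec$key_b
    rows <- which(hit)
  }
  db$records[sort(unique(rows)),
             c("pair_id", "gene_a", "symbol_a", "role_a",
               "gene_b", "symbol_b", "role_b", "source")]
}

#' @export
print.pair_db <- function(x, ...) {
  cat(sprintf("<pair_db> %d unique unordered pairs, %d indexed genes\n",
              nrow(x$records), length(x$index)))
  if (nrow(x$records)) {
    print(utils::head(x$records[, c("pair_id", "symbol_a", "role_a",
                                    "symbol_b", "role_b")], 5L))
    if (nrow(x$records) > 5L) cat("...\n")
  }
  invisible(x)
}

#' @export
length.pair_db <- function(x) nrow(x$records)

#' @export
as.data.frame.pair_db <- function(x, ...) as.data.frame(x$records, ...)
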