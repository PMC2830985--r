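# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
#' Canonical gene key: the numeric locus-link/Entrez identifier when present,
#' otherwise the case-folded gene symbol. Keys are plain strings so profiles,
#' gates and the pair database can be joined without annotation lookups.
canonical_key <- function(gene, symbol) {
  gene <- trimws(as.character(gene %||% ""))
  symbol <- trimws(as.character(symbol %||% ""))
  gene[is.na(gene)] <- ""
  symbol[is.na(symbol)] <- ""
  ifelse(nzchar(gene), gene, tolower(symbol))
}

# Locale-independent, case-insensitive ordering used everywhere output order
# matters, so results are diffable across machines.
ci_order <- function(...) {
  cols <- lapply(list(...), function(x) if (is.character(x)) tolower(x) else x)
  do.call(order, c(cols, list(method = "radix")))
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA", ...)
}

# Writes an optional "# ..." comment header followed by a TSV body.
write_tsv_with_header <- function(x, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(header_lines, con, sep = "\n")
  }
  readr::write_tsv(x, con, na = "NA", progress = FALSE)
  invisible(path)
}

# "# key: value" comment lines at the top of a file -> named character vector.
read_header_fields <- function(path, n_max = 50) {
  lines <- readLines(path, n = n_max)
  lines <- lines[startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^#\\s*([^:]+):\\s*(.*)$", lines))
  keep <- vapply(m, length, 0L) == 3L
  out <- vapply(m[keep], `[[`, "", 3L)
  names(out) <- trimws(vapply(m[keep], `[[`, "", 2L))
  out
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
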