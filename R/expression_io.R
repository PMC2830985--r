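#' Read a probe-level expression table
#'
#' Parses the tab-separated expression format consumed by the matcher: one
#' row per probe set with columns `probe_set`, `accession`, `description`,
#' `gene`, `symbol`, then `intensity_1..intensity_k` (linear-scale,
#' RMA-normalised values, one per replicate array) and aligned
#' `call_1..call_k` detection calls (`P`/`M`/`A`, case-insensitive).
#' Lines starting with `#` are ignored.
#'
#' Intensities must be finite, non-negative numbers; the intensity and call
#' column groups must have the same width. Violations are reported with the
#' file line number of the offending row.
#'
#' @param path Path to the TSV file.
#' @return A `probe_records` tibble with list-columns `intensities` and
#'   `calls`, one element per replicate array.
#' @seealso [aggregate_probesets()]
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stopf("expression table not found: %s", path)
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  required <- c("probe_set", "accession", "description", "gene", "symbol")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stopf("expression table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  int_cols <- grep("^intensity_[0-9]+$", names(x), value = TRUE)
  call_cols <- grep("^call_[0-9]+$", names(x), value = TRUE)
  if (length(int_cols) == 0L) {
    stopf("expression table %s is missing required column 'intensity_1'", path)
  }
  if (length(int_cols) != length(call_cols)) {
    stopf("expression table %s has %d intensity column(s) but %d call column(s)",
          path, length(int_cols), length(call_cols))
  }
  int_cols <- int_cols[ci_order(as.integer(sub("intensity_", "", int_cols)))]
  call_cols <- call_cols[ci_order(as.integer(sub("call_", "", call_cols)))]
  # map tibble rows back to physical line numbers for error reporting
  raw <- readLines(path)
  data_lines <- which(!startsWith(raw, "#") & nzchar(trimws(raw)))
  data_lines <- data_lines[-1L]  # drop the header row

  if (nrow(x) == 0L) {
    return(new_probe_records(x[, required], list(), list(), 0L))
  }

  ints <- matrix(NA_real_, nrow(x), length(int_cols))
  for (j in seq_along(int_cols)) {
    v <- suppressWarnings(as.numeric(x[[int_cols[j]]]))
    bad <- is.na(v) | !is.finite(v) | v < 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stopf("%s line %d: invalid intensity '%s' in column %s",
            basename(path), data_lines[i], x[[int_cols[j]]][i], int_cols[j])
    }
    ints[, j] <- v
  }
  calls <- matrix(NA_character_, nrow(x), length(call_cols))
  for (j in seq_along(call_cols)) {
    v <- toupper(trimws(x[[call_cols[j]]]))
    bad <- is.na(v) | !v %in% c("P", "M", "A")
    if (any(bad)) {
      i <- which(bad)[1L]
      stopf("%s line %d: invalid call token '%s' in column %s (expected P, M or A)",
            basename(path), data_lines[i], x[[call_cols[j]]][i], call_cols[j])
    }
    calls[, j] <- v
  }
  new_probe_records(x[, required],
                    lapply(seq_len(nrow(x)), function(i) ints[i, ]),
                    lapply(seq_len(nrow(x)), function(i) calls[i, ]),
                    length(int_cols))
}

new_probe_records <- function(meta, intensities, calls, n_replicates) {
  out <- tibble::as_tibble(meta)
  out$intensities <- intensities
  out$calls <- calls
  attr(out, "n_replicates") <- as.integer(n_replicates)
  class(out) <- c("probe_records", class(out))
  out
}

#' Aggregate probe sets to a gene-level population profile
#'
#' Collapses probe-level records to one entry per gene. Under the default
#' `max_mean` rule the probe set with the largest mean intensity represents
#' the gene (ties broken by probe set name, so the result does not depend on
#' input row order); under `mean_of_means` the gene value is the mean of the
#' probe-set means. A gene is flagged present when a `"P"` call is seen in at
#' least one replicate (`present_rule = "any"`, the permissive reading of
#' presence-in-at-least-one) or in every replicate (`"all"`). Marginal `"M"`
#' calls count as absent unless `marginal_as_present = TRUE`.
#'
#' @param records A `probe_records` tibble from [read_expression_table()].
#' @param name Population label (e.g. `"proB"`, `"OP9"`).
#' @param method `"max_mean"` (default) or `"mean_of_means"`.
#' @param present_rule `"any"` (default) or `"all"`.
#' @param marginal_as_present Treat `"M"` calls as detections. Default FALSE.
#' @return A [population_profile()].
#' @export
aggregate_probesets <- function(records, name,
                                method = c("max_mean", "mean_of_means"),
                                present_rule = c("any", "all"),
                                marginal_as_present = FALSE) {
  method <- match.arg(method)
  present_rule <- match.arg(present_rule)
  stopifnot(inherits(records, "probe_records"))
  if (nrow(records) == 0L) {
    return(population_profile(name, genes = character(), symbols = character(),
                              intensities = matrix(numeric(), 0, 1)))
  }
  key <- canonical_key(records$gene, records$symbol)
  detected <- c("P", if (marginal_as_present) "M")
  groups <- split(seq_len(nrow(records)), key)
  # deterministic gene order independent of input row permutation
  groups <- groups[ci_order(names(groups))]
  rows <- lapply(groups, function(idx) {
    means <- vapply(records$intensities[idx], mean, 0)
    if (length(idx) > 1L) {
      ord <- order(-means, records$probe_set[idx], method = "radix")
      idx <- idx[ord]; means <- means[ord]
    }
    if (identical(method, "max_mean")) {
      reps <- records$intensities[[idx[1L]]]
      calls <- records$calls[[idx[1L]]]
    } else {
      mat <- do.call(rbind, records$intensities[idx])
      reps <- colMeans(mat)
      callmat <- do.call(rbind, records$calls[idx])
      calls <- apply(callmat, 2, function(col) {
        if (any(col %in% detected)) "P" else if (any(col == "M")) "M" else "A"
      })
    }
    hit <- calls %in% detected
    present <- if (identical(present_rule, "any")) any(hit) else all(hit)
    list(gene = records$gene[[idx[1L]]], symbol = records$symbol[[idx[1L]]],
         reps = reps, calls = calls, present = present)
  })
  population_profile(
    name,
    genes = vapply(rows, `[[`, "", "gene"),
    symbols = vapply(rows, `[[`, "", "symbol"),
    intensities = do.call(rbind, lapply(rows, `[[`, "reps")),
    calls = do.call(rbind, lapply(rows, `[[`, "calls")),
    present = vapply(rows, `[[`, NA, "present"))
}

#' Gene-level expression state of one cell population
#'
#' Constructs a `population_profile`: per gene, the replicate intensities
#' (linear scale), their arithmetic mean, the detection calls and a single
#' presence flag. This is the container consumed by the differential gates
#' and the interaction matcher.
#'
#' @param name Population label.
#' @param genes Character vector of gene identifiers (canonical keys are
#'   derived with symbol fallback).
#' @param symbols Gene symbols (defaults to `genes`).
#' @param intensities Numeric matrix, genes x replicates (a vector is taken
#'   as a single replicate).
#' @param calls Optional character matrix of `P`/`M`/`A` calls, same shape.
#' @param present Optional logical vector; derived from `calls` (`P` in at
#'   least one replicate) when omitted, `TRUE` when neither is given.
#' @return A `population_profile` tibble with columns `gene`, `symbol`,
#'   `mean_intensity`, `present` and list-columns `replicates`, `calls`.
#' @export
population_profile <- function(name, genes, symbols = genes, intensities,
                               calls = NULL, present = NULL) {
  if (is.vector(intensities)) intensities <- matrix(intensities, ncol = 1L)
  dimnames(intensities) <- NULL
  genes <- unname(as.character(genes))
  symbols <- unname(as.character(symbols))
  if (!is.null(present)) present <- unname(present)
  if (!is.null(calls)) dimnames(calls) <- NULL
  stopifnot(nrow(intensities) == length(genes),
            length(symbols) == length(genes))
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stopf("profile '%s': intensities must be finite and >= 0", name)
  }
  key <- canonical_key(genes, symbols)
  if (anyDuplicated(key)) {
    stopf("profile '%s': duplicate gene key '%s' after aggregation",
          name, key[duplicated(key)][1L])
  }
  if (is.null(calls)) {
    calls <- matrix("P", nrow(intensities), ncol(intensities))
  }
  if (is.null(present)) {
    present <- apply(calls == "P", 1L, any)
  }
  out <- tibble::tibble(
    gene = genes, symbol = symbols, key = key,
    mean_intensity = if (nrow(intensities)) rowMeans(intensities) else numeric(),
    present = as.logical(present),
    replicates = lapply(seq_len(nrow(intensities)), function(i) intensities[i, ]),
    calls = lapply(seq_len(nrow(intensities)), function(i) calls[i, ]))
  attr(out, "population") <- as.character(name)
  attr(out, "n_replicates") <- ncol(intensities)
  class(out) <- c("population_profile", class(out))
  out
}

#' Read, aggregate and label an expression table in one step
#'
#' @inheritParams read_expression_table
#' @inheritParams aggregate_probesets
#' @return A [population_profile()].
#' @export
read_population_profile <- function(path, name, ...) {
  aggregate_probesets(read_expression_table(path), name = name, ...)
}

#' Write a gene-level profile in the probe-level expression format
#'
#' Each gene becomes one synthetic probe row, so the file can be re-read with
#' [read_expression_table()] and re-aggregated to the identical profile.
#'
#' @param profile A `population_profile`.
#' @param path Output path.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_expression_table <- function(profile, path, header_lines = character()) {
  stopifnot(inherits(profile, "population_profile"))
  k <- attr(profile, "n_replicates")
  out <- tibble::tibble(
    probe_set = paste0(tolower(profile$symbol), "_at"),
    accession = paste0("SYN", profile$gene),
    description = profile$symbol,
    gene = profile$gene,
    symbol = profile$symbol)
  for (j in seq_len(k)) {
    out[[paste0("intensity_", j)]] <-
      vapply(profile$replicates, `[[`, 0, j)
    out[[paste0("call_", j)]] <- vapply(profile$calls, `[[`, "", j)
  }
  write_tsv_with_header(out, path, header_lines)
}

profile_lookup <- function(profile, keys, field = "mean_intensity") {
  profile[[field]][match(keys, profile$key)]
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("<population_profile> %s: %d genes, %d replicate(s), %d present\n",
              attr(x, "population"), nrow(x), attr(x, "n_replicates"),
              sum(x$present)))
  NextMethod()
}
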