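#' Differentially expressed genes between a population and its reference
#'
#' Computes, for every gene shared by the two profiles, a two-sample test on
#' `log2(intensity + 1)` and retains genes with `p < alpha`. This is the gate
#' that feeds the interaction matcher: each hematopoietic population is
#' compared against the stromal reference at `alpha = 0.01` by default, and
#' no multiple-testing correction is applied unless requested (the screen is
#' a raw p-value gate; a Benjamini-Hochberg switch is provided).
#'
#' `test = "welch_t"` is the transparent default (unequal-variance t with a
#' `1e-8` variance floor). `test = "moderated_t"` shrinks the per-gene pooled
#' variances toward a common prior by empirical Bayes before forming the t
#' statistic, which stabilises inference at small replicate counts; the prior
#' is estimated by moment matching on the log sample variances (see
#' [squeeze_variances()]).
#'
#' @param pop,ref [population_profile()]s with >= 2 replicates each.
#' @param alpha Significance threshold on the (possibly adjusted) p-value.
#' @param test `"welch_t"` or `"moderated_t"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `de_gene_list` tibble with columns `gene`, `symbol`, `p_value`,
#'   `log2_fold_change` (population minus reference, log2 scale) and
#'   `direction` (`"up_in_population"`/`"up_in_reference"`), carrying the
#'   population/reference labels and `alpha` as attributes.
#' @seealso [fold_change_gate()] for the replicate-free fallback.
#' @export
differential_genes <- function(pop, ref, alpha = 0.01,
                               test = c("welch_t", "moderated_t"),
                               adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(inherits(pop, "population_profile"),
            inherits(ref, "population_profile"),
            is_number(alpha), alpha > 0, alpha <= 1)
  n1 <- attr(pop, "n_replicates")
  n2 <- attr(ref, "n_replicates")
  if (n1 < 2L || n2 < 2L) {
    stopf(paste("'%s' test needs >= 2 replicates per profile (have %d and %d);",
                "use fold_change_gate() for single-replicate tables"),
          test, n1, n2)
  }
  keys <- intersect(pop$key, ref$key)
  if (length(keys) == 0L) {
    return(new_de_gene_list(tibble::tibble(
      gene = character(), symbol = character(), p_value = numeric(),
      log2_fold_change = numeric(), direction = character()),
      attr(pop, "population"), attr(ref, "population"), alpha, test))
  }
  X <- log2(do.call(rbind, pop$replicates[match(keys, pop$key)]) + 1)
  Y <- log2(do.call(rbind, ref$replicates[match(keys, ref$key)]) + 1)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- pmax(apply(X, 1L, stats::var), 1e-8)
  v2 <- pmax(apply(Y, 1L, stats::var), 1e-8)
  if (identical(test, "welch_t")) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    d <- n1 + n2 - 2L
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    sq <- squeeze_variances(s2, df = d)
    tstat <- (m1 - m2) / sqrt(sq$var_post * (1 / n1 + 1 / n2))
    df <- d + sq$df_prior
  }
  p <- 2 * stats::pt(-abs(tstat), df = df)
  if (identical(adjust, "BH")) p <- stats::p.adjust(p, method = "BH")
  lfc <- m1 - m2
  keep <- p < alpha
  out <- tibble::tibble(
    gene = pop$gene[match(keys, pop$key)][keep],
    symbol = pop$symbol[match(keys, pop$key)][keep],
    p_value = p[keep],
    log2_fold_change = lfc[keep],
    direction = ifelse(lfc[keep] > 0, "up_in_population", "up_in_reference"))
  new_de_gene_list(out, attr(pop, "population"), attr(ref, "population"),
                   alpha, test)
}

new_de_gene_list <- function(x, population, reference, alpha, test) {
  x <- x[ci_order(x$symbol, x$gene), ]
  attr(x, "population") <- population
  attr(x, "reference") <- reference
  attr(x, "alpha") <- alpha
  attr(x, "test") <- test
  class(x) <- c("de_gene_list", class(x))
  x
}

#' Empirical-Bayes shrinkage of per-gene variances
#'
#' Models the per-gene sample variances as scaled chi-square draws around a
#' common prior variance `s0^2` with `d0` prior degrees of freedom, estimates
#' `(d0, s0^2)` by moment matching on `log(s^2)`, and returns the posterior
#' (shrunken) variances `(d0*s0^2 + d*s^2) / (d0 + d)`. With an infinite
#' prior df all genes share one variance; with `d0 = 0` nothing is shrunk.
#'
#' @param s2 Per-gene sample variances (pooled across the two groups).
#' @param df Residual degrees of freedom of each `s2`.
#' @return List with `var_post`, `df_prior`, `var_prior`.
#' @export
squeeze_variances <- function(s2, df) {
  stopifnot(is.numeric(s2), all(s2 > 0), is_count(df), df >= 1)
  if (length(s2) < 2L) {
    return(list(var_post = s2, df_prior = 0, var_prior = mean(s2)))
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar <= 0) {
    # observed spread no larger than chi-square sampling noise: infinite
    # prior df, every gene shares the common variance
    var_prior <- exp(mean(e))
    return(list(var_post = rep(var_prior, length(s2)),
                df_prior = Inf, var_prior = var_prior))
  }
  d0 <- 2 * trigamma_inverse(evar)
  var_prior <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(var_post = (d0 * var_prior + df * s2) / (d0 + df),
       df_prior = d0, var_prior = var_prior)
}

# Newton solve of trigamma(y) = x, monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Fold-change-only gate for single-replicate tables
#'
#' Retains genes whose linear-intensity ratio between population and
#' reference, in either direction, is at least `min_fold`. Intensities are
#' floored at `intensity_floor` (default 1.0) before forming ratios, so a
#' zero on one side yields a large but finite fold rather than a division
#' blow-up. `p_value` is recorded as the absent-marker value 1.0. This is the
#' fallback gate when replicate arrays are unavailable, as for profiles
#' transcribed from printed mean intensities.
#'
#' @inheritParams differential_genes
#' @param min_fold Minimum linear fold change, >= 1.
#' @param intensity_floor Denominator/numerator floor, default 1.0.
#' @return A `de_gene_list` (see [differential_genes()]).
#' @export
fold_change_gate <- function(pop, ref, min_fold = 5, intensity_floor = 1) {
  stopifnot(inherits(pop, "population_profile"),
            inherits(ref, "population_profile"),
            is_number(min_fold), min_fold >= 1)
  keys <- intersect(pop$key, ref$key)
  p <- pmax(profile_lookup(pop, keys), intensity_floor)
  r <- pmax(profile_lookup(ref, keys), intensity_floor)
  fold <- pmax(p / r, r / p)
  keep <- fold >= min_fold
  out <- tibble::tibble(
    gene = pop$gene[match(keys, pop$key)][keep],
    symbol = pop$symbol[match(keys, pop$key)][keep],
    p_value = 1.0,
    log2_fold_change = log2(p / r)[keep],
    direction = ifelse(p[keep] >= r[keep], "up_in_population",
                       "up_in_reference"))
  out <- new_de_gene_list(out, attr(pop, "population"),
                          attr(ref, "population"), alpha = NA_real_,
                          test = "fold_change")
  attr(out, "min_fold") <- min_fold
  out
}

#' Write a differential gene list as TSV
#' @param x A `de_gene_list`.
#' @param path Output path.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_de_list <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "de_gene_list"))
  write_tsv_with_header(
    x[, c("gene", "symbol", "p_value", "log2_fold_change", "direction")],
    path, header_lines)
}

#' Read a differential gene list written by [write_de_list()]
#' @param path Path to the TSV file.
#' @param population,reference Optional labels to attach.
#' @export
read_de_list <- function(path, population = NA, reference = NA) {
  x <- read_tsv_quiet(path, col_types = readr::cols(
    gene = "c", symbol = "c", p_value = "d", log2_fold_change = "d",
    direction = "c"))
  new_de_gene_list(tibble::as_tibble(x), population, reference,
                   alpha = NA_real_, test = "imported")
}

#' @export
print.de_gene_list <- function(x, ...) {
  cat(sprintf("<de_gene_list> %s vs %s (%s): %d gene(s) retained\n",
              attr(x, "population"), attr(x, "reference"),
              attr(x, "test"), nrow(x)))
  NextMethod()
}
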