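replicate_profile <- function(name, genes, log2_means, sd, k, seed) {
  set.seed(seed)
  mat <- 2^(matrix(stats::rnorm(length(genes) * k, 0, sd),
                   length(genes), k) + log2_means)
  toy_profile(name, genes, intensities = mat[, 1L], replicates = mat)
}

test_that("identical profiles yield an empty differential list", {
  mat <- matrix(c(10, 20, 30, 40, 50, 60), 2, 3)
  a <- toy_profile("a", c("1", "2"), mat[, 1L], replicates = mat)
  b <- toy_profile("b", c("1", "2"), mat[, 1L], replicates = mat)
  expect_equal(nrow(differential_genes(a, b)), 0L)
})

test_that("welch gate agrees with a per-gene t.test oracle", {
  genes <- as.character(1:120)
  mu <- stats::rnorm(120, 8, 1)
  shift <- c(rep(5, 20), rep(0, 100))
  pop <- replicate_profile("pop", genes, mu + shift, sd = 0.4, k = 3, seed = 11)
  ref <- replicate_profile("ref", genes, mu, sd = 0.4, k = 3, seed = 12)
  de <- differential_genes(pop, ref, alpha = 0.01)

  p_oracle <- vapply(seq_along(genes), function(i) {
    stats::t.test(log2(pop$replicates[[i]] + 1),
                  log2(ref$replicates[[i]] + 1))$p.value
  }, 0)
  expect_setequal(de$gene, genes[p_oracle < 0.01])
  expect_equal(de$p_value, p_oracle[match(de$gene, genes)],
               tolerance = 1e-10)
  # a strongly separated gene (log2 10 vs 15, sd 0.1) must be retained
  g <- replicate_profile("g", "x", 15, 0.1, 3, seed = 3)
  h <- replicate_profile("h", "x", 10, 0.1, 3, seed = 4)
  expect_equal(differential_genes(g, h, alpha = 0.01)$gene, "x")
  # ... and p-threshold exclusion is strict: nothing retained has p >= alpha
  expect_true(all(de$p_value < 0.01))
})

test_that("direction flags flip under profile swap, retained set is stable", {
  genes <- as.character(1:60)
  mu <- stats::rnorm(60, 7, 1)
  shift <- sample(c(-4, 0, 4), 60, replace = TRUE)
  pop <- replicate_profile("pop", genes, mu + shift, 0.5, 3, seed = 21)
  ref <- replicate_profile("ref", genes, mu, 0.5, 3, seed = 22)
  fwd <- differential_genes(pop, ref, alpha = 0.05)
  bwd <- differential_genes(ref, pop, alpha = 0.05)
  expect_setequal(fwd$gene, bwd$gene)
  i <- match(fwd$gene, bwd$gene)
  expect_equal(bwd$log2_fold_change[i], -fwd$log2_fold_change)
  expect_true(all(bwd$direction[i] != fwd$direction))
})

test_that("tightening alpha or min_fold only shrinks the retained set", {
  genes <- as.character(1:80)
  mu <- stats::rnorm(80, 7, 1.5)
  pop <- replicate_profile("pop", genes, mu + stats::rnorm(80, 0, 2), 0.6, 3, 31)
  ref <- replicate_profile("ref", genes, mu, 0.6, 3, 32)
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  sets <- lapply(alphas, function(a) differential_genes(pop, ref, a)$gene)
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
  folds <- c(1, 2, 5, 10, 50)
  fsets <- lapply(folds, function(f) fold_change_gate(pop, ref, f)$gene)
  for (i in seq_len(length(fsets) - 1L)) {
    expect_true(all(fsets[[i + 1L]] %in% fsets[[i]]))
  }
})

test_that("welch power on planted 32-fold effects exceeds 0.9", {
  n <- 200
  genes <- as.character(seq_len(n))
  mu <- rep(8, n)
  pop <- replicate_profile("pop", genes, mu + 5, sd = 0.5, k = 3, seed = 41)
  ref <- replicate_profile("ref", genes, mu, sd = 0.5, k = 3, seed = 42)
  de <- differential_genes(pop, ref, alpha = 0.01)
  expect_gt(nrow(de) / n, 0.9)
})

test_that("fold gate applies the floor rule and threshold arithmetic", {
  pop <- toy_profile("pop", c("bmp4", "flat", "zero"), c(1335, 100, 0))
  ref <- toy_profile("ref", c("bmp4", "flat", "zero"), c(66, 100, 50))
  gate <- fold_change_gate(pop, ref, min_fold = 5)
  expect_setequal(gate$gene, c("bmp4", "zero"))      # 20.2x and 50x via floor
  expect_equal(gate$p_value, c(1, 1))                # absent-marker p
  expect_equal(sort(gate$direction),
               sort(c("up_in_population", "up_in_reference")))
  expect_equal(nrow(fold_change_gate(pop, ref, min_fold = 51)), 0L)
  expect_error(fold_change_gate(pop, ref, min_fold = 0.5), "min_fold")
})

test_that("single-replicate profiles are pushed to the fold gate", {
  a <- toy_profile("a", "1", 10)
  b <- toy_profile("b", "1", 20)
  expect_error(differential_genes(a, b), "fold_change_gate")
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  genes <- as.character(1:150)
  mu <- stats::rnorm(150, 7, 1)
  shift <- c(rep(3, 30), rep(0, 120))
  pop <- replicate_profile("pop", genes, mu + shift, 0.5, 3, seed = 51)
  ref <- replicate_profile("ref", genes, mu, 0.5, 3, seed = 52)
  de <- differential_genes(pop, ref, alpha = 1 - 1e-12, test = "moderated_t")

  X <- log2(do.call(rbind, pop$replicates) + 1)
  Y <- log2(do.call(rbind, ref$replicates) + 1)
  design <- cbind(1, c(rep(1, 3), rep(0, 3)))
  fit <- limma::eBayes(limma::lmFit(cbind(Y, X), design))
  p_ref <- fit$p.value[, 2L]
  expect_equal(de$p_value[match(genes, de$gene)], unname(p_ref),
               tolerance = 1e-6)
})

test_that("BH adjustment is available and more conservative", {
  genes <- as.character(1:100)
  mu <- stats::rnorm(100, 7, 1)
  pop <- replicate_profile("pop", genes, mu + stats::rnorm(100, 0, 1), 0.5, 3, 61)
  ref <- replicate_profile("ref", genes, mu, 0.5, 3, 62)
  raw <- differential_genes(pop, ref, alpha = 0.05)
  adj <- differential_genes(pop, ref, alpha = 0.05, adjust = "BH")
  expect_true(all(adj$gene %in% raw$gene))
})
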