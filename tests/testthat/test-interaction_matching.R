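test_that("stem-cell fixture reproduces the printed CXCR4/CXCL12 row", {
  res <- match_table_fixture("lthsc")
  tbl <- res$table
  row <- tbl[tbl$pop_symbol == "Cxcr4", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$pop_intensity, 372)
  expect_equal(row$stroma_symbol, "Cxcl12")
  expect_equal(row$stroma_intensity, 12222)
  expect_equal(row$direction, "pop_receptor__stroma_ligand")
  expect_equal(row$NIH3T3, 23)
  expect_equal(row$MC3T3, 798)
})

test_that("an empty gate or empty database produces an empty table", {
  fx <- load_table_fixture("prob")
  gate0 <- explicit_gate(character())
  expect_equal(nrow(match_interactions(gate0, fx$pop, fx$op9,
                                       global_pair_db())), 0L)
  empty_db <- pair_db(tibble::tibble(gene_a = character(),
                                     gene_b = character()))
  expect_warning(tbl <- match_interactions(NULL, fx$pop, fx$op9, empty_db),
                 "empty pair database")
  expect_equal(nrow(tbl), 0L)
})

test_that("gated genes missing from the population profile are skipped", {
  fx <- load_table_fixture("preb")
  gate <- explicit_gate(c(fx$pop$gene, "999999"))
  expect_message(tbl <- match_interactions(gate, fx$pop, fx$op9,
                                           global_pair_db()),
                 "missing from population profile")
  expect_equal(nrow(tbl), 8L)
})

test_that("population side needs gate and presence; stroma presence only", {
  db <- pair_db(tibble::tibble(gene_a = "1", symbol_a = "R", role_a = "receptor",
                               gene_b = "2", symbol_b = "L", role_b = "ligand"))
  pop <- toy_profile("pop", c("1", "2"), c(100, 100),
                     present = c(TRUE, FALSE))
  stroma <- toy_profile("str", c("1", "2"), c(50, 400))
  # only the receptor-on-population assignment passes: gene 2 is absent on
  # the population side, so the reverse assignment is blocked
  tbl <- match_interactions(NULL, pop, stroma, db)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$pop_gene, "1")
  expect_false(tbl$autocrine)
  # absent population gene fails even when explicitly gated
  expect_equal(nrow(match_interactions(explicit_gate("2"), pop, stroma, db)),
               0L)
  # absent stroma partner blocks the remaining assignment too
  stroma_absent <- toy_profile("str", c("1", "2"), c(50, 400),
                               present = c(TRUE, FALSE))
  expect_equal(nrow(match_interactions(NULL, pop, stroma_absent, db)), 0L)
})

test_that("both directed rows appear and autocrine pairs are flagged", {
  db <- pair_db(tibble::tibble(gene_a = "1", symbol_a = "R", role_a = "receptor",
                               gene_b = "2", symbol_b = "L", role_b = "ligand"))
  pop <- toy_profile("pop", c("1", "2"), c(10, 20))
  stroma <- toy_profile("str", c("1", "2"), c(30, 40))
  tbl <- match_interactions(NULL, pop, stroma, db)
  expect_equal(nrow(tbl), 2L)
  expect_setequal(tbl$direction, c("pop_receptor__stroma_ligand",
                                   "pop_ligand__stroma_receptor"))
  expect_true(all(tbl$autocrine))
  # one-sided case: flag off
  pop1 <- toy_profile("pop", "1", 10)
  tbl1 <- match_interactions(NULL, pop1, stroma, db)
  expect_equal(nrow(tbl1), 1L)
  expect_false(any(tbl1$autocrine))
})

test_that("matcher equals the exhaustive nested-loop reference", {
  for (seed in 1:60) {
    inst <- random_match_instance(seed)
    expect_true(matcher_vs_oracle_identical(inst), label = paste("seed", seed))
  }
})

test_that("every emitted row is backed by the database and the profiles", {
  for (seed in c(3, 17)) {
    inst <- random_match_instance(seed)
    tbl <- match_interactions(inst$gate, inst$pop, inst$stroma, inst$db)
    rec <- as.data.frame(inst$db)
    db_keys <- paste(pmin(rec$gene_a, rec$gene_b),
                     pmax(rec$gene_a, rec$gene_b))
    row_keys <- paste(pmin(tbl$pop_gene, tbl$stroma_gene),
                      pmax(tbl$pop_gene, tbl$stroma_gene))
    expect_true(all(row_keys %in% db_keys))
    expect_true(all(inst$stroma$present[match(tbl$stroma_gene,
                                              inst$stroma$gene)]))
    expect_true(all(tbl$pop_gene %in% inst$gate_keys))
    expect_false(any(duplicated(
      tbl[, c("pop_gene", "stroma_gene", "direction")])))
  }
})

test_that("comparator annotation fills values, sentinels and is identity-safe", {
  res <- match_table_fixture("lthsc", comparators = FALSE)
  tbl <- res$table
  fx <- res$fixture
  ann <- annotate_comparators(tbl, list(fx$nih3t3, fx$mc3t3))
  cx <- ann[ann$stroma_symbol == "Cxcl12", ]
  expect_equal(cx$NIH3T3, 23)
  expect_equal(cx$MC3T3, 798)
  expect_identical(annotate_comparators(tbl, list()), tbl)
  # comparator lacking a gene: NA sentinel, row count unchanged
  partial <- fx$nih3t3[fx$nih3t3$symbol != "Cxcl12", ]
  attr(partial, "population") <- "partial"
  class(partial) <- class(fx$nih3t3)
  ann2 <- annotate_comparators(tbl, list(partial))
  expect_equal(nrow(ann2), nrow(tbl))
  expect_true(is.na(ann2$partial[ann2$stroma_symbol == "Cxcl12"]))
  expect_false(anyNA(ann2$partial[ann2$stroma_symbol != "Cxcl12"]))
  expect_error(annotate_comparators(tbl, list(fx$nih3t3, fx$nih3t3)),
               "unique")
})

test_that("interaction tables round-trip to byte-identical files", {
  res <- match_table_fixture("prob")
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_interaction_table(res$table, f1)
  back <- read_interaction_table(f1)
  expect_equal(attr(back, "population"), "proB")
  expect_equal(attr(back, "stroma"), "OP9")
  expect_equal(as.data.frame(back), as.data.frame(res$table))
  write_interaction_table(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("matching identical inputs twice writes identical bytes", {
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_interaction_table(match_table_fixture("clp")$table, f1)
  write_interaction_table(match_table_fixture("clp")$table, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
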