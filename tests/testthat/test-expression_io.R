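write_expr_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("probe_set\taccession\tdescription\tgene\tsymbol\tintensity_1\tcall_1",
               lines), f)
  f
}

test_that("probe rows parse with intensities and calls", {
  f <- write_expr_lines(c("a_at\tN1\tgene a\t11\tGa\t120.5\tP",
                          "b_at\tN2\tgene b\t12\tGb\t30\ta"))
  rec <- read_expression_table(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$intensities[[1L]], 120.5)
  expect_equal(rec$calls[[2L]], "A")   # case-insensitive token
  expect_equal(attr(rec, "n_replicates"), 1L)
})

test_that("header-only files give an empty record set and empty profile", {
  f <- write_expr_lines(character())
  rec <- read_expression_table(f)
  expect_equal(nrow(rec), 0L)
  prof <- aggregate_probesets(rec, "empty")
  expect_equal(nrow(prof), 0L)
})

test_that("format violations are rejected with the offending line", {
  missing_col <- tempfile(fileext = ".tsv")
  writeLines(c("probe_set\tgene\tsymbol\tintensity_1\tcall_1",
               "a\t1\tG\t5\tP"), missing_col)
  expect_error(read_expression_table(missing_col), "accession")

  ragged <- tempfile(fileext = ".tsv")
  writeLines(c(paste("probe_set", "accession", "description", "gene",
                     "symbol", "intensity_1", "intensity_2", "call_1",
                     sep = "\t"),
               "a\tN\td\t1\tG\t5\t6\tP"), ragged)
  expect_error(read_expression_table(ragged), "2 intensity.*1 call")

  expect_error(read_expression_table(
    write_expr_lines("a_at\tN\td\t1\tG\tabc\tP")),
    "line 2.*invalid intensity")
  expect_error(read_expression_table(
    write_expr_lines(c("a_at\tN\td\t1\tG\t5\tP", "b_at\tN\td\t2\tH\t5\tX"))),
    "line 3.*invalid call")
  expect_error(read_expression_table(
    write_expr_lines("a_at\tN\td\t1\tG\t-4\tP")),
    "invalid intensity")
})

test_that("max_mean aggregation picks the strongest probe set per gene", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("probe_set\taccession\tdescription\tgene\tsymbol\tintensity_1\tintensity_2\tcall_1\tcall_2",
               "lo_at\tN\td\t77\tGx\t90\t110\tP\tP",
               "hi_at\tN\td\t77\tGx\t290\t310\tA\tA",
               "only_at\tN\td\t88\tGy\t55\t65\tA\tM"), f)
  prof <- aggregate_probesets(read_expression_table(f), "toy")
  expect_equal(nrow(prof), 2L)
  gx <- prof[prof$gene == "77", ]
  expect_equal(gx$mean_intensity, 300)           # (290+310)/2, max-mean probe
  expect_false(gx$present)                       # representing probe all-A
  gy <- prof[prof$gene == "88", ]
  expect_equal(gy$mean_intensity, 60)            # single probe: identity
  expect_false(gy$present)                       # M counts as absent...

  prof_m <- aggregate_probesets(read_expression_table(f), "toy",
                                marginal_as_present = TRUE)
  expect_true(prof_m[prof_m$gene == "88", ]$present)  # ...unless configured

  prof_mm <- aggregate_probesets(read_expression_table(f), "toy",
                                 method = "mean_of_means")
  expect_equal(prof_mm[prof_mm$gene == "77", ]$mean_intensity, 200)
  expect_true(prof_mm[prof_mm$gene == "77", ]$present)  # any probe P
})

test_that("aggregation is permutation-invariant and never invents genes", {
  set.seed(7)
  n <- 30
  lines <- sprintf("p%02d_at\tN\td\t%d\tG%d\t%g\t%s", 1:n,
                   sample(1:12, n, replace = TRUE) + 100,
                   sample(1:12, n, replace = TRUE),
                   round(stats::runif(n, 0, 500), 1),
                   sample(c("P", "A", "M"), n, replace = TRUE))
  f1 <- write_expr_lines(lines)
  f2 <- write_expr_lines(sample(lines))
  rec1 <- read_expression_table(f1)
  rec2 <- read_expression_table(f2)
  p1 <- aggregate_probesets(rec1, "x")
  p2 <- aggregate_probesets(rec2, "x")
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_true(all(p1$gene %in% rec1$gene))
})

test_that("fixture profiles carry one printed intensity per distinct gene", {
  prof <- read_population_profile(ext_path("tables", "pop_lthsc.tsv"),
                                  "LT-HSC")
  expect_equal(nrow(prof), 12L)   # 15 printed rows, 3 genes recur
  expect_equal(prof$mean_intensity[prof$symbol == "Cxcr4"], 372)
  expect_true(all(prof$present))
  # single-value fixtures: aggregation is the identity on intensities
  expect_equal(prof$mean_intensity,
               vapply(prof$replicates, `[[`, 0, 1L))
})

test_that("profiles round-trip through the expression writer", {
  prof <- read_population_profile(ext_path("tables", "stroma_op9_prob.tsv"),
                                  "OP9")
  out <- tempfile(fileext = ".tsv")
  write_expression_table(prof, out)
  back <- read_population_profile(out, "OP9")
  expect_equal(as.data.frame(back), as.data.frame(prof))
})

test_that("profile invariants are enforced", {
  expect_error(population_profile("x", c("1", "1"), intensities = c(5, 6)),
               "duplicate gene key")
  expect_error(population_profile("x", "1", intensities = -3),
               "finite")
  prof <- toy_profile("x", c("1", "2"), c(10, 20))
  expect_equal(prof$mean_intensity, vapply(prof$replicates, mean, 0))
})
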