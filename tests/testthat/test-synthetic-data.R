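test_that("simulated cohorts respect ranges, dimensions, and truth-set structure", {
  cfg <- sim_config(n_genes_expr = 120, n_genes_meth = 100,
                    shared_gene_fraction = 0.8,
                    n_tumor_expr = 12, n_normal_expr = 10,
                    n_tumor_meth = 9, n_normal_meth = 7,
                    n_planted = 6, n_expr_only = 4, n_meth_only = 3, seed = 42)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$expression), c(22L, 120L))
  expect_equal(dim(co$methylation), c(16L, 100L))
  expect_true(all(co$expression$values > 0))
  expect_true(all(co$methylation$values > 0 & co$methylation$values < 1))
  # unpaired design: disjoint sample ID spaces
  expect_length(intersect(sample_ids(co$expression), sample_ids(co$methylation)), 0L)

  tr <- co$truth
  expect_equal(lengths(tr[c("planted", "expr_only", "meth_only")]),
               c(planted = 6L, expr_only = 4L, meth_only = 3L))
  expect_length(intersect(tr$planted, tr$expr_only), 0L)
  expect_length(intersect(tr$planted, tr$meth_only), 0L)
  expect_length(intersect(tr$expr_only, tr$meth_only), 0L)
  # differential genes live in the shared gene space
  shared <- intersect(gene_ids(co$expression), gene_ids(co$methylation))
  expect_true(all(unlist(tr) %in% shared))

  expect_error(sim_config(n_genes_expr = 10, n_genes_meth = 10, n_planted = 50),
               "exceed the shared gene set")
})

test_that("identical seeds reproduce the cohort; different seeds change values only", {
  cfg <- sim_config(n_genes_expr = 60, n_genes_meth = 60,
                    n_tumor_expr = 8, n_normal_expr = 8,
                    n_tumor_meth = 8, n_normal_meth = 8,
                    n_planted = 5, n_expr_only = 2, n_meth_only = 2, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$truth, b$truth)

  cfg2 <- cfg; cfg2$seed <- 12L
  c2 <- simulate_cohort(cfg2)
  expect_false(identical(a$expression$values, c2$expression$values))
  expect_identical(dim(a$expression), dim(c2$expression))
  expect_identical(lengths(a$truth), lengths(c2$truth))
})

test_that("planted expression effect is realized at the configured size", {
  # tumor - normal mean log2 difference over planted genes should sit within
  # 3 standard errors of the configured shift; the SE follows from the
  # generator's own noise model: noise_sd * sqrt(1/n_t + 1/n_n) per gene,
  # divided by sqrt(n_planted) for the average over genes.
  cfg <- sim_config(n_genes_expr = 400, n_genes_meth = 400,
                    n_tumor_expr = 60, n_normal_expr = 60,
                    n_tumor_meth = 60, n_normal_meth = 60,
                    n_planted = 20, n_expr_only = 0, n_meth_only = 0,
                    expr_log2_effect = 1.5, noise_sd = 0.4, seed = 7)
  co <- simulate_cohort(cfg)
  lv <- log2(co$expression$values[, co$truth$planted, drop = FALSE])
  tum <- colMeans(lv[co$expression$labels == "tumor", ])
  nor <- colMeans(lv[co$expression$labels == "normal", ])
  realized <- mean(tum - nor)
  se <- cfg$noise_sd * sqrt(1 / 60 + 1 / 60) / sqrt(cfg$n_planted)
  expect_lt(abs(realized - cfg$expr_log2_effect), 3 * se)

  # planted methylation shift is hypomethylation (opposite sign)
  mb <- co$methylation
  dtum <- colMeans(mb$values[mb$labels == "tumor", co$truth$planted]) -
    colMeans(mb$values[mb$labels == "normal", co$truth$planted])
  expect_true(all(dtum < 0))
})

test_that("a null configuration plants no group differences", {
  cfg <- sim_config(n_genes_expr = 200, n_genes_meth = 200,
                    n_tumor_expr = 30, n_normal_expr = 30,
                    n_tumor_meth = 30, n_normal_meth = 30,
                    n_planted = 0, n_expr_only = 0, n_meth_only = 0,
                    expr_log2_effect = 0, meth_beta_effect = 0, seed = 19)
  co <- simulate_cohort(cfg)
  d <- differential_table(co$expression)
  expect_length(call_significant(d), 0L)
  dm <- differential_table(co$methylation, thresholds = diff_thresholds(1.8, 0.05, 0.01))
  expect_length(call_significant(dm, diff_thresholds(1.8, 0.05, 0.01)), 0L)
})

test_that("cohorts write to plain-text files that read back", {
  cfg <- sim_config(n_genes_expr = 30, n_genes_meth = 30,
                    n_tumor_expr = 4, n_normal_expr = 4,
                    n_tumor_meth = 4, n_normal_meth = 4,
                    n_planted = 2, n_expr_only = 1, n_meth_only = 1, seed = 2)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir, config = cfg)
  back <- read_omics_matrix(file.path(dir, "expression.tsv"),
                            file.path(dir, "expression_labels.tsv"))
  expect_equal(back$values, co$expression$values, tolerance = 1e-9)
  expect_equal(readLines(file.path(dir, "truth_planted.txt")), co$truth$planted)
})
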