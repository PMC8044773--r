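test_that("confusion metrics reproduce worked examples and conventions", {
  m <- classification_metrics(2, 1, 3, 0)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 0.8)

  perfect <- classification_metrics(10, 0, 7, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  suppressMessages(degen <- classification_metrics(0, 0, 2, 3))
  expect_equal(degen$precision, 0)  # zero-denominator convention
  expect_equal(degen$recall, 0)
  expect_equal(degen$f1, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
  expect_error(classification_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("metrics match the definition oracle on random confusion tables", {
  set.seed(31)
  for (rep in seq_len(1000)) {
    cts <- rpois(4, 5)
    if (sum(cts) == 0) next
    got <- suppressMessages(classification_metrics(cts[1], cts[2], cts[3], cts[4]))
    want <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("AUC handles perfect ranking, ties, and hand-counted pairs", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # one of two positive-negative pairs correctly ordered
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(17)
  for (rep in seq_len(500)) {
    n <- sample(4:30, 1)
    truth <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(auc_score(scores, truth), oracle_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds balance both classes and respect the seed", {
  labels <- rep(c("tumor", "normal"), c(134, 134))
  f <- stratified_folds(labels, 5, seed = 4)
  expect_identical(f, stratified_folds(labels, 5, seed = 4))
  sizes <- tabulate(f)
  expect_true(all(abs(268 - sizes - 214) <= 1))  # train folds of 214 +/- 1
  for (k in 1:5) {
    expect_gte(sum(labels[f == k] == "tumor"), 1)
    expect_gte(sum(labels[f == k] == "normal"), 1)
  }
  expect_error(stratified_folds(rep(c("tumor", "normal"), c(3, 40)), 5),
               "fewer samples")
})

small_cohort <- function(seed = 77) {
  simulate_cohort(sim_config(
    n_genes_expr = 200, n_genes_meth = 200,
    n_tumor_expr = 40, n_normal_expr = 40,
    n_tumor_meth = 36, n_normal_meth = 36,
    n_planted = 8, n_expr_only = 4, n_meth_only = 4,
    expr_log2_effect = 1.5, meth_beta_effect = 0.15, seed = seed
  ))
}

fast_config <- function(classifier = "dnn") {
  pipeline_config(
    mi_top_n = 100L,
    dnn = dnn_config(n_hidden_layers = 2L, units_per_layer = 16L,
                     epochs = 5L, seed = 8L),
    classifier = classifier, cv_seed = 6L
  )
}

test_that("a pipeline fold recovers planted biomarkers from training data only", {
  co <- small_cohort()
  cfg <- fast_config()
  split_m <- function(x, frac = 0.5) {
    f <- stratified_folds(x$labels, 2, seed = 13)
    list(train = omics_matrix(x$values[f == 1, ], x$labels[f == 1], x$modality),
         test = omics_matrix(x$values[f == 2, ], x$labels[f == 2], x$modality))
  }
  e <- split_m(co$expression); m <- split_m(co$methylation)
  fold <- run_pipeline_fold(e$train, e$test, m$train, m$test, cfg)
  expect_equal(fold$status, "ok")
  expect_gte(mean(co$truth$planted %in% fold$selected_genes), 0.9)
  expect_equal(fold$n_test_pairs, with(
    list(te = sum(e$test$labels == "tumor"), tm = sum(m$test$labels == "tumor"),
         ne = sum(e$test$labels == "normal"), nm = sum(m$test$labels == "normal")),
    te * tm + ne * nm))
  expect_true(all(unlist(fold$counts) >= 0))
  expect_equal(Reduce(`+`, fold$counts), fold$n_test_pairs)

  # leakage sentinel: corrupting held-out values changes nothing selected
  e_bad <- omics_matrix(e$test$values * 100, e$test$labels, "expression")
  m_bad <- omics_matrix(pmin(m$test$values * 1.5, 0.999), m$test$labels, "methylation")
  fold_bad <- run_pipeline_fold(e$train, e_bad, m$train, m_bad, cfg)
  expect_identical(fold_bad$selected_genes, fold$selected_genes)
  expect_identical(fold_bad$expr_diff, fold$expr_diff)
})

test_that("run_cv aggregates folds deterministically with consensus", {
  co <- small_cohort(seed = 78)
  cfg <- fast_config()
  rep1 <- run_cv(co$expression, co$methylation, cfg)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$summary), 5L)
  expect_equal(rep1$consensus_genes,
               consensus_across_folds(rep1$fold_genes))
  ok <- rep1$summary$status == "ok"
  expect_equal(rep1$means$accuracy, mean(rep1$summary$accuracy[ok]))
  expect_true(all(rep1$summary$auc[ok] >= 0 & rep1$summary$auc[ok] <= 1))

  rep2 <- run_cv(co$expression, co$methylation, cfg)
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$fold_genes, rep2$fold_genes)

  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_cv_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "cv_report.tsv")))
  expect_equal(readLines(file.path(dir, "consensus_genes.txt")),
               rep1$consensus_genes)
  expect_true(file.exists(file.path(dir, "fold_3_meth_diff.tsv")))
})

test_that("baseline classifiers slot into the same fold pipeline", {
  co <- small_cohort(seed = 79)
  rep_nb <- run_cv(co$expression, co$methylation, fast_config("nb"))
  ok <- rep_nb$summary$status == "ok"
  expect_true(any(ok))
  expect_gte(rep_nb$means$accuracy, 0.9)  # strong planted signal, easy task
})
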