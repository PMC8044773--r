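# Leakage-free stratified 5-fold cross-validation of the whole pipeline and
# the confusion-derived metrics. Positives are tumor pairs throughout.
#
# The two modalities are folded INDEPENDENTLY (their cohorts are unpaired and
# differently sized); fold k of the run combines expression fold k with
# methylation fold k. Everything that is fitted — standardizers, MI ranks,
# differential tables, the classifier — sees training partitions only.

#' Pipeline configuration
#'
#' Defaults are the published operating point: MI TopN = 3000, expression
#' thresholds (|FC| > 2, p < 0.05, FDR < 0.01), methylation thresholds
#' (|FC| > 1.8, p < 0.05, FDR < 0.01), Levene gate 0.05, five folds.
#'
#' @param mi_top_n Genes retained per modality by the MI pre-screen.
#' @param mi_bins Quantile bins for [mi_score()].
#' @param expr_thresholds,meth_thresholds [diff_thresholds()] per modality.
#' @param gate_alpha Levene variance-homogeneity gate.
#' @param dnn A [dnn_config()].
#' @param classifier `"dnn"` or a [baseline_classifier()] name.
#' @param n_folds Cross-validation folds.
#' @param cv_seed Seed for the stratified fold assignment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mi_top_n = 3000L, mi_bins = 10L,
                            expr_thresholds = diff_thresholds(2, 0.05, 0.01),
                            meth_thresholds = diff_thresholds(1.8, 0.05, 0.01),
                            gate_alpha = 0.05,
                            dnn = dnn_config(),
                            classifier = "dnn",
                            n_folds = 5L, cv_seed = 1L) {
  stopifnot(inherits(expr_thresholds, "diff_thresholds"),
            inherits(meth_thresholds, "diff_thresholds"),
            inherits(dnn, "dnn_config"))
  if (!classifier %in% c("dnn", baseline_classifier_names())) {
    stop("unknown classifier: ", classifier)
  }
  structure(
    list(mi_top_n = assert_count(mi_top_n, "mi_top_n", 1L),
         mi_bins = assert_count(mi_bins, "mi_bins", 2L),
         expr_thresholds = expr_thresholds,
         meth_thresholds = meth_thresholds,
         gate_alpha = gate_alpha,
         dnn = dnn,
         classifier = classifier,
         n_folds = assert_count(n_folds, "n_folds", 2L),
         cv_seed = as.integer(cv_seed)),
    class = "pipeline_config"
  )
}

#' Stratified fold assignment
#'
#' Shuffles within each label stratum under `seed` and deals samples to
#' folds round-robin, so fold sizes differ by at most one per stratum.
#'
#' @param labels Per-sample label vector.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold index (1..n_folds) per sample.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  fold <- integer(length(labels))
  offset <- 0L
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      if (length(idx) < n_folds) {
        stop("class '", lab, "' has fewer samples (", length(idx),
             ") than folds (", n_folds, ")")
      }
      # rotate which folds receive this stratum's leftover samples so the
      # combined fold sizes differ by at most one
      assign_to <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      fold[idx[sample.int(length(idx))]] <- assign_to
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  fold
}

#' Confusion-matrix metrics
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R); a zero denominator yields 0 by
#' convention (with a message).
#'
#' @param tp,fp,tn,fn Non-negative integer counts; tumor is positive.
#' @return Named list: accuracy, precision, recall, f1.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative; tied
#' scores contribute 1/2 via midranks.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary truth (1/`"tumor"` = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  pos <- truth == 1 | truth == "tumor"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("AUC needs both classes in 'truth'")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Feature selection on TRAINING data only. Returns the selected genes plus
# the per-modality differential tables for audit.
select_features_train <- function(expr_train_raw, meth_train_raw, config) {
  expr_std <- fit_standardizer(expr_train_raw)
  meth_std <- fit_standardizer(meth_train_raw)
  expr_z <- apply_standardizer(expr_train_raw, expr_std)
  meth_z <- apply_standardizer(meth_train_raw, meth_std)

  expr_top <- rank_topn(expr_z, config$mi_top_n, config$mi_bins)$gene
  meth_top <- rank_topn(meth_z, config$mi_top_n, config$mi_bins)$gene

  expr_diff <- differential_table(restrict_genes(expr_train_raw, expr_top),
                                  config$gate_alpha, config$expr_thresholds)
  meth_diff <- differential_table(restrict_genes(meth_train_raw, meth_top),
                                  config$gate_alpha, config$meth_thresholds)

  deg <- call_significant(expr_diff, config$expr_thresholds)
  dmp <- call_significant(meth_diff, config$meth_thresholds)
  selected <- suppressWarnings(intersect_biomarkers(deg, dmp))

  list(selected_genes = selected, deg = deg, dmp = dmp,
       expr_standardizer = expr_std, meth_standardizer = meth_std,
       expr_diff = expr_diff, meth_diff = meth_diff)
}

fit_predict_classifier <- function(train_pairs, test_pairs, config) {
  if (config$classifier == "dnn") {
    model <- dnn_train(train_pairs, config$dnn)
    dnn_predict(model, test_pairs)$score
  } else {
    adapter <- baseline_classifier(config$classifier)
    fit <- adapter$fit(train_pairs$features,
                       as.integer(train_pairs$labels == "tumor"))
    as.numeric(adapter$predict_score(fit, test_pairs$features))
  }
}

#' Run one cross-validation fold of the full pipeline
#'
#' preprocess -> MI TopN -> differential calling -> DEG/DMP intersection ->
#' Cartesian pairing -> classifier training -> per-pair test metrics, with
#' every fitted component restricted to the training partitions.
#'
#' @param expr_train,expr_test,meth_train,meth_test [omics_matrix()] objects
#'   on their original (pre-standardization) scale.
#' @param config A [pipeline_config()].
#' @return List: `selected_genes`, `deg`, `dmp`, `status`
#'   (`"ok"`/`"no_biomarkers"`), `counts` (TP/FP/TN/FN), `metrics`
#'   (accuracy/precision/recall/f1/auc), `n_train_pairs`, `n_test_pairs`.
#' @export
run_pipeline_fold <- function(expr_train, expr_test, meth_train, meth_test,
                              config = pipeline_config()) {
  sel <- select_features_train(expr_train, meth_train, config)
  if (length(sel$selected_genes) == 0L) {
    return(list(selected_genes = character(0), deg = sel$deg, dmp = sel$dmp,
                expr_diff = sel$expr_diff, meth_diff = sel$meth_diff,
                status = "no_biomarkers", counts = NULL,
                metrics = list(accuracy = NA_real_, precision = NA_real_,
                               recall = NA_real_, f1 = NA_real_, auc = NA_real_),
                n_train_pairs = 0L, n_test_pairs = 0L))
  }
  genes <- sel$selected_genes
  expr_z_tr <- restrict_genes(apply_standardizer(expr_train, sel$expr_standardizer), genes)
  meth_z_tr <- restrict_genes(apply_standardizer(meth_train, sel$meth_standardizer), genes)
  expr_z_te <- restrict_genes(apply_standardizer(expr_test, sel$expr_standardizer), genes)
  meth_z_te <- restrict_genes(apply_standardizer(meth_test, sel$meth_standardizer), genes)

  train_pairs <- cartesian_pair(expr_z_tr, meth_z_tr)
  test_pairs <- cartesian_pair(expr_z_te, meth_z_te)

  scores <- fit_predict_classifier(train_pairs, test_pairs, config)
  thr <- if (config$classifier == "dnn") config$dnn$decision_threshold else 0.5
  pred_tumor <- scores > thr
  truth_tumor <- test_pairs$labels == "tumor"
  tp <- sum(pred_tumor & truth_tumor)
  fp <- sum(pred_tumor & !truth_tumor)
  tn <- sum(!pred_tumor & !truth_tumor)
  fn <- sum(!pred_tumor & truth_tumor)
  mets <- classification_metrics(tp, fp, tn, fn)
  mets$auc <- auc_score(scores, test_pairs$labels)

  list(selected_genes = genes, deg = sel$deg, dmp = sel$dmp,
       expr_diff = sel$expr_diff, meth_diff = sel$meth_diff, status = "ok",
       counts = list(tp = tp, fp = fp, tn = tn, fn = fn), metrics = mets,
       n_train_pairs = nrow(train_pairs$features),
       n_test_pairs = nrow(test_pairs$features))
}

#' Run the full stratified cross-validation
#'
#' @param expr,meth [omics_matrix()] cohorts on their original scale.
#' @param config A [pipeline_config()].
#' @return A `cv_report`: `folds` (list of [run_pipeline_fold()] results),
#'   `fold_genes` (per-fold gene lists), `consensus_genes` (genes selected in
#'   every fold), `summary` (per-fold metric data frame), and `means`
#'   (fold-averaged metrics; folds without biomarkers are excluded from the
#'   average and flagged).
#' @export
run_cv <- function(expr, meth, config = pipeline_config()) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(meth, "omics_matrix"),
            inherits(config, "pipeline_config"))
  expr_fold <- stratified_folds(expr$labels, config$n_folds, config$cv_seed)
  meth_fold <- stratified_folds(meth$labels, config$n_folds, config$cv_seed + 1L)

  subset_samples <- function(x, keep) {
    omics_matrix(x$values[keep, , drop = FALSE], x$labels[keep], x$modality)
  }

  folds <- lapply(seq_len(config$n_folds), function(k) {
    run_pipeline_fold(
      subset_samples(expr, expr_fold != k), subset_samples(expr, expr_fold == k),
      subset_samples(meth, meth_fold != k), subset_samples(meth, meth_fold == k),
      config
    )
  })

  fold_genes <- lapply(folds, `[[`, "selected_genes")
  names(fold_genes) <- paste0("fold", seq_along(folds))
  non_empty <- lengths(fold_genes) > 0L
  consensus <- if (all(non_empty)) consensus_across_folds(fold_genes) else character(0)

  summary <- do.call(rbind, lapply(seq_along(folds), function(k) {
    m <- folds[[k]]$metrics
    data.frame(fold = k, n_genes = length(fold_genes[[k]]),
               status = folds[[k]]$status,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, auc = m$auc)
  }))
  ok <- summary$status == "ok"
  means <- if (any(ok)) {
    colMeans(summary[ok, c("accuracy", "precision", "recall", "f1", "auc")])
  } else {
    stats::setNames(rep(NA_real_, 5L), c("accuracy", "precision", "recall", "f1", "auc"))
  }

  structure(
    list(folds = folds, fold_genes = fold_genes, consensus_genes = consensus,
         summary = summary, means = as.list(means), config = config),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", length(x$folds), "folds\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("mean accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f | auc %.4f\n",
              x$means$accuracy, x$means$precision, x$means$recall,
              x$means$f1, x$means$auc))
  cat("consensus genes (", length(x$consensus_genes), "): ",
      paste(x$consensus_genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report to a directory
#'
#' Emits `cv_report.tsv`, one `fold_<k>_genes.txt` per fold,
#' `consensus_genes.txt`, and per-fold differential tables.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(dir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(report$fold_genes)) {
    writeLines(report$fold_genes[[k]], file.path(dir, sprintf("fold_%d_genes.txt", k)))
    for (mod in c("expr", "meth")) {
      tab <- report$folds[[k]][[paste0(mod, "_diff")]]
      if (!is.null(tab)) {
        utils::write.table(tab, file.path(dir, sprintf("fold_%d_%s_diff.tsv", k, mod)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  writeLines(report$consensus_genes, file.path(dir, "consensus_genes.txt"))
  invisible(dir)
}
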