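# Seeded generator of paired expression/methylation tumor-normal cohorts with
# planted, cross-modality-concordant differential genes.
#
# The two modalities deliberately have DISJOINT sample ID spaces and different
# sample counts: the real cohorts this emulates are unpaired (different
# patients assayed on different platforms), which is exactly what the
# Cartesian pairing stage has to cope with.
#
# Expression model: per-gene baseline log2 intensity mu_g ~ N(8, 1.5)
# (microarray-like), per-sample value 2^(mu_g + delta + e), e ~ N(0, noise_sd),
# where delta = expr_log2_effect for tumor samples of differential genes and 0
# otherwise. Methylation model: logit-normal beta values; per-gene baseline
# mean beta p_g ~ logit-normal around 0.22 with logit-scale SD 0.15
# (promoter-like low methylation, kept narrow enough that an additive beta
# shift expresses as a comparable fold change at every baseline), tumor
# samples of differential
# genes get a target mean of p_g - meth_beta_effect (hypomethylation — the
# sign opposite to the expression shift, mirroring promoter methylation loss
# accompanying upregulation), realised by shifting the logit-scale mean.

#' Configure a synthetic two-modality cohort
#'
#' Defaults reproduce the scale of the gastric-cancer cohorts that motivate
#' the pipeline: ~13.5k expression features over 134 tumor + 134 normal
#' samples and ~14.5k methylation features over 203 tumor + 94 normal
#' samples, with 20 planted cross-modality biomarkers.
#'
#' @param n_genes_expr,n_genes_meth Feature counts per modality.
#' @param shared_gene_fraction Fraction of the smaller gene set shared
#'   between modalities; planted genes live in the shared set.
#' @param n_tumor_expr,n_normal_expr,n_tumor_meth,n_normal_meth Sample counts.
#' @param n_planted True biomarkers: differential in BOTH modalities.
#' @param n_expr_only,n_meth_only Modality-private differential genes.
#' @param expr_log2_effect Mean log2 expression shift in tumor samples of
#'   differential genes (up in tumor).
#' @param meth_beta_effect Mean beta-value decrease in tumor samples of
#'   differential genes (hypomethylation).
#' @param noise_sd Per-sample Gaussian noise SD (log2 scale for expression,
#'   logit scale for methylation).
#' @param seed Integer driving all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes_expr = 13515, n_genes_meth = 14476,
                       shared_gene_fraction = 0.8,
                       n_tumor_expr = 134, n_normal_expr = 134,
                       n_tumor_meth = 203, n_normal_meth = 94,
                       n_planted = 20, n_expr_only = 15, n_meth_only = 15,
                       expr_log2_effect = 1.5, meth_beta_effect = 0.15,
                       noise_sd = 0.4, seed = 1L) {
  cfg <- list(
    n_genes_expr = assert_count(n_genes_expr, "n_genes_expr", 1L),
    n_genes_meth = assert_count(n_genes_meth, "n_genes_meth", 1L),
    shared_gene_fraction = shared_gene_fraction,
    n_tumor_expr = assert_count(n_tumor_expr, "n_tumor_expr", 1L),
    n_normal_expr = assert_count(n_normal_expr, "n_normal_expr", 1L),
    n_tumor_meth = assert_count(n_tumor_meth, "n_tumor_meth", 1L),
    n_normal_meth = assert_count(n_normal_meth, "n_normal_meth", 1L),
    n_planted = assert_count(n_planted, "n_planted"),
    n_expr_only = assert_count(n_expr_only, "n_expr_only"),
    n_meth_only = assert_count(n_meth_only, "n_meth_only"),
    expr_log2_effect = expr_log2_effect,
    meth_beta_effect = meth_beta_effect,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$shared_gene_fraction < 0 || cfg$shared_gene_fraction > 1) {
    stop("'shared_gene_fraction' must be in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0")
  n_shared <- round(cfg$shared_gene_fraction * min(cfg$n_genes_expr, cfg$n_genes_meth))
  if (cfg$n_planted + cfg$n_expr_only + cfg$n_meth_only > n_shared) {
    stop("planted + modality-private differential genes exceed the shared gene set (",
         n_shared, ")")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an unpaired expression + methylation tumor/normal cohort
#'
#' @param config A [sim_config()].
#' @return List with elements `expression` and `methylation` (each an
#'   [omics_matrix()] on its natural scale: positive intensities,
#'   beta values strictly in (0, 1)) and `truth`, a list of the pairwise
#'   disjoint gene sets `planted`, `expr_only`, and `meth_only`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_shared <- round(cfg$shared_gene_fraction * min(cfg$n_genes_expr, cfg$n_genes_meth))
    n_universe <- cfg$n_genes_expr + cfg$n_genes_meth - n_shared
    universe <- sprintf("GENE%05d", seq_len(n_universe))
    shared <- universe[seq_len(n_shared)]
    expr_genes <- c(shared, universe[seq_len(cfg$n_genes_expr - n_shared) + n_shared])
    meth_genes <- c(shared, utils::tail(universe, cfg$n_genes_meth - n_shared))

    n_diff <- cfg$n_planted + cfg$n_expr_only + cfg$n_meth_only
    diff_genes <- shared[sample.int(length(shared), n_diff)]
    planted <- sort(diff_genes[seq_len(cfg$n_planted)])
    expr_only <- sort(diff_genes[seq_len(cfg$n_expr_only) + cfg$n_planted])
    meth_only <- sort(utils::tail(diff_genes, cfg$n_meth_only))
    if (cfg$n_meth_only == 0L) meth_only <- character(0)

    expr_labels <- c(rep("tumor", cfg$n_tumor_expr), rep("normal", cfg$n_normal_expr))
    expr_samples <- c(sprintf("GE_T%03d", seq_len(cfg$n_tumor_expr)),
                      sprintf("GE_N%03d", seq_len(cfg$n_normal_expr)))
    meth_labels <- c(rep("tumor", cfg$n_tumor_meth), rep("normal", cfg$n_normal_meth))
    meth_samples <- c(sprintf("ME_T%03d", seq_len(cfg$n_tumor_meth)),
                      sprintf("ME_N%03d", seq_len(cfg$n_normal_meth)))

    # expression: log2-scale baseline + tumor shift + noise, exponentiated
    ne <- length(expr_samples)
    mu_e <- stats::rnorm(length(expr_genes), mean = 8, sd = 1.5)
    log2_vals <- matrix(rep(mu_e, each = ne), nrow = ne,
                        dimnames = list(expr_samples, expr_genes))
    de <- expr_genes %in% c(planted, expr_only)
    log2_vals[expr_labels == "tumor", de] <-
      log2_vals[expr_labels == "tumor", de] + cfg$expr_log2_effect
    log2_vals <- log2_vals + stats::rnorm(length(log2_vals), sd = cfg$noise_sd)
    expr <- omics_matrix(2^log2_vals, stats::setNames(expr_labels, expr_samples),
                         "expression")

    # methylation: logit-normal beta; tumor mean of differential genes
    # targeted at baseline - meth_beta_effect (clamped inside (0, 1))
    nm <- length(meth_samples)
    p0 <- stats::plogis(stats::rnorm(length(meth_genes), stats::qlogis(0.22), 0.15))
    lgt <- matrix(rep(stats::qlogis(p0), each = nm), nrow = nm,
                  dimnames = list(meth_samples, meth_genes))
    dm <- meth_genes %in% c(planted, meth_only)
    p1 <- pmin(pmax(p0 - cfg$meth_beta_effect, 0.02), 0.98)
    lgt[meth_labels == "tumor", dm] <-
      matrix(rep(stats::qlogis(p1[dm]), each = sum(meth_labels == "tumor")),
             nrow = sum(meth_labels == "tumor"))
    lgt <- lgt + stats::rnorm(length(lgt), sd = cfg$noise_sd)
    meth <- omics_matrix(stats::plogis(lgt), stats::setNames(meth_labels, meth_samples),
                         "methylation")

    list(
      expression = expr,
      methylation = meth,
      truth = list(planted = planted, expr_only = expr_only, meth_only = meth_only)
    )
  })
}

#' Write a simulated cohort to a directory
#'
#' Writes the two matrices (features x samples), their label tables, the
#' truth gene sets, and the configuration used, all as plain text.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param config The [sim_config()] used, recorded as JSON for provenance.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"),
                     file.path(dir, "expression_labels.tsv"))
  write_omics_matrix(cohort$methylation, file.path(dir, "methylation.tsv"),
                     file.path(dir, "methylation_labels.tsv"))
  for (set in names(cohort$truth)) {
    writeLines(cohort$truth[[set]], file.path(dir, paste0("truth_", set, ".txt")))
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
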