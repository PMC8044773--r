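# Per-gene differential calling: fold change on the original positive scale,
# a Levene-gated choice between the pooled and Welch two-sample t-test, and
# Benjamini-Hochberg FDR over the tested gene universe.
#
# Fold change deliberately uses the PRE-standardization values: z-scored
# group means can be negative or near zero, so a ratio threshold like
# |FC| > 2 is only meaningful on the original intensity / beta scale. The
# t-test, by contrast, is location-scale invariant, so testing standardized
# values gives identical p-values.

#' Differential-calling thresholds
#'
#' Defaults follow the pipeline's published operating point: expression
#' |FC| > 2, methylation |FC| > 1.8, both with p < 0.05 and FDR < 0.01.
#'
#' @param abs_fc_min Minimum |FC| (reciprocal convention, so >= 1).
#' @param p_max Maximum raw p-value.
#' @param q_max Maximum BH-adjusted q-value.
#' @return A `diff_thresholds` list.
#' @export
diff_thresholds <- function(abs_fc_min = 2, p_max = 0.05, q_max = 0.01) {
  if (abs_fc_min <= 0 || p_max <= 0 || q_max <= 0 || p_max > 1 || q_max > 1) {
    stop("thresholds must be positive, with p_max and q_max <= 1")
  }
  structure(list(abs_fc_min = abs_fc_min, p_max = p_max, q_max = q_max),
            class = "diff_thresholds")
}

#' Per-gene fold change between tumor and normal means
#'
#' fc = mean(tumor) / mean(normal) on the matrix's original scale;
#' abs_fc = max(fc, 1/fc), so down-regulation by half scores the same as
#' doubling. Genes with a non-positive class mean get `fc_undefined = TRUE`
#' and are never called significant.
#'
#' @param x An [omics_matrix()] on its pre-standardization (positive) scale.
#' @return Data frame (gene, fc, abs_fc, fc_undefined).
#' @export
fold_change <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  tum <- colMeans(x$values[x$labels == "tumor", , drop = FALSE])
  nor <- colMeans(x$values[x$labels == "normal", , drop = FALSE])
  undef <- tum <= 0 | nor <= 0
  fc <- ifelse(undef, NA_real_, tum / nor)
  data.frame(gene = gene_ids(x), fc = fc, abs_fc = pmax(fc, 1 / fc),
             fc_undefined = undef, row.names = NULL, stringsAsFactors = FALSE)
}

# Levene's test (mean-centred) for two groups: one-way ANOVA F on absolute
# deviations from the group mean. Returns the p-value.
levene_p_value <- function(a, b) {
  za <- abs(a - mean(a))
  zb <- abs(b - mean(b))
  na <- length(za); nb <- length(zb)
  zbar <- (sum(za) + sum(zb)) / (na + nb)
  ssb <- na * (mean(za) - zbar)^2 + nb * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw == 0) return(if (ssb == 0) 1 else 0)
  f <- ssb / (ssw / (na + nb - 2))
  stats::pf(f, 1, na + nb - 2, lower.tail = FALSE)
}

#' Variance-gated two-sample t-test
#'
#' Levene's test (mean-centred) first checks variance homogeneity; if its
#' p-value exceeds `gate_alpha` the groups are treated as homoscedastic and
#' the pooled-variance t-test is used, otherwise Welch's t-test with
#' Welch-Satterthwaite degrees of freedom. Both are two-sided.
#'
#' @param tumor_values,normal_values Numeric vectors, >= 2 values each.
#' @param gate_alpha Levene significance gate (default 0.05).
#' @return List with `levene_p`, `test_variant` (`"pooled"`/`"welch"`),
#'   `statistic`, `df`, and `p_value`.
#' @export
variance_gated_test <- function(tumor_values, normal_values, gate_alpha = 0.05) {
  if (length(tumor_values) < 2L || length(normal_values) < 2L) {
    stop("each group needs at least 2 values")
  }
  lp <- levene_p_value(tumor_values, normal_values)
  pooled <- lp > gate_alpha
  n1 <- length(tumor_values); n2 <- length(normal_values)
  m1 <- mean(tumor_values); m2 <- mean(normal_values)
  v1 <- stats::var(tumor_values); v2 <- stats::var(normal_values)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- if (se == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    (m1 - m2) / se
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  list(levene_p = lp, test_variant = if (pooled) "pooled" else "welch",
       statistic = tstat, df = df, p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q(i) = min over j with p(j) >= p(i) of p(j) * m / rank(j), clipped to 1,
#' preserving input order. The correction universe is exactly the vector
#' supplied — in the pipeline, the TopN mutual-information survivors of one
#' modality and fold.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing entries")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Full differential table for one modality
#'
#' Combines [fold_change()] on the raw-scale matrix with the
#' [variance_gated_test()] per gene (computable on either scale; p-values
#' are scale-invariant) and [bh_fdr()] over all tested genes.
#'
#' @param raw An [omics_matrix()] on its original positive scale, restricted
#'   to the gene universe being tested (the TopN survivors).
#' @param gate_alpha Levene gate passed to [variance_gated_test()].
#' @param thresholds A [diff_thresholds()] used to set the `significant` flag.
#' @return Data frame (gene, fc, abs_fc, fc_undefined, levene_p,
#'   test_variant, p_value, q_value, significant).
#' @export
differential_table <- function(raw, gate_alpha = 0.05,
                               thresholds = diff_thresholds()) {
  stopifnot(inherits(raw, "omics_matrix"), inherits(thresholds, "diff_thresholds"))
  fc <- fold_change(raw)
  tum <- raw$values[raw$labels == "tumor", , drop = FALSE]
  nor <- raw$values[raw$labels == "normal", , drop = FALSE]
  if (nrow(tum) < 2L || nrow(nor) < 2L) {
    stop("each class needs at least 2 samples for differential testing")
  }
  tests <- lapply(seq_len(ncol(raw$values)), function(j) {
    variance_gated_test(tum[, j], nor[, j], gate_alpha)
  })
  fc$levene_p <- vapply(tests, `[[`, numeric(1), "levene_p")
  fc$test_variant <- vapply(tests, `[[`, character(1), "test_variant")
  fc$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  fc$q_value <- bh_fdr(fc$p_value)
  fc$significant <- !fc$fc_undefined &
    fc$abs_fc > thresholds$abs_fc_min &
    fc$p_value < thresholds$p_max &
    fc$q_value < thresholds$q_max
  fc$significant[is.na(fc$significant)] <- FALSE
  fc
}

#' Genes passing all differential thresholds
#'
#' A gene is called iff |FC| exceeds `abs_fc_min` AND p < `p_max` AND
#' q < `q_max`; genes with undefined fold change are excluded.
#'
#' @param records A [differential_table()] data frame.
#' @param thresholds A [diff_thresholds()].
#' @return Character vector of significant genes, lexicographically sorted.
#' @export
call_significant <- function(records, thresholds = diff_thresholds()) {
  stopifnot(inherits(thresholds, "diff_thresholds"))
  keep <- !records$fc_undefined &
    !is.na(records$abs_fc) &
    records$abs_fc > thresholds$abs_fc_min &
    records$p_value < thresholds$p_max &
    records$q_value < thresholds$q_max
  sort(records$gene[keep])
}
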