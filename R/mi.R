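# Mutual-information relevance ranking for the TopN pre-screen.
#
# Continuous gene values are quantile-binned (default 10 bins; ties can
# collapse bins) and scored with the plug-in discrete MI estimator in bits:
#   MI = sum_{x,y} p(x,y) log2[ p(x,y) / (p(x) p(y)) ],
# empty cells contributing 0. The estimator is deterministic — no kNN
# machinery, no seed sensitivity — which keeps fold-to-fold gene lists
# reproducible and lets an exhaustive oracle verify it exactly.

#' Quantile-bin a continuous vector
#'
#' Returns an integer bin index per value. Duplicate quantile breaks collapse
#' under heavy ties, so the realised bin count can be smaller than `bins`; a
#' constant vector yields a single bin (and hence MI 0).
#'
#' @param values Numeric vector.
#' @param bins Target number of bins.
#' @return Integer vector of bin indices.
#' @export
quantile_bins <- function(values, bins = 10L) {
  ux <- sort(unique(values))
  # with at most `bins` distinct values each value is its own category;
  # quantile breaks would otherwise merge minority values into neighbours
  if (length(ux) <= bins) return(match(values, ux))
  breaks <- unique(stats::quantile(values, probs = seq(0, 1, length.out = bins + 1L),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2L) return(rep(1L, length(values)))
  as.integer(cut(values, breaks = breaks, include.lowest = TRUE))
}

#' Mutual information between a gene and the class label
#'
#' @param values Numeric per-sample vector.
#' @param labels Per-sample labels with exactly two classes present.
#' @param bins Number of quantile bins for `values` (default 10).
#' @return MI in bits (>= 0).
#' @export
mi_score <- function(values, labels, bins = 10L) {
  if (length(values) < 2L || length(values) != length(labels)) {
    stop("'values' and 'labels' must be equal-length vectors with >= 2 samples")
  }
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; MI against the label is undefined")
  }
  joint <- table(quantile_bins(values, bins), labels)
  p_xy <- joint / sum(joint)
  p_x <- rowSums(p_xy)
  p_y <- colSums(p_xy)
  nz <- p_xy > 0
  sum(p_xy[nz] * log2(p_xy[nz] / outer(p_x, p_y)[nz]))
}

#' Rank genes by mutual information with the label and keep the top n
#'
#' Ties are broken lexicographically by gene symbol so ranks are
#' deterministic across platforms and runs.
#'
#' @param x An [omics_matrix()] (typically standardized training data).
#' @param n Number of top genes to retain; clamped to the gene count.
#' @param bins Quantile bin count passed to [mi_score()].
#' @return Data frame (gene, mi_bits, rank) with `rank` 1-based and
#'   `mi_bits` non-increasing, restricted to the top `min(n, n_genes)` rows.
#' @export
rank_topn <- function(x, n = 3000L, bins = 10L) {
  stopifnot(inherits(x, "omics_matrix"))
  n <- assert_count(n, "n", 1L)
  genes <- gene_ids(x)
  scores <- vapply(seq_along(genes),
                   function(j) mi_score(x$values[, j], x$labels, bins),
                   numeric(1))
  ord <- order(-scores, genes)
  out <- data.frame(gene = genes[ord], mi_bits = scores[ord],
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}
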