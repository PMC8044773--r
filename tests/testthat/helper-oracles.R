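# Independent brute-force oracles for the statistical primitives. Each takes
# a different computational route from the package implementation: explicit
# loops over definitions rather than vectorised/step-up algorithms.

# BH q-value straight from the FDR definition: q_i is the smallest
# m * t / #{p <= t} over candidate thresholds t >= p_i, clipped to 1.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Plug-in discrete MI in bits by explicit enumeration of the joint table.
oracle_mi <- function(x_cat, y_cat) {
  n <- length(x_cat)
  total <- 0
  for (bx in unique(x_cat)) {
    for (by in unique(y_cat)) {
      pxy <- sum(x_cat == bx & y_cat == by) / n
      if (pxy > 0) {
        total <- total + pxy *
          log2(pxy / ((sum(x_cat == bx) / n) * (sum(y_cat == by) / n)))
      }
    }
  }
  total
}

# Mann-Whitney AUC by exhaustive positive-negative pair counting.
oracle_auc <- function(scores, truth) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Textbook pooled-variance two-sided t-test.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Textbook Welch test with Welch-Satterthwaite df.
oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Confusion metrics evaluated directly from their defining ratios.
oracle_metrics <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = prec,
    recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  )
}
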