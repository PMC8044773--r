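# Train-set-fitted z-score standardization, applied without leakage.
#
# The transform is x' = (x - xbar) / sigma, with xbar and sigma estimated per
# gene on the TRAINING samples only, then reused verbatim on held-out data.
# sigma is the sample standard deviation (denominator n - 1). Genes that are
# constant on the fitting set are excluded (the transform is undefined for
# them and they carry no class signal); apply_standardizer() drops them and
# refuses genes it has never seen, which turns accidental leakage into a
# hard error.

#' Fit per-gene standardization parameters on a training set
#'
#' @param train An [omics_matrix()] of training samples (>= 2 samples).
#' @return A `standardizer` object: data frame `params` (gene, mean, sd) for
#'   retained genes, character vector `dropped` of zero-variance genes, and
#'   `fitted_on`, the training sample IDs.
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "omics_matrix"))
  if (nrow(train$values) < 2L) stop("need at least 2 training samples to fit a standardizer")
  mu <- colMeans(train$values)
  sdv <- sqrt(col_vars(train$values, mu))
  keep <- sdv > 0
  structure(
    list(
      params = data.frame(gene = names(mu)[keep], mean = unname(mu[keep]),
                          sd = unname(sdv[keep]), stringsAsFactors = FALSE),
      dropped = names(mu)[!keep],
      fitted_on = sample_ids(train)
    ),
    class = "standardizer"
  )
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("standardizer: %d genes (fitted on %d samples, %d zero-variance dropped)\n",
              nrow(x$params), length(x$fitted_on), length(x$dropped)))
  invisible(x)
}

#' Apply fitted standardization parameters to a matrix
#'
#' Uses the fitted means/SDs only — never statistics of `x` itself — so the
#' same object transforms training and held-out data consistently. Genes the
#' standardizer excluded are dropped; genes it has never seen raise an error.
#'
#' @param x An [omics_matrix()].
#' @param standardizer A fitted [fit_standardizer()] object.
#' @return The standardized `omics_matrix`, restricted to retained genes.
#' @export
apply_standardizer <- function(x, standardizer) {
  stopifnot(inherits(x, "omics_matrix"), inherits(standardizer, "standardizer"))
  p <- standardizer$params
  known <- c(p$gene, standardizer$dropped)
  unseen <- setdiff(gene_ids(x), known)
  if (length(unseen)) {
    stop("genes absent from the fitted standardizer: ",
         paste(utils::head(unseen, 5L), collapse = ", "))
  }
  genes <- intersect(gene_ids(x), p$gene)
  vals <- x$values[, genes, drop = FALSE]
  mu <- p$mean[match(genes, p$gene)]
  sdv <- p$sd[match(genes, p$gene)]
  vals <- sweep(sweep(vals, 2L, mu, "-"), 2L, sdv, "/")
  omics_matrix(vals, x$labels, x$modality)
}

#' Serialize standardization parameters for audit
#'
#' @param standardizer A fitted standardizer.
#' @param path Output TSV path (columns gene, mean, sd).
#' @return `path`, invisibly.
#' @export
write_standardizer <- function(standardizer, path) {
  utils::write.table(standardizer$params, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
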