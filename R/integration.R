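# Cross-modality integration: the DEG-and-DMP intersection hypothesis (a gene
# that is both differentially expressed and differentially methylated is a
# biomarker candidate), the cross-fold consensus, and the Cartesian-product
# pairing that turns two unpaired cohorts into one combined training set.

#' Intersect differential gene sets across modalities
#'
#' @param deg Character vector of differentially expressed genes.
#' @param dmp Character vector of differentially methylated genes.
#' @return The intersection in lexicographic order; an empty intersection is
#'   a valid outcome and raises a warning, not an error.
#' @export
intersect_biomarkers <- function(deg, dmp) {
  out <- sort(intersect(unique(toupper(deg)), unique(toupper(dmp))))
  if (length(out) == 0L) warning("DEG/DMP intersection is empty: no candidate biomarkers")
  out
}

#' Consensus genes across cross-validation folds
#'
#' The genes selected in EVERY fold — the pipeline's final biomarker call.
#'
#' @param fold_lists A list of gene-symbol vectors (e.g. a
#'   [load_reference_fold_genes()] object), at least one.
#' @return Character vector of consensus genes, lexicographically sorted.
#' @export
consensus_across_folds <- function(fold_lists) {
  lists <- lapply(unclass(fold_lists), function(g) unique(toupper(g)))
  if (length(lists) == 0L) stop("need at least one fold gene list")
  sort(Reduce(intersect, lists))
}

#' Cartesian-product pairing of two unpaired modality cohorts
#'
#' Every tumor expression sample is paired with every tumor methylation
#' sample, and likewise for normals, so a fold with t_e/n_e expression and
#' t_m/n_m methylation samples yields t_e*t_m + n_e*n_m combined rows. Each
#' row's feature vector is the expression block followed by the methylation
#' block, genes in the shared selected-gene order. Rows are ordered tumor
#' block first, expression-sample-major within a block.
#'
#' @param expr,meth [omics_matrix()] objects already standardized and
#'   restricted to the SAME selected-gene list (same order).
#' @return A `paired_dataset`: `features` (numeric matrix, 2 * n_genes
#'   columns), `labels` (`"tumor"`/`"normal"`), provenance vectors
#'   `expr_sample_id` / `meth_sample_id`, and `selected_genes`.
#' @export
cartesian_pair <- function(expr, meth) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(meth, "omics_matrix"))
  if (!identical(gene_ids(expr), gene_ids(meth))) {
    stop("expression and methylation matrices must share the same selected-gene list")
  }
  if (nrow(expr$values) < 1L || nrow(meth$values) < 1L) {
    stop("both matrices must contain at least one sample")
  }
  genes <- gene_ids(expr)
  one_class <- function(lab) {
    es <- sample_ids(expr)[expr$labels == lab]
    ms <- sample_ids(meth)[meth$labels == lab]
    if (length(es) == 0L || length(ms) == 0L) {
      return(list(e = character(0), m = character(0)))
    }
    list(e = rep(es, each = length(ms)), m = rep(ms, times = length(es)))
  }
  tum <- one_class("tumor")
  nor <- one_class("normal")
  e_idx <- c(tum$e, nor$e)
  m_idx <- c(tum$m, nor$m)
  features <- cbind(expr$values[e_idx, , drop = FALSE],
                    meth$values[m_idx, , drop = FALSE])
  colnames(features) <- c(paste0("expr_", genes), paste0("meth_", genes))
  rownames(features) <- NULL
  structure(
    list(
      features = features,
      labels = c(rep("tumor", length(tum$e)), rep("normal", length(nor$e))),
      expr_sample_id = e_idx,
      meth_sample_id = m_idx,
      selected_genes = genes
    ),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired_dataset: %d rows (%d tumor / %d normal), %d genes x 2 blocks\n",
              nrow(x$features), sum(x$labels == "tumor"), sum(x$labels == "normal"),
              length(x$selected_genes)))
  invisible(x)
}

#' Write a paired dataset with provenance columns
#'
#' @param x A `paired_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_paired_dataset <- function(x, path) {
  out <- data.frame(expr_sample_id = x$expr_sample_id,
                    meth_sample_id = x$meth_sample_id,
                    label = x$labels, x$features, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
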