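#' Bundled per-fold biomarker gene lists from a published gastric-cancer study
#'
#' The package ships the per-fold selected-gene lists reported by a
#' five-fold cross-validation analysis that integrated gastric-cancer gene
#' expression and DNA methylation cohorts (17/19/17/24/17 genes across the
#' five folds; eight genes recur in every fold). They serve as a reference
#' input for [consensus_across_folds()] and as a realistic example of the
#' pipeline's output shape.
#'
#' @param fold Optional single fold index in 1..5; if given, only that
#'   fold's gene vector is returned.
#' @return A `fold_gene_lists` object — a named list of upper-case,
#'   deduplicated gene-symbol vectors, one per fold — or a single character
#'   vector when `fold` is supplied.
#' @export
load_reference_fold_genes <- function(fold = NULL) {
  path <- system.file("extdata", "reference_fold_genes.tsv", package = "gcbmi",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lists <- lapply(strsplit(tab$genes, ","), function(g) unique(toupper(trimws(g))))
  names(lists) <- paste0("fold", tab$fold)
  class(lists) <- "fold_gene_lists"
  if (!is.null(fold)) {
    if (!is.numeric(fold) || length(fold) != 1L || !fold %in% seq_along(lists)) {
      stop("fold out of range: must be in 1..", length(lists))
    }
    return(lists[[fold]])
  }
  lists
}

#' @export
print.fold_gene_lists <- function(x, ...) {
  cat("fold_gene_lists:", length(x), "folds with",
      paste(vapply(x, length, integer(1)), collapse = "/"), "genes\n")
  invisible(x)
}
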