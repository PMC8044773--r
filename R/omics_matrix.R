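#' Construct an omics matrix
#'
#' The central container of the pipeline: one modality's real-valued
#' samples-by-genes table together with per-sample tumor/normal labels.
#' Internally the orientation is always samples x genes, mirroring how the
#' classifiers consume the data; readers accept GEO-style
#' features-by-samples files via an orientation flag.
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   unique row and column names.
#' @param labels Character (or factor) vector of `"tumor"`/`"normal"`, either
#'   named by sample ID or in row order of `values`.
#' @param modality `"expression"` or `"methylation"`.
#' @param allow_missing Permit `NA` cells. Only probe-level matrices awaiting
#'   [collapse_probes()] should set this; gene-level matrices must be complete.
#' @return An object of class `omics_matrix` with elements `values`,
#'   `labels` (named character), and `modality`.
#' @export
omics_matrix <- function(values, labels, modality = c("expression", "methylation"),
                         allow_missing = FALSE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have sample IDs as rownames and gene IDs as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ID: ", rownames(values)[duplicated(rownames(values))][1L])
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene ID: ", colnames(values)[duplicated(colnames(values))][1L])
  }
  label_names <- names(labels)
  labels <- stats::setNames(as.character(labels), label_names)
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(values), names(labels))
    if (length(missing)) {
      stop("missing label for sample: ", paste(missing, collapse = ", "))
    }
    labels <- labels[rownames(values)]
  } else if (length(labels) == nrow(values)) {
    names(labels) <- rownames(values)
  } else {
    stop("'labels' must be named by sample ID or match nrow(values)")
  }
  bad <- setdiff(unique(labels), c("tumor", "normal"))
  if (length(bad)) stop("labels must be 'tumor' or 'normal', found: ", paste(bad, collapse = ", "))
  if (!allow_missing && anyNA(values)) {
    stop("'values' contains missing entries; clean before constructing")
  }
  structure(
    list(values = values, labels = labels, modality = modality),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix [%s]: %d samples x %d genes (%d tumor / %d normal)\n",
    x$modality, nrow(x$values), ncol(x$values),
    sum(x$labels == "tumor"), sum(x$labels == "normal")
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample and gene identifiers
#' @param x An `omics_matrix`.
#' @return Character vector of IDs.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Restrict an omics matrix to a gene subset
#'
#' @param x An `omics_matrix`.
#' @param genes Character vector of gene IDs, all present in `x`.
#' @return The restricted `omics_matrix`, genes in the order of `genes`.
#' @export
restrict_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  omics_matrix(x$values[, genes, drop = FALSE], x$labels, x$modality)
}

#' Read a delimited omics matrix with a separate label table
#'
#' Expects UTF-8 delimited text with a header line; the first column holds
#' feature (or sample) IDs depending on `orientation`. GEO-style series
#' matrices are features x samples (`"genes_by_samples"`, the default).
#' Labels come from a separate two-column table because sample naming
#' conventions are too inconsistent to parse labels from IDs.
#'
#' @param path Path to the matrix file.
#' @param labels Data frame with columns `sample_id` and `label`, or a path
#'   to a two-column delimited file with those columns.
#' @param orientation `"genes_by_samples"` (file rows are features) or
#'   `"samples_by_genes"`.
#' @param modality `"expression"` or `"methylation"`.
#' @param sep Field separator; `"\t"` default, use `","` for CSV.
#' @param drop_incomplete Drop features containing missing values (default).
#'   Set `FALSE` for probe-level matrices that will go through
#'   [collapse_probes()], which handles nulls itself.
#' @return An [omics_matrix()] in samples x genes orientation. Features
#'   containing missing values are dropped with a message so the returned
#'   object is complete.
#' @export
read_omics_matrix <- function(path, labels,
                              orientation = c("genes_by_samples", "samples_by_genes"),
                              modality = c("expression", "methylation"),
                              sep = "\t", drop_incomplete = TRUE) {
  orientation <- match.arg(orientation)
  modality <- match.arg(modality)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"")
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row ID in ", path, ": ", ids[duplicated(ids)][1L])
  }
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)) & as.matrix(body) != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]], path))
  }
  rownames(num) <- ids
  vals <- if (orientation == "genes_by_samples") t(num) else num
  if (is.character(labels) && length(labels) == 1L) {
    labels <- utils::read.table(labels, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "label") %in% names(labels))) {
    stop("label table must have columns 'sample_id' and 'label'")
  }
  lab <- stats::setNames(as.character(labels$label), labels$sample_id)
  incomplete <- colnames(vals)[colSums(is.na(vals)) > 0L]
  if (drop_incomplete && length(incomplete)) {
    message("dropping ", length(incomplete), " feature(s) with missing values")
    vals <- vals[, setdiff(colnames(vals), incomplete), drop = FALSE]
  }
  omics_matrix(vals, lab, modality, allow_missing = !drop_incomplete)
}

#' Write an omics matrix and its label table
#'
#' Inverse of [read_omics_matrix()]: the matrix is written features x samples
#' (GEO convention) with the feature ID in the first column, plus a
#' two-column label table.
#'
#' @param x An `omics_matrix`.
#' @param path Output path for the matrix.
#' @param labels_path Optional output path for the label table.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, labels_path = NULL, sep = "\t") {
  out <- data.frame(feature_id = gene_ids(x), t(x$values), check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample_id = sample_ids(x), label = unname(x$labels)),
      labels_path, sep = sep, quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' @param path Two-column delimited file with header `probe_id`, `gene_symbol`.
#' @param sep Field separator.
#' @return Data frame with columns `probe_id` and `gene_symbol`; rows with an
#'   empty gene symbol (unmapped probes) are dropped with a message.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("probe_id", "gene_symbol") %in% names(ann))) {
    stop("annotation must have columns 'probe_id' and 'gene_symbol'")
  }
  ann$gene_symbol <- toupper(trimws(ann$gene_symbol))
  unmapped <- is.na(ann$gene_symbol) | ann$gene_symbol == ""
  if (any(unmapped)) {
    message("dropping ", sum(unmapped), " unmapped probe(s)")
    ann <- ann[!unmapped, , drop = FALSE]
  }
  ann
}

#' Collapse a probe-level matrix to gene level by the median
#'
#' Each gene's value per sample is the median over its probes (many-to-one
#' mapping allowed; an even probe count yields the midpoint of the two
#' central values). Genes left with any missing value across samples are
#' removed. Gene symbols are upper-cased so downstream set operations are
#' case-stable.
#'
#' @param x An `omics_matrix` whose columns are probe IDs.
#' @param annotation Data frame with columns `probe_id`, `gene_symbol`
#'   (see [read_probe_annotation()]).
#' @return An `omics_matrix` keyed by gene symbol.
#' @export
collapse_probes <- function(x, annotation) {
  ann <- annotation[annotation$probe_id %in% gene_ids(x), , drop = FALSE]
  if (nrow(ann) == 0L) stop("annotation maps no probe present in the matrix")
  ann$gene_symbol <- toupper(ann$gene_symbol)
  genes <- sort(unique(ann$gene_symbol))
  vals <- matrix(NA_real_, nrow = nrow(x$values), ncol = length(genes),
                 dimnames = list(sample_ids(x), genes))
  by_gene <- split(ann$probe_id, ann$gene_symbol)
  for (g in genes) {
    sub <- x$values[, by_gene[[g]], drop = FALSE]
    vals[, g] <- apply(sub, 1L, stats::median)
  }
  complete <- colSums(is.na(vals)) == 0L
  if (!any(complete)) stop("no gene has complete data after collapsing")
  if (any(!complete)) {
    message("removing ", sum(!complete), " gene(s) with null values")
  }
  omics_matrix(vals[, complete, drop = FALSE], x$labels, x$modality)
}
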