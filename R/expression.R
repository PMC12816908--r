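#' Construct a validated expression matrix
#'
#' The common substrate of every scoring step: a genes x samples (or
#' genes x cells) numeric matrix together with a value-class flag that
#' records whether entries are raw counts or continuous quantities
#' (e.g. log-TPM). Counts select the discrete (Poisson) kernel in
#' [kcdf_stats()]; continuous values select the Gaussian kernel.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, genes in rows.
#' @param gene_ids,sample_ids character vectors of unique identifiers; if
#'   `NULL`, taken from `dimnames(values)`.
#' @param value_class `"count"` or `"continuous"`. Counts must be
#'   non-negative and integral.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (dimnames set), `gene_ids`, `sample_ids`, `value_class`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              value_class = c("count", "continuous")) {
  value_class <- match.arg(value_class)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a matrix")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimension mismatch between id lists and the value matrix")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5), collapse = ", "))
  v <- if (methods::is(values, "Matrix")) values@x else values
  if (anyNA(v) || any(!is.finite(v)))
    stop("expression values must be finite and non-missing")
  if (value_class == "count") {
    if (any(v < 0)) stop("count-class matrix contains negative values")
    if (any(abs(v - round(v)) > 1e-8)) stop("count-class matrix contains non-integral values")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 value_class = value_class),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids), x$value_class))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expression_matrix`.
#' @param genes,samples character or integer/logical indices; `NULL` keeps all.
#' @return an `expression_matrix` over the selected rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, value_class = x$value_class)
}

#' Dense numeric matrix of an expression_matrix
#' @param x an `expression_matrix`.
#' @return base numeric matrix, genes x samples.
#' @export
as_matrix <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  as.matrix(x$values)
}

#' Single-cell dataset: expression plus cell annotations
#'
#' One unit of the signature-derivation framework: an expression matrix
#' over cells together with per-cell type labels and a malignant mask.
#'
#' @param expr an `expression_matrix` (columns are cells).
#' @param cell_types character vector, one non-empty label per cell.
#' @param malignant_mask logical vector, one value per cell; at least one
#'   malignant and one non-malignant cell are required (the derivation
#'   steps compare the two compartments).
#' @param dataset_id single string naming the dataset.
#' @param cancer_type optional single string.
#' @return an object of class `cell_dataset`.
#' @export
cell_dataset <- function(expr, cell_types, malignant_mask, dataset_id,
                         cancer_type = NA_character_) {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- length(expr$sample_ids)
  cell_types <- as.character(cell_types)
  malignant_mask <- as.logical(malignant_mask)
  if (length(cell_types) != n || length(malignant_mask) != n)
    stop("cell annotations must have one entry per cell")
  if (anyNA(malignant_mask)) stop("malignant_mask must not contain NA")
  if (any(!nzchar(cell_types)) || anyNA(cell_types))
    stop("cell_types labels must be non-empty")
  if (!any(malignant_mask) || all(malignant_mask))
    stop("dataset must contain both malignant and non-malignant cells")
  structure(list(expr = expr, cell_types = cell_types,
                 malignant_mask = malignant_mask,
                 dataset_id = as.character(dataset_id)[1],
                 cancer_type = as.character(cancer_type)[1]),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %s: %d genes x %d cells (%d malignant)\n",
              x$dataset_id, length(x$expr$gene_ids), length(x$expr$sample_ids),
              sum(x$malignant_mask)))
  invisible(x)
}

#' Library-size normalize counts and (optionally) log-transform
#'
#' Counts are scaled so every cell sums to `scale_factor` (default 1e4),
#' the convention used by single-cell differential-expression routines;
#' `log1p = TRUE` additionally applies the natural log1p.
#'
#' @param expr an `expression_matrix`.
#' @param scale_factor target column sum.
#' @param log1p apply `log1p` after scaling.
#' @return an `expression_matrix` with `value_class = "continuous"`.
#' @export
normalize_counts <- function(expr, scale_factor = 1e4, log1p = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- as_matrix(expr)
  libs <- colSums(v)
  libs[libs == 0] <- 1
  v <- sweep(v, 2, libs / scale_factor, "/")
  if (log1p) v <- log1p(v)
  expression_matrix(v, expr$gene_ids, expr$sample_ids, "continuous")
}
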