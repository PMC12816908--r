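#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV: genes in rows (first column = gene id), samples in columns.
#' MTX: a MatrixMarket file plus two sidecar files of gene and sample
#' identifiers, one per line.
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`.
#' @param value_class `"count"` or `"continuous"`.
#' @param genes_path,samples_path sidecar id files; defaults are
#'   `<path>.genes.tsv` / `<path>.samples.tsv` (mtx only).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            value_class = c("count", "continuous"),
                            genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  value_class <- match.arg(value_class)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    expression_matrix(m, gene_ids, colnames(d)[-1], value_class)
  } else {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    if (is.null(samples_path)) samples_path <- paste0(path, ".samples.tsv")
    if (!file.exists(genes_path) || !file.exists(samples_path))
      stop("MTX input requires gene and sample id sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    expression_matrix(m, gene_ids, sample_ids, value_class)
  }
}

#' Write an expression matrix (TSV or MTX with id sidecars)
#' @param expr an `expression_matrix`.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx"),
                             genes_path = NULL, samples_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.frame(gene = expr$gene_ids, as_matrix(expr), check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    if (is.null(samples_path)) samples_path <- paste0(path, ".samples.tsv")
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as_matrix(expr)),
                                            "generalMatrix"), "CsparseMatrix"), path)
    writeLines(expr$gene_ids, genes_path)
    writeLines(expr$sample_ids, samples_path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: set name, description (discarded),
#' then one gene symbol per field. Duplicate symbols within a line are
#' dropped with a warning; order of first occurrence is kept.
#'
#' @param path GMT file.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes removed", i, f[1]))
      genes <- unique(genes)
    }
    out[[f[1]]] <- gene_set(f[1], genes)
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets a `gene_set` or list of them.
#' @param path output file.
#' @param description value for the second GMT column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene set
#' @param name set name.
#' @param genes character vector of symbols; must be non-empty, duplicates
#'   are an error (use [read_gmt()] for forgiving parsing). Symbols are
#'   matched case-sensitively everywhere in the package; no alias resolution.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene set must be non-empty")
  if (anyDuplicated(genes)) stop("gene set contains duplicates")
  structure(list(name = as.character(name)[1], genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a segmented copy-number table (SEG)
#'
#' Expected columns: sample, chromosome, start, end, log2_ratio, with
#' 1-based inclusive coordinates on disk. Internally the package uses
#' 0-based half-open intervals; conversion happens here, at the I/O
#' boundary, and is reversed by [write_segments()].
#'
#' @param path tab-separated SEG file with a header.
#' @return a `data.frame` of class `segment_table` with columns
#'   `sample`, `chrom`, `start`, `end` (0-based half-open), `log2_ratio`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("sample", "chromosome", "start", "end", "log2_ratio")
  if (!all(need %in% names(d)))
    stop("SEG file must have columns: ", paste(need, collapse = ", "))
  segment_table(data.frame(sample = as.character(d$sample),
                           chrom = as.character(d$chromosome),
                           start = as.numeric(d$start) - 1,
                           end = as.numeric(d$end),
                           log2_ratio = as.numeric(d$log2_ratio),
                           stringsAsFactors = FALSE))
}

#' Validate an internal (0-based half-open) segment table
#' @param d data.frame with columns sample, chrom, start, end, log2_ratio
#'   in 0-based half-open coordinates.
#' @return the validated `segment_table`.
#' @export
segment_table <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(d))) stop("missing segment columns")
  if (any(d$end <= d$start)) stop("segments must satisfy end > start")
  if (any(!is.finite(d$log2_ratio))) stop("log2_ratio must be finite")
  # per sample x chromosome, segments must not overlap
  if (nrow(d) > 1) {
    key <- split(seq_len(nrow(d)), paste(d$sample, d$chrom))
    for (idx in key) {
      if (length(idx) < 2) next
      o <- idx[order(d$start[idx])]
      if (any(d$start[o][-1] < d$end[o][-length(o)]))
        stop("overlapping segments within one sample/chromosome")
    }
  }
  class(d) <- c("segment_table", "data.frame")
  d
}

#' Write a segment table back to SEG (1-based inclusive)
#' @param seg a `segment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, path) {
  d <- data.frame(sample = seg$sample, chromosome = seg$chrom,
                  start = seg$start + 1, end = seg$end,
                  log2_ratio = seg$log2_ratio)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Required columns: `patient`, `time` (> 0), `event` (0/1). Optional:
#' `stage` (I-IV, case-insensitive roman or 1-4) and `endpoint`
#' (e.g. OS, PFI, DFI, DSS).
#'
#' @param path TSV with a header.
#' @return a `data.frame` of class `survival_table`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  survival_table(d)
}

#' Validate a survival table
#' @param d data.frame with patient, time, event (and optional stage, endpoint).
#' @return validated `survival_table`.
#' @export
survival_table <- function(d) {
  need <- c("patient", "time", "event")
  if (!all(need %in% names(d))) stop("survival table needs columns patient, time, event")
  d$time <- as.numeric(d$time)
  if (any(!is.finite(d$time)) || any(d$time <= 0)) stop("time must be > 0")
  if (!all(d$event %in% c(0, 1))) stop("event must be 0 or 1")
  d$event <- as.integer(d$event)
  if (anyDuplicated(d$patient)) stop("duplicate patient identifiers")
  if ("stage" %in% names(d)) {
    d$stage <- parse_stage(d$stage)
  }
  class(d) <- c("survival_table", "data.frame")
  d
}

parse_stage <- function(x) {
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% 1:4))) stop("stage must be I-IV / 1-4")
    return(as.integer(x))
  }
  map <- c(I = 1L, II = 2L, III = 3L, IV = 4L,
           "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L)
  v <- map[toupper(trimws(as.character(x)))]
  if (any(is.na(v) & !is.na(x) & nzchar(trimws(as.character(x)))))
    stop("stage must be I-IV / 1-4")
  unname(v)
}

#' Write a survival table
#' @param surv a `survival_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x screen score matrix
#'
#' TSV with gene ids in the first column and one numeric column per
#' screen; empty cells become `NA` (missing values are allowed, genes
#' with no observation at all are rejected).
#'
#' @param path TSV file.
#' @return numeric matrix of class `screen_matrix` (genes x screens).
#' @export
read_screens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.na(m) & !is.finite(m))) stop("non-numeric screen score")
  rownames(m) <- as.character(d[[1]])
  screen_matrix(m)
}

#' Validate a screen matrix
#' @param m numeric matrix, genes x screens, NA allowed.
#' @return `screen_matrix`.
#' @export
screen_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("screen matrix needs dimnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate screen ids")
  if (any(rowSums(!is.na(m)) == 0))
    stop("gene with no non-missing score: ",
         paste(utils::head(rownames(m)[rowSums(!is.na(m)) == 0], 5), collapse = ", "))
  class(m) <- c("screen_matrix", class(m))
  m
}

#' Read a chromosome-arm annotation table
#'
#' Columns: `chrom`, `arm` (p/q), `start`, `end`, 1-based inclusive on
#' disk, converted to 0-based half-open like [read_segments()].
#'
#' @param path TSV file.
#' @return `arm_model` data.frame.
#' @export
read_arm_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  arm_model(data.frame(chrom = as.character(d$chrom), arm = as.character(d$arm),
                       start = as.numeric(d$start) - 1, end = as.numeric(d$end),
                       stringsAsFactors = FALSE))
}

#' Validate an arm model (0-based half-open internal coordinates)
#' @param d data.frame with chrom, arm, start, end.
#' @return `arm_model`.
#' @export
arm_model <- function(d) {
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(d))) stop("arm model needs columns chrom, arm, start, end")
  if (!all(d$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  if (any(d$end <= d$start)) stop("arm intervals must satisfy end > start")
  if (anyDuplicated(paste(d$chrom, d$arm))) stop("duplicate chromosome arm")
  for (ch in unique(d$chrom)) {
    s <- d[d$chrom == ch, ]
    if (nrow(s) == 2) {
      s <- s[order(s$start), ]
      if (s$end[1] > s$start[2]) stop("arms overlap on ", ch)
    }
  }
  class(d) <- c("arm_model", "data.frame")
  d
}

#' Read an analysis configuration (YAML)
#'
#' Validates the few keys the pipeline consumes: `seed` (non-negative
#' integer) and any of the derivation thresholds (see
#' [derivation_thresholds()]), which must lie in their legal ranges.
#' Unknown keys are kept untouched.
#'
#' @param path YAML file.
#' @return named list of class `analysis_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
      stop("seed must be a non-negative integer")
    cfg$seed <- as.integer(cfg$seed)
  }
  th_keys <- intersect(names(cfg),
                       c("cor_min", "fdr_max", "logfc_min", "min_expr_frac", "geo_mean_min"))
  if (length(th_keys)) {
    th <- do.call(derivation_thresholds, cfg[th_keys])  # range validation
    cfg[names(th)] <- th
  }
  structure(cfg, class = c("analysis_config", "list"))
}
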