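#' Thresholds of the four-step signature-derivation framework
#'
#' Defaults are the framework's published operating point: positively
#' hypoxia-correlated genes (`cor_min = 0`) at BH `fdr_max = 0.05`,
#' malignant-up genes at natural-log fold change `logfc_min = 0.25` with
#' detection in at least `min_expr_frac = 0.10` of cells of some cell
#' type, and a cross-dataset geometric-mean correlation above
#' `geo_mean_min = 0.4`.
#'
#' @param cor_min minimum Spearman correlation (exclusive).
#' @param fdr_max BH-adjusted q-value cutoff, in (0, 1).
#' @param logfc_min log fold-change cutoff (exclusive), natural log.
#' @param min_expr_frac minimum detection fraction, in \[0, 1\].
#' @param geo_mean_min geometric-mean correlation cutoff (exclusive).
#' @return named list of class `derivation_thresholds`.
#' @export
derivation_thresholds <- function(cor_min = 0, fdr_max = 0.05, logfc_min = 0.25,
                                  min_expr_frac = 0.10, geo_mean_min = 0.4) {
  if (fdr_max <= 0 || fdr_max >= 1) stop("fdr_max must be in (0, 1)")
  if (min_expr_frac < 0 || min_expr_frac > 1) stop("min_expr_frac must be in [0, 1]")
  if (cor_min < -1 || cor_min >= 1) stop("cor_min must be in [-1, 1)")
  if (geo_mean_min < 0 || geo_mean_min >= 1) stop("geo_mean_min must be in [0, 1)")
  if (logfc_min < 0) stop("logfc_min must be >= 0")
  structure(list(cor_min = cor_min, fdr_max = fdr_max, logfc_min = logfc_min,
                 min_expr_frac = min_expr_frac, geo_mean_min = geo_mean_min),
            class = c("derivation_thresholds", "list"))
}

# Spearman rho (tie-corrected via average ranks) of every row of `m`
# against `y`, with a t-approximation p-value. Constant rows yield NA.
.row_spearman <- function(m, y) {
  n <- length(y)
  ry <- rank(y)
  rm <- t(apply(m, 1, rank))
  ry_c <- ry - mean(ry)
  rm_c <- rm - rowMeans(rm)
  denom <- sqrt(rowSums(rm_c^2) * sum(ry_c^2))
  rho <- as.vector(rm_c %*% ry_c) / denom
  rho[!is.finite(rho)] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(p, 1)
  list(rho = rho, p = p)
}

#' Hypoxia scores for the malignant cells of one dataset
#'
#' Applies the single-sample scoring engine to the malignant-cell
#' submatrix only (non-malignant cells do not appear in the output).
#'
#' @param ds a [cell_dataset()].
#' @param seed_set a [gene_set()] of reference hypoxia genes; must
#'   intersect the dataset's genes.
#' @param method scoring method, see [hyp_score()].
#' @return a `score_vector` over the malignant cells.
#' @export
malignant_hypoxia_scores <- function(ds, seed_set, method = "gsva") {
  stopifnot(inherits(ds, "cell_dataset"))
  if (sum(ds$malignant_mask) < 3)
    stop("need at least 3 malignant cells to score")
  if (!any(seed_set$genes %in% ds$expr$gene_ids))
    stop("seed set does not intersect dataset genes")
  sub <- subset_expression(ds$expr, samples = which(ds$malignant_mask))
  hyp_score(sub, seed_set, method = method)$scores
}

#' Hypoxia-correlated genes within malignant cells (step 2)
#'
#' Spearman correlation of each gene's (normalized) expression with the
#' per-malignant-cell hypoxia score; genes with `rho > cor_min` and BH
#' `q < fdr_max` are kept (`use_fdr = FALSE` thresholds the raw p
#' instead). Constant genes have undefined correlation and are excluded
#' (counted in the `n_constant` attribute).
#'
#' @param ds a [cell_dataset()].
#' @param scores `score_vector` from [malignant_hypoxia_scores()].
#' @param th [derivation_thresholds()].
#' @param use_fdr threshold BH q (default) rather than raw p.
#' @return data.frame (gene, rho, p, q) of the retained genes.
#' @export
correlated_genes_Gx <- function(ds, scores, th = derivation_thresholds(),
                                use_fdr = TRUE) {
  stopifnot(inherits(ds, "cell_dataset"))
  cells <- ds$expr$sample_ids[ds$malignant_mask]
  if (!setequal(scores$sample_ids, cells))
    stop("scores are not aligned to the malignant cells of this dataset")
  norm <- if (ds$expr$value_class == "count") normalize_counts(ds$expr) else ds$expr
  m <- as_matrix(norm)[, cells, drop = FALSE]
  sp <- .row_spearman(m, scores$scores[cells])
  ok <- !is.na(sp$rho)
  res <- data.frame(gene = ds$expr$gene_ids[ok], rho = sp$rho[ok], p = sp$p[ok],
                    stringsAsFactors = FALSE)
  res$q <- stats::p.adjust(res$p, method = "BH")
  crit <- if (use_fdr) res$q else res$p
  out <- res[res$rho > th$cor_min & crit < th$fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_constant") <- sum(!ok)
  out
}

# Vectorized two-sided Wilcoxon rank-sum across rows: normal approximation
# with tie correction for large groups, exact enumeration (via group_test)
# when both groups have <= 10 observations.
.row_ranksum <- function(m, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  if (n1 <= 10 && n2 <= 10) {
    p <- apply(m, 1, function(v)
      group_test(v, ifelse(in_group, "a", "b"), test = "wilcoxon")$p.value)
    return(p)
  }
  p <- apply(m, 1, function(v) {
    r <- rank(v)
    w <- sum(r[in_group])
    mu <- n1 * (n + 1) / 2
    ties <- table(v)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    2 * stats::pnorm(-abs(w - mu) / sqrt(sig2))
  })
  pmin(p, 1)
}

#' Malignant-upregulated genes (step 3)
#'
#' Differential expression of malignant versus all other cells pooled
#' (`one_vs_each = TRUE` instead requires significance against every
#' other cell type separately). Expression is library-size normalized to
#' 1e4 per cell; the fold change is
#' `ln(mean(norm) + 1 | malignant) - ln(mean(norm) + 1 | rest)`
#' (`base2 = TRUE` switches to log2). Kept genes need
#' `logFC > logfc_min`, BH `q < fdr_max` (Wilcoxon rank-sum), and
#' detection in at least `min_expr_frac` of the cells of one or more
#' cell types.
#'
#' @inheritParams correlated_genes_Gx
#' @param one_vs_each compare malignant against each other cell type
#'   instead of the pooled rest.
#' @param base2 report log2 rather than natural-log fold changes.
#' @return data.frame (gene, logfc, p, q, max_detect) of retained genes.
#' @export
malignant_up_genes_Gy <- function(ds, th = derivation_thresholds(),
                                  use_fdr = TRUE, one_vs_each = FALSE,
                                  base2 = FALSE) {
  stopifnot(inherits(ds, "cell_dataset"))
  mal <- ds$malignant_mask
  if (!any(mal) || all(mal)) stop("both cell groups must be non-empty")
  raw <- as_matrix(ds$expr)
  norm <- as_matrix(normalize_counts(ds$expr, log1p = FALSE))
  logf <- if (base2) log2 else log
  mu1 <- rowMeans(norm[, mal, drop = FALSE])
  lgm <- as_matrix(normalize_counts(ds$expr, log1p = TRUE))

  if (one_vs_each) {
    others <- unique(ds$cell_types[!mal])
    pmat <- sapply(others, function(ct) {
      sel <- mal | (!mal & ds$cell_types == ct)
      .row_ranksum(lgm[, sel, drop = FALSE], mal[sel])
    })
    p <- apply(as.matrix(pmat), 1, max)   # must beat every other type
    mu0 <- rowMeans(norm[, !mal, drop = FALSE])
  } else {
    p <- .row_ranksum(lgm, mal)
    mu0 <- rowMeans(norm[, !mal, drop = FALSE])
  }
  logfc <- logf(mu1 + 1) - logf(mu0 + 1)
  detect <- sapply(split(seq_len(ncol(raw)), ds$cell_types), function(idx)
    rowMeans(raw[, idx, drop = FALSE] > 0))
  max_detect <- apply(as.matrix(detect), 1, max)
  q <- stats::p.adjust(p, method = "BH")
  crit <- if (use_fdr) q else p
  keep <- logfc > th$logfc_min & crit < th$fdr_max & max_detect >= th$min_expr_frac
  out <- data.frame(gene = ds$expr$gene_ids, logfc = logfc, p = p, q = q,
                    max_detect = max_detect, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect the hypoxia-correlated and malignant-up gene sets (step 3b)
#'
#' @param gx data.frame from [correlated_genes_Gx()].
#' @param gy data.frame from [malignant_up_genes_Gy()].
#' @return data.frame (gene, rho, q) carrying each intersected gene's
#'   correlation from `gx`.
#' @export
intersect_Gn <- function(gx, gy) {
  keep <- gx$gene %in% gy$gene
  out <- gx[keep, c("gene", "rho", "q"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-dataset gene sets into the final signature (step 4)
#'
#' For every gene, the geometric mean of its Spearman correlations over
#' the datasets whose intersected set contains it (membership guarantees
#' positive correlations, so the geometric mean is well defined). Genes
#' with geometric mean strictly greater than `geo_mean_min` and support
#' in at least `min_support` datasets form the signature.
#'
#' @param gn_list list of data.frames from [intersect_Gn()], one per dataset.
#' @param th [derivation_thresholds()].
#' @param min_support minimum number of supporting datasets.
#' @param name name given to the resulting [gene_set()].
#' @return list of class `derivation_result`: `aggregate` (data.frame of
#'   gene, geo_mean, support), `signature` (a `gene_set`, or `NULL` when
#'   empty), `gn_list`.
#' @export
aggregate_signature <- function(gn_list, th = derivation_thresholds(),
                                min_support = 2, name = "hypoxia_signature") {
  if (length(gn_list) < 1) stop("need at least one dataset")
  all_rows <- do.call(rbind, lapply(gn_list, function(g) g[, c("gene", "rho")]))
  if (any(all_rows$rho <= 0))
    stop("internal invariant violated: non-positive correlation reached aggregation")
  sp <- split(all_rows$rho, all_rows$gene)
  agg <- data.frame(gene = names(sp),
                    geo_mean = vapply(sp, function(r) exp(mean(log(r))), numeric(1)),
                    support = lengths(sp), stringsAsFactors = FALSE)
  agg <- agg[order(-agg$geo_mean), , drop = FALSE]
  rownames(agg) <- NULL
  keep <- agg$geo_mean > th$geo_mean_min & agg$support >= min_support
  sig <- if (any(keep)) gene_set(name, agg$gene[keep]) else NULL
  structure(list(aggregate = agg, signature = sig, gn_list = gn_list),
            class = "derivation_result")
}

#' @export
print.derivation_result <- function(x, ...) {
  nsig <- if (is.null(x$signature)) 0L else length(x$signature$genes)
  cat(sprintf("<derivation_result> %d datasets, %d candidate genes, %d signature genes\n",
              length(x$gn_list), nrow(x$aggregate), nsig))
  invisible(x)
}

#' Run the full four-step derivation across datasets
#'
#' Per dataset: score malignant cells against the seed hypoxia set,
#' select hypoxia-correlated genes and malignant-up genes, intersect;
#' then aggregate across datasets by geometric-mean correlation.
#'
#' @param datasets list of [cell_dataset()] objects.
#' @param seed_set reference hypoxia [gene_set()].
#' @param th [derivation_thresholds()].
#' @param min_support minimum supporting datasets for a signature gene.
#' @param method scoring method for the seed scores.
#' @param use_fdr see [correlated_genes_Gx()].
#' @return a `derivation_result` with a `per_dataset` element holding
#'   each dataset's Gx/Gy/Gn tables.
#' @export
derive_signature <- function(datasets, seed_set, th = derivation_thresholds(),
                             min_support = 2, method = "gsva", use_fdr = TRUE) {
  per <- lapply(datasets, function(ds) {
    sc <- malignant_hypoxia_scores(ds, seed_set, method = method)
    gx <- correlated_genes_Gx(ds, sc, th, use_fdr = use_fdr)
    gy <- malignant_up_genes_Gy(ds, th, use_fdr = use_fdr)
    list(dataset_id = ds$dataset_id, Gx = gx, Gy = gy, Gn = intersect_Gn(gx, gy))
  })
  res <- aggregate_signature(lapply(per, `[[`, "Gn"), th, min_support)
  res$per_dataset <- per
  res
}
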