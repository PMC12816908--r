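#' Kernel-CDF expression-level statistics
#'
#' First stage of the single-sample scoring engine. For every gene, each
#' sample's value is scored by a kernel estimate of its cumulative
#' distribution across all samples of that gene, centered to
#' \eqn{(-1/2, 1/2)}. Continuous matrices use a Gaussian kernel with a
#' per-gene bandwidth of SD/4 (floored at 1e-8 so constant genes are
#' well-defined); count matrices use a discrete Poisson kernel
#' (\eqn{\lambda = x_{ik} + 0.5}). The statistic is non-decreasing in the
#' raw value within each gene, so any strictly increasing per-gene
#' transform of the input leaves downstream scores unchanged.
#'
#' @param expr an [expression_matrix()]; at least 3 samples (the
#'   cross-sample density is undefined below that).
#' @return list of class `gene_stat_matrix` with `gene_ids`, `sample_ids`
#'   and `stat` (genes x samples).
#' @export
kcdf_stats <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- as_matrix(expr)
  if (ncol(x) < 3)
    stop("kernel CDF statistics require at least 3 samples")
  if (expr$value_class == "continuous") {
    h <- pmax(apply(x, 1, stats::sd) / 4, 1e-8)
    z <- .kcdf_gauss_cpp(x, h)
  } else {
    z <- .kcdf_pois_cpp(x, 0.5)
  }
  dimnames(z) <- dimnames(x)
  structure(list(gene_ids = expr$gene_ids, sample_ids = expr$sample_ids, stat = z),
            class = "gene_stat_matrix")
}

# Deterministic gene ordering for one sample: decreasing statistic,
# ties broken by gene id (lexicographic, C locale).
.rank_order <- function(stat_col, gene_ids) {
  order(-stat_col, gene_ids, method = "radix")
}

#' Single-sample enrichment score from a weighted KS-like walk
#'
#' For each sample, genes are ranked by their statistic (decreasing; ties
#' broken by gene id for determinism) and a running sum is walked down the
#' list: positions of gene-set members step up proportionally to their
#' weight raised to `tau` (normalized over members), other positions step
#' down by \eqn{1/(p - m)}. Method `"gsva"` weights each member by the
#' centered rank \eqn{|(p+1)/2 - r|} and reports the sum of the walk's
#' largest positive and largest negative deviations (the cited
#' algorithm's default convention; bounded in \eqn{[-1, 1]}, exactly
#' antisymmetric under rank reversal and centered at zero for random
#' sets); `"ssgsea"` weights by the ascending-value rank
#' \eqn{p - r + 1} and reports the mean deviation (the normalized
#' integral of the walk).
#'
#' @param stats a `gene_stat_matrix` from [kcdf_stats()], or any numeric
#'   genes x samples matrix of per-sample ranking statistics (e.g. raw
#'   expression for the ssgsea method).
#' @param set a [gene_set()]. Must hit at least one but not all genes.
#' @param method `"gsva"` or `"ssgsea"`.
#' @param tau non-negative weight exponent (default 1; 0 gives the
#'   unweighted two-sample KS walk).
#' @return list of class `score_vector`: `sample_ids`, `scores`, `method`.
#' @export
enrichment_score <- function(stats, set, method = c("gsva", "ssgsea"), tau = 1) {
  method <- match.arg(method)
  if (tau < 0) stop("tau must be >= 0")
  stopifnot(inherits(set, "gene_set"))
  if (inherits(stats, "gene_stat_matrix")) {
    m <- stats$stat
  } else {
    m <- as.matrix(stats)
    if (is.null(rownames(m))) stop("statistic matrix must have gene row names")
  }
  gene_ids <- rownames(m)
  hit <- gene_ids %in% set$genes
  p <- length(gene_ids); nm <- sum(hit)
  if (nm == 0) stop("gene set does not intersect the expression genes")
  if (nm == p) stop("gene set covers every gene; miss step undefined")
  scores <- vapply(seq_len(ncol(m)), function(j) {
    ord <- .rank_order(m[, j], gene_ids)
    hit_o <- hit[ord]
    r <- seq_len(p)                       # rank position after ordering
    w <- if (method == "gsva") abs((p + 1) / 2 - r) else (p - r + 1)
    w <- w^tau
    step <- ifelse(hit_o, w / sum(w[hit_o]), -1 / (p - nm))
    walk <- cumsum(step)
    if (method == "gsva") max(c(walk, 0)) + min(c(walk, 0)) else mean(walk)
  }, numeric(1))
  structure(list(sample_ids = colnames(m), scores = stats::setNames(scores, colnames(m)),
                 method = method),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s, %d samples; range [%.3f, %.3f]\n",
              x$method, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Hypoxia score and high/low grouping for each sample
#'
#' Composes [kcdf_stats()] and [enrichment_score()]: scores every sample
#' against the supplied hypoxia gene set, then dichotomizes at the cohort
#' median. A sample is labeled `"high"` only when its score is strictly
#' greater than the median (ties fall to `"low"`), so an all-equal score
#' vector yields an all-`"low"` cohort.
#'
#' @param expr an [expression_matrix()].
#' @param set a [gene_set()], e.g. a hypoxia signature.
#' @param method `"gsva"` (kernel-CDF rank statistic) or `"ssgsea"`
#'   (expression-rank statistic).
#' @param tau weight exponent passed to [enrichment_score()].
#' @return list of class `hyp_score_result`: `gene_set`, `scores` (a
#'   `score_vector`), `groups` (named factor, levels low/high).
#' @export
hyp_score <- function(expr, set, method = c("gsva", "ssgsea"), tau = 1) {
  method <- match.arg(method)
  stats <- if (method == "gsva") {
    z <- kcdf_stats(expr)
    # convert the kernel CDF to centered within-gene ranks: scores then
    # depend on expression only through per-gene ranks, so any strictly
    # increasing per-gene transform of the input leaves them unchanged
    n <- ncol(z$stat)
    z$stat <- (t(apply(z$stat, 1, rank)) - (n + 1) / 2) / n
    dimnames(z$stat) <- list(expr$gene_ids, expr$sample_ids)
    z
  } else {
    m <- as_matrix(expr)
    # ssgsea ranks raw expression within each sample
    structure(list(gene_ids = expr$gene_ids, sample_ids = expr$sample_ids, stat = m),
              class = "gene_stat_matrix")
  }
  sv <- enrichment_score(stats, set, method = method, tau = tau)
  med <- stats::median(sv$scores)
  groups <- factor(ifelse(sv$scores > med, "high", "low"), levels = c("low", "high"))
  names(groups) <- sv$sample_ids
  structure(list(gene_set = set, scores = sv, groups = groups),
            class = "hyp_score_result")
}

#' @export
print.hyp_score_result <- function(x, ...) {
  cat(sprintf("<hyp_score_result> set '%s' (%d genes), %d samples, %d high / %d low\n",
              x$gene_set$name, length(x$gene_set$genes), length(x$groups),
              sum(x$groups == "high"), sum(x$groups == "low")))
  invisible(x)
}

#' Median split of a numeric score into high/low labels
#'
#' Shared tie convention of the whole package: strictly greater than the
#' median is `"high"`, everything else `"low"`.
#'
#' @param x named numeric vector.
#' @return factor with levels `low`, `high`, same names as `x`.
#' @export
median_split <- function(x) {
  g <- factor(ifelse(x > stats::median(x), "high", "low"), levels = c("low", "high"))
  names(g) <- names(x)
  g
}
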