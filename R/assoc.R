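#' Tie-corrected Spearman correlation with a p-value
#'
#' Correlation of average ranks; two-sided p by exact permutation
#' enumeration for n <= 10 (valid under ties) and by the t approximation
#' otherwise.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `rho` and `p.value` (`rho = NA` when either input
#'   is constant).
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be paired")
  if (n < 3) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p.value = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- .spearman_exact_p_cpp(rx, ry)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  list(rho = rho, p.value = p)
}

#' Spearman association of many features with a score
#'
#' One row per feature: tie-corrected rho, two-sided p, BH q and the
#' number of paired observations. Constant features are flagged
#' (`rho = NA`) and excluded from the BH adjustment.
#'
#' @param features samples x features numeric matrix or data.frame.
#' @param score named numeric vector or a `score_vector`; names must
#'   match the feature rows.
#' @return data.frame of class `assoc_table` (feature, rho, p, q, n).
#' @export
spearman_assoc <- function(features, score) {
  if (inherits(score, "score_vector")) score <- score$scores
  features <- as.matrix(features)
  if (is.null(rownames(features)) || is.null(names(score)))
    stop("features and score must be named by sample")
  common <- intersect(rownames(features), names(score))
  if (length(common) < 3) stop("need at least 3 paired samples")
  features <- features[common, , drop = FALSE]
  score <- score[common]
  res <- lapply(seq_len(ncol(features)), function(j)
    spearman_test(features[, j], score))
  out <- data.frame(feature = colnames(features),
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p = vapply(res, `[[`, numeric(1), "p.value"),
                    n = length(common), stringsAsFactors = FALSE)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out <- out[, c("feature", "rho", "p", "q", "n")]
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Total mutation burden per sample
#'
#' Counts mutation records per sample; samples listed in `samples` but
#' absent from the records get 0.
#'
#' @param record_samples character vector: the sample id of each
#'   mutation record (one entry per event).
#' @param samples optional universe of sample ids.
#' @return named integer vector of per-sample mutation counts.
#' @export
mutation_load <- function(record_samples, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(record_samples))
  tab <- table(factor(record_samples, levels = samples))
  stats::setNames(as.integer(tab), samples)
}

#' Quadrant labels from median splits of hypoxia score and TMB
#'
#' Samples are split at the median of each axis (strictly greater than
#' the median = high, the shared tie rule) and labeled HPHT, HPLT, LPHT
#' or LPLT (high/low hypoxia x high/low tumor mutational burden). Labels
#' depend only on ranks, so any strictly monotone transform of either
#' axis leaves them unchanged.
#'
#' @param score named numeric hypoxia scores or a `score_vector`.
#' @param tmb named numeric per-sample mutation burden; must cover the
#'   same samples.
#' @return named factor with levels HPHT, HPLT, LPHT, LPLT.
#' @export
median_quadrants <- function(score, tmb) {
  if (inherits(score, "score_vector")) score <- score$scores
  if (!setequal(names(score), names(tmb)))
    stop("score and TMB must cover the same samples")
  tmb <- tmb[names(score)]
  hyp_high <- score > stats::median(score)
  tmb_high <- tmb > stats::median(tmb)
  lab <- paste0(ifelse(hyp_high, "HP", "LP"), ifelse(tmb_high, "HT", "LT"))
  factor(stats::setNames(lab, names(score)),
         levels = c("HPHT", "HPLT", "LPHT", "LPLT"))
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (handles ties exactly); used when both groups are small.
.ranksum_exact <- function(r, n1) {
  n <- length(r)
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  w <- sum(r[seq_len(n1)])           # caller puts group 1 first
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

#' Two-group and multi-group tests used across the pipeline
#'
#' `"wilcoxon"`: two-sided rank-sum; exact enumeration over all group
#' assignments when both groups have at most 10 observations (remains
#' exact under ties), normal approximation with tie correction otherwise.
#' `"kruskal"`: Kruskal-Wallis ([stats::kruskal.test()]). `"paired_t"`:
#' paired t test; `values` must hold the two equal-length groups in
#' pairing order. `"chisq"`: chi-square on a contingency table built
#' from `values` and `labels` (or pass a table/matrix as `values`),
#' without continuity correction unless `correct = TRUE`.
#'
#' @param values numeric vector (or contingency table for chisq).
#' @param labels group labels aligned to `values` (ignored when `values`
#'   is already a table).
#' @param test one of `"wilcoxon"`, `"kruskal"`, `"paired_t"`, `"chisq"`.
#' @param correct continuity correction for the chi-square test.
#' @return list with `statistic` and `p.value`.
#' @export
group_test <- function(values, labels = NULL,
                       test = c("wilcoxon", "kruskal", "paired_t", "chisq"),
                       correct = FALSE) {
  test <- match.arg(test)
  if (test == "chisq") {
    tab <- if (is.matrix(values) || is.table(values)) as.table(as.matrix(values))
           else table(values, labels)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value))
  }
  labels <- as.character(labels)
  if (length(labels) != length(values)) stop("labels must align with values")
  groups <- split(values, labels)
  if (any(lengths(groups) == 0) || length(groups) < 2) stop("need non-empty groups")
  if (test == "kruskal") {
    ht <- stats::kruskal.test(values, factor(labels))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value))
  }
  if (test == "paired_t") {
    if (length(groups) != 2 || length(groups[[1]]) != length(groups[[2]]))
      stop("paired t test needs two equal-length groups")
    d <- groups[[1]] - groups[[2]]
    if (stats::sd(d) == 0)
      return(list(statistic = 0, p.value = if (all(d == 0)) 1 else NA_real_))
    ht <- stats::t.test(groups[[1]], groups[[2]], paired = TRUE)
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value))
  }
  # wilcoxon rank-sum
  if (length(groups) != 2) stop("rank-sum test needs exactly two groups")
  x <- groups[[1]]; y <- groups[[2]]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= 10 && n2 <= 10) {
    p <- .ranksum_exact(r, n1)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (sig2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs(w - mu) / sqrt(sig2)))
  }
  list(statistic = w - n1 * (n1 + 1) / 2, p.value = p)  # Mann-Whitney U
}

#' Area under the ROC curve by the rank (Mann-Whitney) identity
#'
#' @param scores numeric predictor.
#' @param labels binary labels (0/1, logical, or a two-level factor where
#'   the second level is the positive class); both classes must occur.
#' @return AUC in \[0, 1\]; ties between classes count 1/2.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(labels) != length(scores)) stop("scores and labels must align")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
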