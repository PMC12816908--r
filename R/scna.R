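#' Bin a log2 copy-number ratio into an event score
#'
#' Exact bin mapping: 2 if log2 >= 1; 1 if 0.25 <= log2 < 1; 0 if
#' -0.25 <= log2 < 0.25; -1 if -1 <= log2 < -0.25; -2 if log2 < -1.
#' Each inner boundary belongs to the bin whose inequality is inclusive
#' (so -0.25 scores 0 and 0.25 scores 1).
#'
#' @param log2_ratio numeric vector of finite log2 ratios.
#' @return integer vector in \{-2, -1, 0, 1, 2\}.
#' @export
score_event <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio))) stop("log2 ratio must be finite")
  ifelse(log2_ratio >= 1, 2L,
  ifelse(log2_ratio >= 0.25, 1L,
  ifelse(log2_ratio >= -0.25, 0L,
  ifelse(log2_ratio >= -1, -1L, -2L))))
}

# Overlap (in bases) of segments with one 0-based half-open interval.
.overlap <- function(start, end, a_start, a_end) {
  pmax(0, pmin(end, a_end) - pmax(start, a_start))
}

#' Classify copy-number events as focal, arm or chromosome level
#'
#' An event is broad when its overlap with some chromosome arm exceeds
#' 70% of that arm's length (strictly); otherwise it is focal. On a
#' chromosome where both arms carry broad events and the (length-weighted
#' merged) bin scores of the two arms share the same non-zero sign, all
#' broad events on that chromosome are chromosome-level; otherwise they
#' are arm-level.
#'
#' @param seg a [segment_table()] for one sample.
#' @param arms an [arm_model()].
#' @param broad_frac broadness threshold as a fraction of arm length
#'   (default 0.70, strict >).
#' @param same_bin require identical bins (not just the same sign) for
#'   chromosome-level classification.
#' @return `seg` with added columns `score`, `level`
#'   (focal/arm/chromosome) and `broad_arm` (the arm carrying a broad
#'   event, `NA` for focal events).
#' @export
classify_events <- function(seg, arms, broad_frac = 0.70, same_bin = FALSE) {
  stopifnot(inherits(seg, "segment_table"), inherits(arms, "arm_model"))
  if (!all(seg$chrom %in% arms$chrom))
    stop("segment on unknown chromosome: ",
         paste(unique(setdiff(seg$chrom, arms$chrom)), collapse = ", "))
  seg <- as.data.frame(seg)
  seg$score <- score_event(seg$log2_ratio)
  seg$level <- "focal"
  seg$broad_arm <- NA_character_
  for (i in seq_len(nrow(seg))) {
    a <- arms[arms$chrom == seg$chrom[i], , drop = FALSE]
    ov <- .overlap(seg$start[i], seg$end[i], a$start, a$end)
    frac <- ov / (a$end - a$start)
    j <- which.max(frac)
    if (length(j) && frac[j] > broad_frac) {
      seg$level[i] <- "arm"
      seg$broad_arm[i] <- a$arm[j]
    }
  }
  # promote arm-level events to chromosome-level when both arms agree
  for (ch in unique(seg$chrom)) {
    idx <- which(seg$chrom == ch & seg$level != "focal")
    if (!length(idx)) next
    by_arm <- split(idx, seg$broad_arm[idx])
    if (length(by_arm) < 2) next
    merged <- vapply(by_arm, function(ii) {
      w <- seg$end[ii] - seg$start[ii]
      score_event(sum(w * seg$log2_ratio[ii]) / sum(w))
    }, numeric(1))
    agree <- if (same_bin) merged[1] == merged[2] && merged[1] != 0
             else sign(merged[1]) == sign(merged[2]) && merged[1] != 0
    if (agree) seg$level[idx] <- "chromosome"
  }
  seg
}

#' Sum absolute event scores at each level
#'
#' @param classified output of [classify_events()] for one sample.
#' @return named numeric vector `c(focal_raw, arm_raw, chrom_raw)`, each
#'   the sum of `|score|` over events of that level.
#' @export
level_scores <- function(classified) {
  s <- abs(classified$score)
  c(focal_raw = sum(s[classified$level == "focal"]),
    arm_raw = sum(s[classified$level == "arm"]),
    chrom_raw = sum(s[classified$level == "chromosome"]))
}

#' Rank-based normalization to \[0, 1\] within a cohort
#'
#' Average-tie ranks mapped by `(rank - 1) / (n - 1)`; an all-equal
#' vector maps to 0.5 everywhere.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector in \[0, 1\].
#' @export
rank_normalize <- function(x) {
  if (length(x) < 2) stop("rank normalization needs at least 2 samples")
  (rank(x) - 1) / (length(x) - 1)
}

#' Per-arm gain/loss/neutral calls from broad events
#'
#' Broad (arm- or chromosome-level) events on each arm are merged by
#' length-weighted mean log2 ratio; the arm is called a gain when the
#' merged ratio exceeds 0.25, a loss when below -0.25, neutral otherwise
#' (arms without broad events are neutral).
#'
#' @param classified output of [classify_events()] for one sample.
#' @param arms an [arm_model()].
#' @return data.frame (chrom, arm, call) over every modeled arm.
#' @export
arm_calls <- function(classified, arms) {
  out <- data.frame(chrom = arms$chrom, arm = arms$arm, call = "neutral",
                    stringsAsFactors = FALSE)
  broad <- classified[classified$level != "focal", , drop = FALSE]
  if (nrow(broad)) {
    for (k in seq_len(nrow(out))) {
      ii <- which(broad$chrom == out$chrom[k] & broad$broad_arm == out$arm[k])
      if (!length(ii)) next
      w <- broad$end[ii] - broad$start[ii]
      m <- sum(w * broad$log2_ratio[ii]) / sum(w)
      out$call[k] <- if (m > 0.25) "gain" else if (m < -0.25) "loss" else "neutral"
    }
  }
  out
}

#' Cohort-level SCNA instability scores
#'
#' Classifies every sample's events, sums absolute bin scores at the
#' focal, arm and chromosome levels, rank-normalizes each level to
#' \[0, 1\] within its cohort (`groups`, e.g. cancer type; one cohort by
#' default - samples with no segments score 0 at every level and still
#' participate in the normalization), and reports the total instability
#' score as the sum of the three normalized levels (bounded \[0, 3\]).
#'
#' @param seg a [segment_table()] covering all samples.
#' @param arms an [arm_model()].
#' @param samples optional character vector of all cohort samples
#'   (defaults to those present in `seg`; supply explicitly so that
#'   segment-free samples are included).
#' @param groups optional named vector mapping sample to cohort.
#' @param min_cohort minimum cohort size for normalization (default 2).
#' @param ... passed to [classify_events()].
#' @return list of class `scna_result`: `scores` (data.frame with raw and
#'   normalized level scores and `total` per sample), `arm_calls`
#'   (data.frame sample x arm call), `classified` (per-event table).
#' @export
scna_score <- function(seg, arms, samples = NULL, groups = NULL,
                       min_cohort = 2, ...) {
  stopifnot(inherits(seg, "segment_table"))
  if (is.null(samples)) samples <- unique(seg$sample)
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(samples)), samples)
  if (!all(samples %in% names(groups))) stop("every sample needs a cohort label")
  cls_list <- lapply(samples, function(s) {
    one <- seg[seg$sample == s, , drop = FALSE]
    if (!nrow(one))
      return(cbind(one, data.frame(score = integer(0), level = character(0),
                                   broad_arm = character(0))))
    classify_events(segment_table(one), arms, ...)
  })
  names(cls_list) <- samples
  raw <- t(vapply(cls_list, level_scores, numeric(3)))
  scores <- data.frame(sample = samples, group = unname(groups[samples]), raw,
                       stringsAsFactors = FALSE)
  for (lvl in c("focal", "arm", "chrom")) scores[[paste0(lvl, "_norm")]] <- NA_real_
  for (g in unique(scores$group)) {
    ii <- which(scores$group == g)
    if (length(ii) < min_cohort)
      stop(sprintf("cohort '%s' has fewer than %d samples", g, min_cohort))
    for (lvl in c("focal", "arm", "chrom"))
      scores[[paste0(lvl, "_norm")]][ii] <- rank_normalize(scores[[paste0(lvl, "_raw")]][ii])
  }
  scores$total <- scores$focal_norm + scores$arm_norm + scores$chrom_norm
  calls <- do.call(rbind, lapply(samples, function(s)
    cbind(sample = s, arm_calls(cls_list[[s]], arms))))
  classified <- do.call(rbind, cls_list[vapply(cls_list, nrow, 0L) > 0])
  rownames(classified) <- NULL
  structure(list(scores = scores, arm_calls = calls, classified = classified),
            class = "scna_result")
}

#' @export
print.scna_result <- function(x, ...) {
  cat(sprintf("<scna_result> %d samples, total score range [%.2f, %.2f]\n",
              nrow(x$scores), min(x$scores$total), max(x$scores$total)))
  invisible(x)
}
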