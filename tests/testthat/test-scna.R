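test_that("event scores reproduce the bin definitions at and around boundaries", {
  expect_identical(score_event(1.4), 2L)
  expect_identical(score_event(0.25), 1L)
  expect_identical(score_event(0.0), 0L)
  expect_identical(score_event(-0.5), -1L)
  expect_identical(score_event(-1.6), -2L)
  # boundary cases per the inclusive inner edges
  expect_identical(score_event(c(1, 0.9999, -0.25, -0.2501, -1, -1.0001)),
                   c(2L, 1L, 0L, -1L, -1L, -2L))
  # monotone over a grid
  g <- seq(-3, 3, by = 0.01)
  expect_true(all(diff(score_event(g)) >= 0))
  expect_error(score_event(NaN), "finite")
})

toy_arms <- arm_model(data.frame(
  chrom = c("chr1", "chr1", "chr2", "chr2"),
  arm = c("p", "q", "p", "q"),
  start = c(0, 100, 0, 80),
  end = c(100, 300, 80, 200)))

seg_of <- function(...) segment_table(data.frame(...))

test_that("the 70% rule separates focal from broad events", {
  # 80% of chr1 p, nothing on chr1 q -> arm level
  s <- seg_of(sample = "S1", chrom = "chr1", start = 0, end = 80, log2_ratio = 0.5)
  cls <- classify_events(s, toy_arms)
  expect_identical(cls$level, "arm")
  expect_identical(cls$broad_arm, "p")
  # exactly 70% is not broad (strict >)
  s <- seg_of(sample = "S1", chrom = "chr1", start = 0, end = 70, log2_ratio = 0.5)
  expect_identical(classify_events(s, toy_arms)$level, "focal")
  # 50% of an arm -> focal
  s <- seg_of(sample = "S1", chrom = "chr1", start = 0, end = 50, log2_ratio = 1.2)
  expect_identical(classify_events(s, toy_arms)$level, "focal")
  # unknown chromosome is an error
  s <- seg_of(sample = "S1", chrom = "chrX", start = 0, end = 50, log2_ratio = 1)
  expect_error(classify_events(s, toy_arms), "unknown chromosome")
})

test_that("same-sign broad events on both arms become chromosome-level", {
  # 80% of 1p at +1 bin and 75% of 1q at +2 bin -> same sign -> chromosome
  s <- seg_of(sample = "S1", chrom = "chr1", start = c(0, 100),
              end = c(80, 250), log2_ratio = c(0.5, 1.4))
  cls <- classify_events(s, toy_arms)
  expect_identical(cls$level, c("chromosome", "chromosome"))
  # opposite signs stay arm-level
  s <- seg_of(sample = "S1", chrom = "chr1", start = c(0, 100),
              end = c(80, 250), log2_ratio = c(0.5, -1.4))
  expect_identical(classify_events(s, toy_arms)$level, c("arm", "arm"))
  # same_bin mode: +1 vs +2 no longer promotes
  s <- seg_of(sample = "S1", chrom = "chr1", start = c(0, 100),
              end = c(80, 250), log2_ratio = c(0.5, 1.4))
  expect_identical(classify_events(s, toy_arms, same_bin = TRUE)$level,
                   c("arm", "arm"))
})

test_that("level scores sum absolute bins; raw scores are additive", {
  s <- seg_of(sample = "S1", chrom = "chr2",
              start = c(0, 20, 40), end = c(10, 30, 50),
              log2_ratio = c(1.4, -0.5, 0))  # bins +2, -1, 0 (all focal)
  cls <- classify_events(s, toy_arms)
  ls <- level_scores(cls)
  expect_equal(unname(ls["focal_raw"]), 3)
  expect_equal(unname(ls[c("arm_raw", "chrom_raw")]), c(0, 0))
  # no events
  expect_equal(unname(level_scores(cls[0, ])), c(0, 0, 0))
  # duplicating focal events doubles the focal score (on chr2 q to avoid overlap)
  s2 <- seg_of(sample = "S1", chrom = "chr2",
               start = c(0, 20, 40, 80, 100, 120),
               end = c(10, 30, 50, 90, 110, 130),
               log2_ratio = rep(c(1.4, -0.5, 0), 2))
  expect_equal(unname(level_scores(classify_events(s2, toy_arms))["focal_raw"]), 6)
})

test_that("rank normalization maps to [0,1] with average ties", {
  expect_equal(rank_normalize(c(5, 10, 20)), c(0, 0.5, 1))
  expect_equal(rank_normalize(c(7, 7, 7)), c(0.5, 0.5, 0.5))
  expect_equal(rank_normalize(c(1, 2, 2, 9)), c(0, 0.5, 0.5, 1))
  expect_error(rank_normalize(1), "at least 2")
  # order preserving
  set.seed(2); v <- rnorm(20)
  expect_identical(order(rank_normalize(v)), order(v))
})

test_that("arm calls use the 0.25 gain/loss thresholds on merged broad events", {
  s <- seg_of(sample = "S1", chrom = c("chr1", "chr1", "chr2"),
              start = c(0, 100, 0), end = c(80, 260, 65),
              log2_ratio = c(0.4, -0.3, 0.9))
  cls <- classify_events(s, toy_arms)
  calls <- arm_calls(cls, toy_arms)
  expect_identical(calls$call[calls$chrom == "chr1" & calls$arm == "p"], "gain")
  expect_identical(calls$call[calls$chrom == "chr1" & calls$arm == "q"], "loss")
  # chr2 p event covers 65/80 = 81% -> broad; 0.9 -> gain
  expect_identical(calls$call[calls$chrom == "chr2" & calls$arm == "p"], "gain")
  expect_identical(calls$call[calls$chrom == "chr2" & calls$arm == "q"], "neutral")
  # a 0.1-ratio broad event is neutral
  s2 <- seg_of(sample = "S1", chrom = "chr1", start = 0, end = 80, log2_ratio = 0.1)
  c2 <- arm_calls(classify_events(s2, toy_arms), toy_arms)
  expect_identical(c2$call[c2$chrom == "chr1" & c2$arm == "p"], "neutral")
})

test_that("cohort totals sum the three normalized levels and stay in [0,3]", {
  am <- toy_arm_model()
  sim <- make_segments(25, am, seed = 4)
  res <- scna_score(sim$segments, am, samples = sprintf("S%04d", 1:25))
  sc <- res$scores
  expect_equal(sc$total, sc$focal_norm + sc$arm_norm + sc$chrom_norm)
  expect_true(all(sc$total >= 0 & sc$total <= 3))
  expect_true(all(sc$focal_raw == round(sc$focal_raw) & sc$focal_raw >= 0))
  # rank normalization is order preserving within the cohort
  expect_identical(order(sc$focal_norm), order(rank(sc$focal_raw, ties.method = "first")))
})

test_that("planted event classes are recovered exactly away from boundaries", {
  am <- toy_arm_model()
  sim <- make_segments(40, am, seed = 9)
  res <- scna_score(sim$segments, am,
                    samples = sprintf("S%04d", 1:40))
  key <- merge(res$classified, sim$truth, by = c("sample", "chrom", "start"))
  expect_equal(nrow(key), nrow(sim$truth))
  expect_identical(key$level.x, key$level.y)
})

test_that("segment-free samples score zero and join the normalization", {
  s <- seg_of(sample = c("A", "A"), chrom = "chr1", start = c(0, 100),
              end = c(80, 260), log2_ratio = c(0.5, 0.6))
  res <- scna_score(s, toy_arms, samples = c("A", "B", "C"))
  sc <- res$scores
  expect_equal(sc$focal_raw[sc$sample %in% c("B", "C")], c(0, 0))
  # B and C tie at the bottom of every level
  expect_equal(sc$chrom_norm[sc$sample == "B"], sc$chrom_norm[sc$sample == "C"])
  expect_gt(sc$total[sc$sample == "A"], sc$total[sc$sample == "B"])
})
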