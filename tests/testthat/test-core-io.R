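test_that("expression matrices validate identifiers, values and class", {
  m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  em <- expression_matrix(m, value_class = "count")
  expect_identical(dim(em), c(3L, 2L))
  expect_error(expression_matrix(rbind(m, a = c(7L, 8L)), value_class = "count"),
               "duplicate gene")
  expect_error(expression_matrix(cbind(m, s1 = 1:3), value_class = "count"),
               "duplicate sample")
  m2 <- m; m2[1, 1] <- -1
  expect_error(expression_matrix(m2, value_class = "count"), "negative")
  m3 <- m; m3[1, 1] <- 1.5
  expect_error(expression_matrix(m3, value_class = "count"), "non-integral")
  expect_silent(expression_matrix(m3, value_class = "continuous"))
  expect_error(expression_matrix(m, gene_ids = c("a", "b"), value_class = "count"),
               "dimension mismatch")
})

test_that("expression TSV and MTX round trips are lossless", {
  em <- tiny_expr(n_genes = 3, n_samples = 2, value_class = "count")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, tsv, "tsv")
  back <- read_expression(tsv, "tsv", "count")
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(as_matrix(back), as_matrix(em))
  expect_identical(back$gene_ids, em$gene_ids)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_expression(em, mtx, "mtx")
  back2 <- read_expression(mtx, "mtx", "count")
  expect_equal(as_matrix(back2), as_matrix(em))
  # duplicated gene id in the sidecar is a hard error
  writeLines(c("g01", "g01", "g03"), paste0(mtx, ".genes.tsv"))
  expect_error(read_expression(mtx, "mtx", "count"), "duplicate gene")
})

test_that("GMT parsing: set semantics, empty files, malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("HYP\td\tA\tB\tC", "OTHER\tx\tB\tD"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("HYP", "OTHER"))
  expect_identical(sets$HYP$genes, c("A", "B", "C"))

  writeLines(character(0), f)
  expect_length(read_gmt(f), 0)

  writeLines("HYP\td\tA\tA\tB", f)
  expect_warning(sets <- read_gmt(f), "duplicate")
  expect_identical(sets$HYP$genes, c("A", "B"))

  writeLines(c("HYP\td\tA", "BAD\tonly2"), f)
  expect_error(read_gmt(f), "line 2")

  # round trip
  write_gmt(gene_set("S", c("A", "B")), f)
  expect_identical(read_gmt(f)$S$genes, c("A", "B"))
})

test_that("SEG coordinates convert 1-based inclusive <-> 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchromosome\tstart\tend\tlog2_ratio",
               "S1\tchr1\t1\t1000\t0.5"), f)
  seg <- read_segments(f)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 0)     # internal 0-based
  expect_equal(seg$end, 1000)
  expect_equal(seg$end - seg$start, 1000)  # length arithmetic
  expect_equal(seg$log2_ratio, 0.5)

  out <- withr::local_tempfile(fileext = ".seg")
  write_segments(seg, out)
  expect_equal(read_segments(out), seg)
  d <- utils::read.delim(out)
  expect_equal(d$start, 1)       # external 1-based again

  writeLines(c("sample\tchromosome\tstart\tend\tlog2_ratio",
               "S1\tchr1\t1000\t10\t0.5"), f)
  expect_error(read_segments(f), "end > start")
})

test_that("segment tables reject overlaps within a sample chromosome", {
  d <- data.frame(sample = "S1", chrom = "chr1", start = c(0, 500),
                  end = c(1000, 1500), log2_ratio = 0.5)
  expect_error(segment_table(d), "overlapping")
  d$start <- c(0, 1000); d$end <- c(1000, 1500)
  expect_silent(segment_table(d))
})

test_that("survival tables enforce time > 0, binary events and stages", {
  base <- data.frame(patient = c("a", "b"), time = c(10, 20), event = c(0, 1),
                     stage = c("II", "IV"))
  st <- survival_table(base)
  expect_identical(st$stage, c(2L, 4L))
  bad <- base; bad$time[1] <- 0
  expect_error(survival_table(bad), "time")
  bad <- base; bad$event[1] <- 2
  expect_error(survival_table(bad), "event")
  bad <- base; bad$stage[1] <- "V"
  expect_error(survival_table(bad), "stage")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_survival(st, f)
  expect_equal(as.data.frame(read_survival(f)), as.data.frame(st))
})

test_that("screen matrices allow NA but not empty or non-numeric genes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tscr1\tscr2", "A\t-1.5\t0.2", "B\t\t1.0"), f)
  m <- read_screens(f)
  expect_true(is.na(m["B", "scr1"]))
  writeLines(c("gene\tscr1\tscr2", "A\t-1.5\t0.2", "B\t\t"), f)
  expect_error(read_screens(f), "non-missing")
})

test_that("the shipped toy arm model loads and matches the in-code generator", {
  f <- system.file("extdata", "toy_arms.tsv", package = "cellhypoxia")
  am <- read_arm_model(f)
  ref <- toy_arm_model()
  expect_equal(am$start, ref$start)
  expect_equal(am$end, ref$end)
  expect_identical(am$arm, ref$arm)
  # arms are disjoint within each chromosome
  for (ch in unique(am$chrom)) {
    s <- am[am$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_lte(s$end[1], s$start[2])
  }
})

test_that("config files are validated at load time", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "fdr_max: 0.05", "note: hello"), f)
  cfg <- read_config(f)
  expect_identical(cfg$seed, 7L)
  expect_equal(cfg$fdr_max, 0.05)
  expect_identical(cfg$note, "hello")
  writeLines("seed: -1", f)
  expect_error(read_config(f), "seed")
  writeLines("fdr_max: 1.5", f)
  expect_error(read_config(f), "fdr_max")
})
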