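test_that("threshold objects validate their legal ranges", {
  th <- derivation_thresholds()
  expect_equal(th$geo_mean_min, 0.4)
  expect_error(derivation_thresholds(fdr_max = 0), "fdr_max")
  expect_error(derivation_thresholds(min_expr_frac = 1.2), "min_expr_frac")
  expect_error(derivation_thresholds(logfc_min = -1), "logfc_min")
})

test_that("malignant scoring uses only the malignant compartment", {
  ds <- tiny_cell_dataset()
  seed_set <- gene_set("seed", c("g01", "g02", "g03"))
  sc <- malignant_hypoxia_scores(ds, seed_set)
  expect_setequal(sc$sample_ids, ds$expr$sample_ids[ds$malignant_mask])
  expect_error(malignant_hypoxia_scores(ds, gene_set("x", "absent")),
               "intersect")
  few <- ds
  few$malignant_mask[ds$malignant_mask][-(1:2)] <- FALSE
  expect_error(malignant_hypoxia_scores(few, seed_set), "3 malignant")
})

test_that("hypoxia-correlated gene selection matches rank-correlation behaviour", {
  ds <- tiny_cell_dataset(n_cells = 40)
  cells <- ds$expr$sample_ids[ds$malignant_mask]
  # plant one gene equal to the score and one anti-monotone to it
  sc_vals <- seq_along(cells)
  v <- ds$expr$values
  v["g01", cells] <- sc_vals * 10       # rho = +1 after normalization ranks
  v["g02", cells] <- rev(sc_vals) * 10  # rho = -1
  v["g03", ] <- 0                       # constant (also after normalization) -> excluded
  ds$expr <- expression_matrix(v, value_class = "count")
  sc <- structure(list(sample_ids = cells,
                       scores = stats::setNames(as.numeric(sc_vals), cells),
                       method = "gsva"), class = "score_vector")
  gx <- correlated_genes_Gx(ds, sc, derivation_thresholds())
  expect_true("g01" %in% gx$gene)
  expect_false("g02" %in% gx$gene)
  expect_false("g03" %in% gx$gene)
  expect_gte(attr(gx, "n_constant"), 1)
  expect_true(all(gx$rho > 0 & gx$q < 0.05))
})

test_that("small-sample Spearman p-values equal the exact permutation oracle", {
  # 6 cells with one tie pair; oracle enumerates all 720 orderings in R
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6, 5)
  st <- spearman_test(x, y)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- gtools_perms <- NULL
  allp <- combinat_permn <- NULL
  # enumerate permutations via recursive index generation
  perm_idx <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_idx(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ps <- vapply(perm_idx(seq_along(y)),
               function(ix) abs(cor(rx, ry[ix])), numeric(1))
  expect_equal(st$p.value, mean(ps >= obs - 1e-9), tolerance = 1e-12)
  expect_equal(st$rho, cor(rx, ry))
})

test_that("malignant-up selection honours logFC, FDR and detection rules", {
  ds <- tiny_cell_dataset(n_cells = 40, n_genes = 10)
  v <- ds$expr$values
  mal <- ds$malignant_mask
  v["g01", ] <- ifelse(mal, 50L, 0L)   # malignant-only, high -> included
  v["g02", ] <- rep(4L, ncol(v))       # identical distribution -> excluded
  ds$expr <- expression_matrix(v, value_class = "count")
  gy <- malignant_up_genes_Gy(ds, derivation_thresholds())
  expect_true("g01" %in% gy$gene)
  expect_false("g02" %in% gy$gene)
  expect_equal(gy$logfc[gy$gene == "g02"], numeric(0))

  # detection rule: a gene expressed in <10% of every cell type is excluded
  ds2 <- tiny_cell_dataset(n_cells = 60, n_genes = 6)
  v2 <- ds2$expr$values
  v2["g04", ] <- 0L
  v2["g04", which(ds2$malignant_mask)[1]] <- 80L   # 1/30 malignant cells
  ds2$expr <- expression_matrix(v2, value_class = "count")
  gy2 <- malignant_up_genes_Gy(ds2, derivation_thresholds())
  expect_false("g04" %in% gy2$gene)
})

test_that("rank-sum p-values in the small-sample regime match wilcox.test exactly", {
  # tie-free 20-cell fixture: implementation enumerates assignments,
  # wilcox.test's exact conditional distribution is the oracle
  set.seed(13)
  x <- sample(seq(1, 40), 10); y <- sample(seq(41, 80), 10) / 2.3
  gt <- group_test(c(x, y), rep(c("a", "b"), each = 10), "wilcoxon")
  wt <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(gt$p.value, wt$p.value, tolerance = 1e-12)
  expect_equal(gt$statistic, unname(wt$statistic), tolerance = 1e-12)
})

test_that("intersection carries correlations and behaves set-theoretically", {
  gx <- data.frame(gene = c("a", "b", "c", "d", "e"), rho = seq(0.1, 0.5, 0.1),
                   q = 0.01)
  gy <- data.frame(gene = c("c", "e", "f"), logfc = 1, q = 0.01)
  gn <- intersect_Gn(gx, gy)
  expect_identical(gn$gene, c("c", "e"))
  expect_equal(gn$rho, c(0.3, 0.5))
  expect_equal(nrow(intersect_Gn(gx, data.frame(gene = "zz"))), 0)
  expect_identical(intersect_Gn(gx, gx)$gene, gx$gene)
})

test_that("geometric-mean aggregation applies strict thresholds and support", {
  gn1 <- data.frame(gene = c("a", "b", "c"), rho = c(0.5, 0.2, 0.9), q = 0.01)
  gn2 <- data.frame(gene = c("a", "b", "d"), rho = c(0.5, 0.8, 0.6), q = 0.01)
  res <- aggregate_signature(list(gn1, gn2), min_support = 2)
  agg <- res$aggregate
  expect_equal(agg$geo_mean[agg$gene == "a"], 0.5)        # {0.5, 0.5} -> 0.5
  expect_equal(agg$geo_mean[agg$gene == "b"], 0.4)        # sqrt(0.16) exactly
  expect_true("a" %in% res$signature$genes)
  expect_false("b" %in% res$signature$genes)              # strict > 0.4
  expect_false("c" %in% res$signature$genes)              # support 1 < 2
  # geometric mean bounded by min/max of the inputs
  expect_true(all(agg$geo_mean >= 0.2 - 1e-12 & agg$geo_mean <= 0.9 + 1e-12))
  # non-positive rho is an internal invariant violation
  expect_error(aggregate_signature(list(data.frame(gene = "a", rho = -0.1, q = 0.01))),
               "invariant")
})

test_that("shrinking thresholds never shrinks the selected sets", {
  ds <- tiny_cell_dataset(n_cells = 50, n_genes = 20, seed = 3)
  sc <- malignant_hypoxia_scores(ds, gene_set("s", c("g01", "g02", "g03", "g04")))
  strict <- derivation_thresholds(fdr_max = 0.01, logfc_min = 0.5)
  loose <- derivation_thresholds(fdr_max = 0.2, logfc_min = 0.05)
  expect_true(all(correlated_genes_Gx(ds, sc, strict)$gene %in%
                  correlated_genes_Gx(ds, sc, loose)$gene))
  expect_true(all(malignant_up_genes_Gy(ds, strict)$gene %in%
                  malignant_up_genes_Gy(ds, loose)$gene))
})
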