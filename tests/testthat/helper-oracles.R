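# Brute-force oracles for the scoring engine, independent of the
# compiled implementation.

gauss_kcdf_oracle <- function(x) {
  h <- pmax(apply(x, 1, sd) / 4, 1e-8)
  z <- x
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      z[i, j] <- mean(pnorm((x[i, j] - x[i, ]) / h[i])) - 0.5
  z
}

pois_kcdf_oracle <- function(x) {
  z <- x
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      z[i, j] <- mean(ppois(x[i, j], x[i, ] + 0.5)) - 0.5
  z
}

# Explicit running-sum walk for one sample (max-deviation convention).
walk_oracle <- function(stat, gene_ids, set_genes, tau = 1, method = "gsva") {
  ord <- order(-stat, gene_ids, method = "radix")
  hit <- gene_ids[ord] %in% set_genes
  p <- length(stat); m <- sum(hit)
  r <- seq_len(p)
  w <- if (method == "gsva") abs((p + 1) / 2 - r)^tau else (p - r + 1)^tau
  walk <- numeric(p); run <- 0
  wh_sum <- sum(w[hit])
  for (k in seq_len(p)) {
    run <- run + if (hit[k]) w[k] / wh_sum else -1 / (p - m)
    walk[k] <- run
  }
  if (method == "gsva") max(c(walk, 0)) + min(c(walk, 0)) else mean(walk)
}
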