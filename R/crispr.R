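#' Rank genes by mean screen score
#'
#' Mean over non-missing screens; rank 1 is the lowest (most negative)
#' mean - in knockout screens a low z or essentiality score marks a gene
#' whose loss improves the phenotype, so rank 1 is the strongest
#' candidate. Ties are broken by gene id; genes with no observation are
#' rejected by [screen_matrix()] upstream.
#'
#' @param screens a [screen_matrix()] (genes x screens, NA allowed).
#' @param restandardize z-score each screen column before averaging.
#' @return data.frame of class `ranked_genes` (gene, mean_score, rank),
#'   sorted by rank.
#' @export
mean_rank <- function(screens, restandardize = FALSE) {
  m <- unclass(screens)
  if (restandardize) m <- scale(m)
  mu <- rowMeans(m, na.rm = TRUE)
  ord <- order(mu, rownames(m), method = "radix")
  out <- data.frame(gene = rownames(m)[ord], mean_score = mu[ord],
                    rank = seq_along(mu), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Best-ranked fraction of genes
#'
#' The `floor(k/100 * n)` best-ranked genes, with a minimum of 1 when
#' any gene exists; top fractions are nested in `k`.
#'
#' @param ranked a `ranked_genes` table from [mean_rank()].
#' @param k_percent percentage in (0, 100\].
#' @return character vector of gene ids.
#' @export
top_fraction <- function(ranked, k_percent) {
  if (k_percent <= 0 || k_percent > 100) stop("k_percent must be in (0, 100]")
  n <- nrow(ranked)
  if (n == 0) return(character(0))
  k <- max(1L, floor(k_percent / 100 * n))
  ranked$gene[seq_len(k)]
}

#' Percentage of a signature captured by a top-ranked set
#'
#' `100 * |signature \eqn{\cap} topset| / |signature \eqn{\cap} universe|`;
#' genes outside the universe never contribute.
#'
#' @param signature a [gene_set()] or character vector.
#' @param topset character vector (e.g. from [top_fraction()]).
#' @param universe all genes measured by the screen.
#' @return percentage in \[0, 100\], or `NA` (with a warning) when the
#'   signature misses the universe entirely.
#' @export
overlap_percent <- function(signature, topset, universe) {
  genes <- if (inherits(signature, "gene_set")) signature$genes else signature
  in_univ <- intersect(genes, universe)
  if (!length(in_univ)) {
    warning("signature does not intersect the screen universe")
    return(NA_real_)
  }
  100 * length(intersect(in_univ, topset)) / length(in_univ)
}

#' Hub genes: signature genes top-ranked in both screen collections
#'
#' Intersects the signature with the top `k_percent` of the cell-line
#' essentiality ranking and with the top `k_percent` of the immune-screen
#' ranking; genes present in both intersections are the prioritized
#' therapeutic candidates. Monotone non-decreasing in `k_percent`.
#'
#' @param signature a [gene_set()] or character vector.
#' @param cellline_ranked,immune_ranked `ranked_genes` tables.
#' @param k_percent top fraction (default 15).
#' @return character vector of hub genes (sorted).
#' @export
hub_genes <- function(signature, cellline_ranked, immune_ranked, k_percent = 15) {
  genes <- if (inherits(signature, "gene_set")) signature$genes else signature
  a <- intersect(genes, top_fraction(cellline_ranked, k_percent))
  b <- intersect(genes, top_fraction(immune_ranked, k_percent))
  sort(intersect(a, b))
}
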