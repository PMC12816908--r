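---
title: "Methods: cell-specific hypoxia scoring and its downstream models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-specific hypoxia scoring and its downstream models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhypoxia)
```

cellhypoxia quantifies tumor hypoxia from transcriptomes and carries that
quantity through the analyses it typically supports: deriving a
malignant-cell-specific hypoxia signature from multiple single-cell
datasets, relating the per-sample score to copy-number instability and
mutation burden, predicting immunotherapy response, building survival risk
and nomogram scores, and prioritizing therapeutic targets from CRISPR
screens. This vignette explains the models, the conventions we fixed where
the field leaves a choice open, and what the synthetic-data generators do
and do not emulate.

## Single-sample gene-set scoring

The scoring engine is a rank-based single-sample enrichment statistic in
the GSVA/ssGSEA family, written from scratch.

**Expression-level statistic.** For gene $i$ and sample $j$,
`kcdf_stats()` estimates the within-gene cumulative distribution of
$x_{ij}$ against all samples of that gene with a kernel:

$$z_{ij} = \frac{1}{n}\sum_{k=1}^{n} K\!\left(x_{ij};\, x_{ik}\right) - \tfrac12 ,$$

with a Gaussian kernel of per-gene bandwidth $\mathrm{SD}_i/4$ (floored at
$10^{-8}$ so constant genes remain defined) for continuous data, and a
discrete Poisson kernel ($\lambda = x_{ik} + 0.5$) for counts. The
statistic is non-decreasing in the raw value within each gene.

**Rank conversion.** The `gsva` path of `hyp_score()` converts $z_{ij}$ to
centered within-gene ranks before the walk. This makes the final score a
function of per-gene ranks only, so it is exactly invariant under any
strictly increasing per-gene transform of the input — the property the
test suite checks. The kernel CDF remains available as an intermediate
statistic.

**Enrichment walk.** Per sample, genes are ordered by decreasing
statistic (ties broken by gene identifier, so results are deterministic)
and a running sum steps up at gene-set members — proportionally to
$|\,(p+1)/2 - r\,|^{\tau}$, normalized over members — and down by
$1/(p-m)$ elsewhere ($p$ genes, $m$ members, default $\tau = 1$). The
score is the sum of the walk's largest positive and largest negative
deviations. We chose this convention (over the signed maximum deviation)
because it is the cited algorithm family's default, it is exactly
antisymmetric under rank reversal, and its null distribution over random
gene sets is centered at zero; the weight is centered at $(p+1)/2$ rather
than $p/2$ for the same symmetry reason. Scores are bounded in
$[-1, 1]$. The `ssgsea` method ranks raw expression within each sample,
weights by the ascending rank, and reports the normalized integral of the
walk.

**Grouping.** `hyp_score()` dichotomizes at the cohort median with a fixed
tie rule used throughout the package: strictly greater than the median is
"high". An all-tied cohort is therefore all-"low".

The value-class flag deserves a note: RNA-seq integer counts select the
Poisson kernel, while log-scale quantities (log-TPM, log-RPKM) select the
Gaussian kernel. Published descriptions of this algorithm family label
these classes inconsistently; we expose an explicit
`{count, continuous}` enum instead of reproducing that ambiguity.

## The four-step signature derivation

Given several single-cell datasets with malignant-cell masks and a seed
hypoxia gene set:

1. **Score** malignant cells only (`malignant_hypoxia_scores()`).
2. **Correlate**: per gene, the Spearman correlation between expression
   and the malignant-cell score; keep $\rho > 0$ at BH $q < 0.05$
   (`correlated_genes_Gx()`). Sources for this step disagree between raw
   $p$ and FDR thresholds; we default to the stricter BH reading with a
   `use_fdr = FALSE` escape hatch.
3. **Malignant-up**: Wilcoxon rank-sum of malignant versus all other
   cells pooled, natural-log fold change of library-size-normalized
   means ($\ln(\bar x + 1)$ difference, the convention of the standard
   single-cell marker-detection routines; log2 by flag), detected in at
   least 10% of the cells of some cell type; keep logFC $> 0.25$ at
   $q < 0.05$ (`malignant_up_genes_Gy()`). Whether the comparison should
   be pooled or one-vs-each-type is unstated in the framework we follow;
   pooled is the default and `one_vs_each` is available.
4. **Intersect and aggregate**: the per-dataset intersection carries each
   gene's $\rho$; across datasets, genes are kept when the geometric mean
   of their correlations — computed only over the datasets whose
   intersection contains the gene, the only well-defined reading since
   geometric means of signed values are undefined — exceeds 0.4, with
   support in at least `min_support = 2` datasets.

Correlation p-values use the $t$ approximation for $n > 10$ and exact
permutation enumeration below that (implemented in C++; exactness under
ties is what makes the brute-force test oracle meaningful). Constant
genes are excluded from step 2 with a count attribute rather than
silently dropped.

## Copy-number instability score

Segmented log2 ratios are binned into event scores
$\{-2,-1,0,1,2\}$ with cut points at $-1$, $-0.25$, $0.25$ and $1$
(inner edges inclusive: $-0.25$ scores 0, $0.25$ scores 1). An event is
*broad* when it covers strictly more than 70% of a chromosome arm; on a
chromosome where both arms carry broad events whose merged bin scores
share a non-zero sign, the broad events are chromosome-level, otherwise
arm-level; everything else is focal. "Same copy-number change" is read
as same *sign* (a same-bin mode exists, since the stricter reading is
also defensible). Multiple broad events on one arm are merged by
length-weighted mean log2 before arm gain/loss calling at $\pm 0.25$.

Per sample, the absolute bin scores are summed within each level; each
level is rank-normalized to $[0,1]$ within its cohort
(`(rank-1)/(n-1)`, average ties), and the total instability score is the
sum of the three normalized levels, bounded $[0,3]$. Samples with no
segments score zero and stay in the normalization — absence of events is
informative. External SEG files are 1-based inclusive; internally all
coordinates are 0-based half-open, converted only at the I/O boundary so
length arithmetic is unambiguous.

## Association statistics

`spearman_assoc()` reports tie-corrected $\rho$, two-sided $p$
($t$ approximation above $n = 10$, exact permutation at or below),
and BH $q$ per feature. `median_quadrants()` crosses the hypoxia-score
and mutation-burden median splits into HPHT/HPLT/LPHT/LPLT labels using
the same strict-greater tie rule, so the labels are invariant to
monotone transforms of either axis. `group_test()` wraps the rank-sum
test (exact enumeration when both groups have at most 10 observations,
tie-corrected normal approximation otherwise), Kruskal-Wallis, the
paired $t$, and the chi-square test (no continuity correction by
default). `roc_auc()` uses the rank/Mann-Whitney identity with
half-weight ties.

## Immunotherapy-response harness

The harness owns the protocol, not the learners: merge cohorts
(optionally removing batch effects via the sva empirical-Bayes adjustment
or a built-in per-cohort standardization; the method applied is recorded
in metadata), split 80/20 stratified by response using the ceiling rule
($n_\text{train} = \lceil 0.8\,n \rceil$, reproducing 749 → 600/149 and
9637 → 7710/1927), tune each of six learners by mean AUC over
5×10-fold cross-validation on its small declared grid, refit at the best
grid point, and select the learner with the highest AUC on the held-out
validation set (ties to the lexicographically first identifier).
Features are the signature genes, z-scored on the training set;
zero-variance features are dropped; genes missing from a test cohort are
imputed to the training mean with a message.

Random forest, naive Bayes, k-nearest neighbors and the class-weighted
RBF SVM are delegated to randomForest, e1071 and class. AdaBoost
(exponential-weight decision stumps) and boosted logistic regression
(LogitBoost Newton steps on stumps) are compact implementations in this
package. The tuning grids are deliberately small and declared in
`ici_learners()`; published descriptions of this protocol do not state
grids, so ours are a documented choice.

## Survival models

`consensus_select()` intersects three feature selectors: L1-penalized
Cox (glmnet, non-zero coefficients at the cross-validated
`lambda.min`), a random survival forest (ranger, positive permutation
importance), and gradient-boosted Cox trees (xgboost `survival:cox`,
non-zero gain). An empty three-way intersection falls back to the union
of pairwise intersections with a warning. The sources we follow name the
selector trio inconsistently in different places; the trio is
configurable and the default follows the most specific description.

`stepwise_cox()` runs bidirectional AIC selection from the null model
with candidates in fixed input order (deterministic), Efron ties, and
returns the final partial-likelihood fit; the risk score is the exact
linear combination $\sum \hat\beta_g x_g$, and an empty model scores
everyone zero. `km_logrank()` median-splits the score (same tie rule)
and reports product-limit curves with the 1-df log-rank chi-square.
`univariate_cox()` classifies features as risk factors
($p < 0.05$, HR $> 1$), protective, or non-significant. Stage enters
`nomogram_score()` as an ordinal 1-4 covariate by default (categorical
by flag); calibration compares Breslow-baseline predicted survival with
Kaplan-Meier observed survival in linear-predictor deciles at the
requested horizons. `time_dependent_auc()` implements the
cumulative-case/dynamic-control AUC with inverse-probability-of-censoring
weights from the Kaplan-Meier censoring estimator; with no censoring it
reduces exactly to the plain AUC against $I(T \le t)$.

## CRISPR target prioritization

Genes are ranked by their mean score over non-missing screens (rank 1 =
most negative = strongest candidate; ties by gene id; per-screen
re-standardization by flag, off by default since the input matrices are
already z-scored). Top fractions use `floor(k/100·n)` with a minimum of
one — the rounding rule is unstated in the sources, so it is fixed here.
`hub_genes()` intersects the signature with the top fraction of both the
cell-line essentiality ranking and the immune-screen ranking. Genes
absent from a screen matrix are excluded from that matrix's universe,
never imputed.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed (child
seeds are derived per component, so adding generators never perturbs
existing streams), and serializes its planted truth.

- `make_scrna()` draws negative-binomial counts over a
  malignant/immune/stromal mixture. Malignant cells carry a latent
  hypoxia level $h \sim U(0,1)$; program genes gain
  `effect`·$h$ plus a constant malignant offset (0.5) on the log-mean.
  The free constants are fixed at values that make an `effect = 1`
  program behave like a strong, real hypoxia program: program genes come
  from an abundant pool (lognormal mean-log $\log 15$, spread 0.3;
  canonical hypoxia/glycolysis markers are high-expression transcripts),
  dispersion is mild (NB size 10), and the background baseline
  (mean-log $\log 3$) carries most of the library mass so that the
  30-gene program occupies a realistic share (~10%) of each cell's
  library despite the reduced 2,000-gene universe — without this, the
  library-size normalization used in the derivation divides the planted
  signal out of the program genes, an artifact of a small gene universe
  rather than a property of the method. Per-dataset lognormal gene
  factors (spread 0.2) emulate between-dataset detection differences.
  Default sizes (4 datasets × 600 cells × 2,000 genes) keep the full
  derivation under a minute per run.
- `make_segments()` plants focal (5-65% of an arm), arm (75-95%) and
  chromosome (both arms, same sign) events — deliberately away from the
  70% broadness boundary so the planted labels are exactly recoverable —
  with log2 ratios drawn inside the non-neutral bins and at most one
  event per arm, so segments never overlap.
- `make_survival()` uses standard-normal expression, a Weibull baseline
  (median 730 days, shape 1.2) with hazard $\propto e^{\beta x}$,
  exponential censoring whose rate is calibrated by root-finding to the
  requested censoring fraction, and an ordinal stage correlated with the
  true linear predictor.
- `make_ici()` gives each patient a latent hypoxia score
  $h \sim N(0, 3)$, read out by each signature gene with unit loading
  plus unit noise and per-cohort batch shifts; response is
  $\mathrm{Bern}(\mathrm{logistic}(\alpha + \text{slope}\cdot h))$. The
  latent scale 3 places a unit slope in the strongly predictive regime
  (latent AUC ≈ 0.92) while slope 0 is exactly uninformative; the
  default cohort sizes reproduce the nine-cohort compendium design
  (749 merged + 155 external = 904 patients).
- `make_screens()` produces two gene × screen z-matrices with N(0,1)
  background and planted hits shifted by `-hit_effect`: by default 4
  dual hits, 12 cell-line-only and 10 immune-only hits among a 68-gene
  signature (the 16/14/4 top-15% structure of the real compendium).
  Signature genes *not* planted as hits in a matrix are resampled away
  from that matrix's low tail, the screen analogue of planting
  copy-number events away from the broadness boundary: the planted
  labels are then the identifiable ground truth. Background marginals
  are untouched.

What the generators do **not** emulate: doublets, ambient RNA, dropout
structure beyond NB sampling, subclonal copy number, competing risks,
informative censoring, or real between-cohort platform effects beyond
location shifts. Passing the planted-truth tests therefore shows the
pipeline recovers the structures it models under its own assumptions; it
does not certify performance on real data.

## Numerical conventions and degenerate inputs

- All median splits: strictly greater than the median is "high".
- All ranking ties: average ranks for statistics, gene-id order for
  deterministic orderings.
- Constant features: excluded with a flag (`rho = NA`, class
  `"undefined"`), never silently dropped.
- Exact small-sample tests (Spearman $n \le 10$, rank-sum both groups
  $\le 10$) are enumerations that remain exact under ties.
- Empty models, empty cohort lists, zero-segment samples and
  zero-censoring requests all have defined, tested behaviour.

## Problem sizes used in the packaged validation

The shipped tests exercise the derivation at 4 × 600 cells × 2,000 genes
(signal and null), the ICI harness at the 749/155 compendium design plus
a 500-patient permuted-label null against 2,000 uninformative external
patients, the survival stack at n = 2,000 (hazard recovery) and 100 ×
1,000 (null coverage), and the screen prioritization at 2 × 2,000 × 15
matrices — sizes at which every stochastic check sits well inside its
tolerance while the whole suite stays fast.
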