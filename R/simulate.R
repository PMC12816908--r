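# Seeded generators with planted ground truth. Each generator derives its
# own child seed from the global seed and a fixed component offset, so
# adding a generator never perturbs the streams of existing ones, and each
# is a pure function of (params, seed): identical calls are bit-identical.

.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + offset)
}

#' Simulate multi-dataset single-cell RNA counts with a planted hypoxia program
#'
#' Each dataset holds negative-binomial counts over a mixture of cell
#' types. Malignant cells carry a latent hypoxia level `h ~ Uniform(0,1)`;
#' the planted program genes' log-mean increases by `effect * h` in
#' malignant cells plus a constant malignant offset (so the program is
#' both hypoxia-correlated and malignant-up, the structure the
#' derivation framework assumes), while background genes are i.i.d.
#' across cells. Per-dataset lognormal gene factors emulate
#' between-dataset detection differences. Program genes are drawn from a
#' moderately expressed pool so a single gene carries a usable
#' correlation signal at `effect = 1`; baseline means, dispersion and
#' the malignant offset are fixed design constants (see the methods
#' vignette).
#'
#' @param n_datasets number of datasets.
#' @param n_cells cells per dataset.
#' @param cell_type_mix named non-negative proportions summing to 1;
#'   must contain `malignant`.
#' @param n_genes total genes.
#' @param program_size planted program size (< `n_genes`).
#' @param effect slope of the program genes' log-mean in `h` (>= 0).
#' @param malignant_offset constant log-mean increase of program genes
#'   in malignant cells.
#' @param seed integer seed.
#' @return list: `datasets` (list of [cell_dataset()]), `truth`
#'   (program genes, per-dataset latent `h` of malignant cells, params).
#' @export
make_scrna <- function(n_datasets = 4, n_cells = 600,
                       cell_type_mix = c(malignant = 0.5, immune = 0.3, stromal = 0.2),
                       n_genes = 2000, program_size = 30, effect = 1,
                       malignant_offset = 0.5, seed = 1) {
  if (program_size >= n_genes) stop("program_size must be < n_genes")
  if (effect < 0) stop("effect must be >= 0")
  if (abs(sum(cell_type_mix) - 1) > 1e-8 || any(cell_type_mix < 0) ||
      !"malignant" %in% names(cell_type_mix))
    stop("cell_type_mix must be non-negative proportions summing to 1 with a 'malignant' entry")
  set.seed(.child_seed(seed, 1L))
  genes <- sprintf("G%04d", seq_len(n_genes))
  program <- sort(sample(genes, program_size))
  # baseline means: lognormal background; program genes from an abundant
  # pool (canonical hypoxia/glycolysis markers are high-expression transcripts).
  # Background carries most of the library mass so the program's share of
  # each cell's library stays realistic despite the reduced gene universe.
  base_mu <- stats::setNames(exp(stats::rnorm(n_genes, log(3), 1)), genes)
  base_mu[program] <- exp(stats::rnorm(program_size, log(15), 0.3))
  size <- 10  # NB inverse-dispersion (var = mu + mu^2/size)

  datasets <- vector("list", n_datasets)
  h_list <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(.child_seed(seed, 100L + d))
    cnt <- diff(round(cumsum(c(0, cell_type_mix)) * n_cells))
    types <- sample(rep(names(cell_type_mix), cnt))
    mal <- types == "malignant"
    h <- ifelse(mal, stats::runif(n_cells), 0)
    ds_factor <- exp(stats::rnorm(n_genes, 0, 0.2))   # per-dataset detection noise
    logmu <- matrix(log(base_mu * ds_factor), n_genes, n_cells)
    pi_ <- match(program, genes)
    logmu[pi_, mal] <- logmu[pi_, mal] + malignant_offset +
      effect * matrix(h[mal], length(pi_), sum(mal), byrow = TRUE)
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = exp(logmu), size = size),
                     n_genes, n_cells,
                     dimnames = list(genes, sprintf("D%d_C%04d", d, seq_len(n_cells))))
    expr <- expression_matrix(counts, value_class = "count")
    datasets[[d]] <- cell_dataset(expr, types, mal, sprintf("sim_ds%d", d))
    h_list[[d]] <- stats::setNames(h[mal], colnames(counts)[mal])
  }
  list(datasets = datasets,
       truth = list(program = program, h = h_list, effect = effect,
                    seed = seed,
                    params = list(n_datasets = n_datasets, n_cells = n_cells,
                                  n_genes = n_genes, program_size = program_size,
                                  malignant_offset = malignant_offset)))
}

.draw_log2 <- function(n, sign) {
  bin <- sample(c(1, 2), n, replace = TRUE, prob = c(0.7, 0.3))
  mag <- ifelse(bin == 1, stats::runif(n, 0.3, 0.9), stats::runif(n, 1.1, 2))
  sign * mag
}

#' Simulate copy-number segments with known focal/arm/chromosome events
#'
#' Events are planted away from the 70% broadness boundary: focal events
#' cover 5-65% of an arm, broad events 75-95%; chromosome events place
#' same-sign broad events on both arms of one chromosome. At most one
#' event per arm and per sample, so segments never overlap. Log2 ratios
#' are drawn from the non-neutral score bins (|log2| in
#' \[0.3, 0.9\] or \[1.1, 2\]).
#'
#' @param n_samples samples to simulate.
#' @param arms an [arm_model()].
#' @param rates named expected event counts per sample,
#'   `c(focal=, arm=, chromosome=)`; realized counts are Poisson and
#'   capped by the number of free arms/chromosomes.
#' @param seed integer seed.
#' @return list: `segments` (a [segment_table()]), `truth` (data.frame
#'   sample/chrom/arm/level/log2 per planted event).
#' @export
make_segments <- function(n_samples, arms,
                          rates = c(focal = 3, arm = 1.5, chromosome = 0.75),
                          seed = 1) {
  stopifnot(inherits(arms, "arm_model"))
  set.seed(.child_seed(seed, 2L))
  rows <- list(); truths <- list()
  chroms <- unique(arms$chrom)
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%04d", s)
    used_arm <- character(0)   # "chrom:arm"
    n_chr <- stats::rpois(1, rates[["chromosome"]])
    n_arm <- stats::rpois(1, rates[["arm"]])
    n_foc <- stats::rpois(1, rates[["focal"]])
    # chromosome events: both arms of an unused chromosome, same sign
    two_armed <- names(which(table(arms$chrom) == 2))
    free_chr <- two_armed[!two_armed %in% sub(":.*", "", used_arm)]
    for (ch in utils::head(sample(free_chr), n_chr)) {
      sg <- sample(c(-1, 1), 1)
      for (arm in c("p", "q")) {
        a <- arms[arms$chrom == ch & arms$arm == arm, ]
        if (!nrow(a)) next
        len <- a$end - a$start
        frac <- stats::runif(1, 0.75, 0.95)
        st <- a$start + floor(stats::runif(1, 0, (1 - frac) * len))
        l2 <- .draw_log2(1, sg)
        rows[[length(rows) + 1]] <- data.frame(sample = sid, chrom = ch,
                                               start = st, end = st + round(frac * len),
                                               log2_ratio = l2)
        truths[[length(truths) + 1]] <- data.frame(sample = sid, chrom = ch, arm = arm,
                                                   start = st, end = st + round(frac * len),
                                                   level = "chromosome", log2 = l2)
        used_arm <- c(used_arm, paste0(ch, ":", arm))
      }
    }
    place <- function(level, n, frac_range) {
      all_arms <- paste0(arms$chrom, ":", arms$arm)
      free <- setdiff(all_arms, used_arm)
      for (key in utils::head(sample(free), n)) {
        ch <- sub(":.*", "", key); arm <- sub(".*:", "", key)
        if (level == "arm" && paste0(ch, ":", setdiff(c("p", "q"), arm)) %in% used_arm) next
        a <- arms[arms$chrom == ch & arms$arm == arm, ]
        len <- a$end - a$start
        frac <- stats::runif(1, frac_range[1], frac_range[2])
        st <- a$start + floor(stats::runif(1, 0, (1 - frac) * len))
        l2 <- .draw_log2(1, sample(c(-1, 1), 1))
        rows[[length(rows) + 1]] <<- data.frame(sample = sid, chrom = ch,
                                                start = st, end = st + round(frac * len),
                                                log2_ratio = l2)
        truths[[length(truths) + 1]] <<- data.frame(sample = sid, chrom = ch, arm = arm,
                                                    start = st, end = st + round(frac * len),
                                                    level = level, log2 = l2)
        used_arm <<- c(used_arm, key)
      }
    }
    place("arm", n_arm, c(0.75, 0.95))
    place("focal", n_foc, c(0.05, 0.65))
  }
  seg <- if (length(rows)) segment_table(do.call(rbind, rows))
         else segment_table(data.frame(sample = character(0), chrom = character(0),
                                       start = numeric(0), end = numeric(0),
                                       log2_ratio = numeric(0)))
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(sample = character(0), chrom = character(0),
                           arm = character(0), start = numeric(0), end = numeric(0),
                           level = character(0), log2 = numeric(0))
  list(segments = seg, truth = truth, seed = seed)
}

#' A small synthetic arm model (toy genome)
#'
#' Ten chromosomes with p/q arms of varying lengths; internal 0-based
#' half-open coordinates. Purely synthetic - no genome build is implied.
#'
#' @param n_chrom number of chromosomes (default 10).
#' @return an [arm_model()].
#' @export
toy_arm_model <- function(n_chrom = 10) {
  lens_p <- 3e7 + 2e6 * seq_len(n_chrom)
  lens_q <- 5e7 + 3e6 * seq_len(n_chrom)
  arm_model(data.frame(
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = 2),
    arm = rep(c("p", "q"), n_chrom),
    start = as.vector(rbind(0, lens_p)),
    end = as.vector(rbind(lens_p, lens_p + lens_q))))
}

#' Simulate expression with proportional-hazards survival
#'
#' Gene expression is standard normal; event times follow a Weibull
#' baseline with hazard proportional to `exp(beta . x)`. Censoring is
#' independent exponential, with its rate calibrated so the realized
#' censoring fraction matches `censor_rate`. An ordinal stage (1-4) is
#' generated with correlation `stage_cor` to the true linear predictor.
#'
#' @param n patients.
#' @param n_genes genes.
#' @param beta named coefficient vector (genes absent from it have no
#'   effect); default plants `n_causal` genes at `causal_beta`.
#' @param n_causal,causal_beta used only when `beta` is `NULL`.
#' @param weibull_shape Weibull shape (>1 = increasing hazard).
#' @param median_days baseline median survival time, days.
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param stage_cor correlation of the latent stage score with the true
#'   linear predictor.
#' @param seed integer seed.
#' @return list: `expr` (an [expression_matrix()], genes x patients),
#'   `surv` (a [survival_table()] with stage), `truth` (beta, linear
#'   predictor, censoring rate used).
#' @export
make_survival <- function(n = 800, n_genes = 20, beta = NULL, n_causal = 5,
                          causal_beta = 1, weibull_shape = 1.2,
                          median_days = 730, censor_rate = 0.3,
                          stage_cor = 0.3, seed = 1) {
  set.seed(.child_seed(seed, 3L))
  genes <- sprintf("SG%03d", seq_len(n_genes))
  if (is.null(beta))
    beta <- stats::setNames(c(rep(causal_beta, n_causal),
                              rep(0, n_genes - n_causal)), genes)
  x <- matrix(stats::rnorm(n * n_genes), n, n_genes,
              dimnames = list(sprintf("P%04d", seq_len(n)), genes))
  lp <- drop(x[, names(beta), drop = FALSE] %*% beta)
  lambda0 <- log(2) / median_days^weibull_shape
  u <- stats::runif(n)
  t_event <- (-log(u) / (lambda0 * exp(lp)))^(1 / weibull_shape)
  if (censor_rate > 0) {
    # calibrate exponential censoring rate: E[1 - exp(-r T)] = censor_rate
    f <- function(r) mean(1 - exp(-r * t_event)) - censor_rate
    r <- stats::uniroot(f, c(1e-10, 1e3), tol = 1e-12)$root
    cens <- stats::rexp(n, r)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  lp_std <- if (stats::sd(lp) > 0) scale(lp)[, 1] else rep(0, n)
  z <- stage_cor * lp_std + sqrt(1 - stage_cor^2) * stats::rnorm(n)
  stage <- as.integer(cut(z, stats::quantile(z, c(0, .4, .7, .9, 1)),
                          include.lowest = TRUE, labels = FALSE))
  surv <- survival_table(data.frame(patient = rownames(x),
                                    time = pmax(time, 0.5), event = event,
                                    stage = stage))
  list(expr = expression_matrix(t(x), value_class = "continuous"),
       surv = surv,
       truth = list(beta = beta, lp = lp, censor_rate = censor_rate, seed = seed))
}

#' Simulate ICI cohorts with a logistic response link on a latent hypoxia score
#'
#' Each patient carries a latent hypoxia score `h ~ N(0, latent_sd)`;
#' every signature gene reads it out with unit loading plus N(0, 1)
#' noise, and cohorts add per-gene batch shifts. Response is
#' `Bernoulli(plogis(qlogis(base_rate) + slope * h))`. The default
#' latent scale (`latent_sd = 3`) puts a unit slope in the
#' strongly-predictive regime while slope 0 is exactly uninformative.
#'
#' @param n total patients; split among `cohort_sizes`.
#' @param slope logistic link slope on `h`.
#' @param base_rate response probability at `h = 0`.
#' @param cohort_sizes named integer vector; defaults to `n` split
#'   evenly over 3 cohorts.
#' @param n_genes signature genes measured.
#' @param latent_sd SD of the latent hypoxia score.
#' @param batch_sd SD of per-cohort per-gene mean shifts.
#' @param seed integer seed.
#' @return list: `cohorts` (named list of `list(x, y)` with patients x
#'   genes matrices), `truth` (per-patient `h`, slope, cohort).
#' @export
make_ici <- function(n = 749, slope = 1, base_rate = 0.3, cohort_sizes = NULL,
                     n_genes = 20, latent_sd = 3, batch_sd = 1, seed = 1) {
  set.seed(.child_seed(seed, 4L))
  if (is.null(cohort_sizes)) {
    k <- 3
    cohort_sizes <- stats::setNames(c(rep(n %/% k, k - 1), n - (k - 1) * (n %/% k)),
                                    paste0("cohort", seq_len(k)))
  }
  if (sum(cohort_sizes) != n) stop("cohort_sizes must sum to n")
  genes <- sprintf("HG%03d", seq_len(n_genes))
  h <- stats::rnorm(n, 0, latent_sd)
  pid <- sprintf("I%04d", seq_len(n))
  cohort <- rep(names(cohort_sizes), cohort_sizes)
  x <- matrix(h, n, n_genes) + matrix(stats::rnorm(n * n_genes), n, n_genes)
  dimnames(x) <- list(pid, genes)
  for (co in names(cohort_sizes)) {
    shift <- stats::rnorm(n_genes, 0, batch_sd)
    x[cohort == co, ] <- sweep(x[cohort == co, , drop = FALSE], 2, shift, "+")
  }
  y <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(base_rate) + slope * h))
  cohorts <- lapply(split(seq_len(n), cohort), function(ii)
    list(x = x[ii, , drop = FALSE], y = y[ii]))
  list(cohorts = cohorts[names(cohort_sizes)],
       truth = list(h = stats::setNames(h, pid), slope = slope,
                    cohort = stats::setNames(cohort, pid), seed = seed))
}

#' Simulate paired CRISPR screen matrices with planted hits
#'
#' Two gene x screen z-score matrices (cell-line essentiality and
#' immune screens) with i.i.d. N(0, 1) background. Signature genes are
#' planted as dual hits (shifted by `-hit_effect` in both matrices) or
#' single-matrix hits (shifted in one). With `ensure_separation = TRUE`
#' (default), signature genes *not* planted as hits in a matrix are
#' resampled away from that matrix's low tail, so the planted labels
#' are the identifiable ground truth (the screen analogue of planting
#' copy-number events away from the broadness boundary); background
#' gene marginals are untouched.
#'
#' @param n_genes universe size per matrix.
#' @param n_screens length-2 vector: screens in the cell-line and
#'   immune matrices.
#' @param signature_size signature genes (first in the universe).
#' @param n_dual,n_cellline_only,n_immune_only planted hit counts.
#' @param hit_effect shift magnitude (>= 0).
#' @param ensure_separation keep non-hit signature genes out of the low
#'   tail of matrices they are not planted in.
#' @param seed integer seed.
#' @return list: `cellline`, `immune` (two [screen_matrix()]),
#'   `signature` (a [gene_set()]), `truth` (dual/cellline/immune hit ids).
#' @export
make_screens <- function(n_genes = 2000, n_screens = c(15, 15),
                         signature_size = 68, n_dual = 4, n_cellline_only = 12,
                         n_immune_only = 10, hit_effect = 3,
                         ensure_separation = TRUE, seed = 1) {
  if (n_dual + n_cellline_only + n_immune_only > signature_size)
    stop("more planted hits than signature genes")
  set.seed(.child_seed(seed, 5L))
  genes <- sprintf("CG%04d", seq_len(n_genes))
  sig <- genes[seq_len(signature_size)]
  dual <- sig[seq_len(n_dual)]
  cl_only <- sig[n_dual + seq_len(n_cellline_only)]
  im_only <- sig[n_dual + n_cellline_only + seq_len(n_immune_only)]
  draw <- function(ns, hits, protected) {
    m <- matrix(stats::rnorm(n_genes * ns), n_genes, ns,
                dimnames = list(genes, sprintf("scr%02d", seq_len(ns))))
    m[hits, ] <- m[hits, , drop = FALSE] - hit_effect
    if (ensure_separation && length(protected)) {
      bg_mu <- rowMeans(m[setdiff(genes, sig), , drop = FALSE])
      lo <- stats::quantile(bg_mu, 0.18)
      for (g in protected) {
        tries <- 0
        while (mean(m[g, ]) < lo && tries < 50) {
          m[g, ] <- stats::rnorm(ns)
          tries <- tries + 1
        }
      }
    }
    m
  }
  cellline <- draw(n_screens[1], c(dual, cl_only), setdiff(sig, c(dual, cl_only)))
  immune <- draw(n_screens[2], c(dual, im_only), setdiff(sig, c(dual, im_only)))
  list(cellline = screen_matrix(cellline), immune = screen_matrix(immune),
       signature = gene_set("sim_signature", sig),
       truth = list(dual = dual, cellline_only = cl_only, immune_only = im_only,
                    hit_effect = hit_effect, seed = seed))
}
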