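#' Training/rest partition sizes under the ceiling rule
#'
#' `n_train = ceiling(p * n)`, `n_rest = n - n_train`; reproduces e.g.
#' 749 -> 600/149 and 9637 -> 7710/1927 at p = 0.8.
#'
#' @param n total sample count (>= 2).
#' @param p training fraction in (0, 1).
#' @return integer vector `c(n_train, n_rest)`.
#' @export
partition_sizes <- function(n, p) {
  if (n < 2) stop("need at least 2 samples to partition")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  n_train <- as.integer(ceiling(p * n))
  c(n_train = n_train, n_rest = as.integer(n) - n_train)
}

#' Seeded, response-stratified train/rest split
#'
#' Applies the ceiling rule within each class, so class balance is
#' preserved up to one patient. A class with a single member goes to the
#' training side with a warning.
#'
#' @param response binary vector (0/1 or two-level factor).
#' @param p training fraction.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train` and `rest`.
#' @export
stratified_split <- function(response, p, seed) {
  n <- length(response)
  if (n < 2) stop("need at least 2 samples")
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cls in unique(response)) {
    idx <- which(response == cls)
    if (length(idx) == 1) {
      warning("class with a single member assigned to training")
      train <- c(train, idx)
    } else {
      k <- partition_sizes(length(idx), p)[["n_train"]]
      train <- c(train, sample(idx, k))
    }
  }
  train <- sort(train)
  list(train = train, rest = setdiff(seq_len(n), train))
}

# Stratified fold assignment for k-fold CV.
.make_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mean CV AUC of one learner/grid-point under repeats x k-fold CV.
.cv_auc <- function(x, y, learner, params, folds, repeats, seed) {
  aucs <- c()
  for (r in seq_len(repeats)) {
    fold <- .make_folds(y, folds, seed + 1000L * r)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
      model <- learner$fit(x[tr, , drop = FALSE], y[tr], params)
      pr <- learner$predict(model, x[!tr, , drop = FALSE])
      aucs <- c(aucs, roc_auc(pr, y[!tr]))
    }
  }
  mean(aucs)
}

#' Train six learners under repeated CV and select by validation AUC
#'
#' Features are z-scored on the training set (zero-variance features are
#' dropped); each learner's tuning grid is searched by mean AUC over
#' `repeats` x `folds` cross-validation, the learner is refit on the full
#' training set at its best grid point, and the learner with the highest
#' AUC on the held-out validation set wins (ties go to the
#' lexicographically first learner id).
#'
#' @param train_x,train_y training features (patients x genes) and 0/1
#'   response.
#' @param val_x,val_y held-out validation set used only for the final
#'   selection.
#' @param learners learner registry, see [ici_learners()].
#' @param folds,repeats cross-validation protocol (default 10-fold,
#'   5 repeats).
#' @param seed integer seed controlling fold assignment.
#' @return list of class `model_selection`: `chosen`, `val_auc` (named,
#'   all learners), `cv` (data.frame learner/params/cv_auc), `model`
#'   (fitted winner), plus the preprocessing constants (`center`,
#'   `scale`, `features`) needed to score new cohorts.
#' @export
train_select <- function(train_x, train_y, val_x, val_y,
                         learners = ici_learners(), folds = 10, repeats = 5,
                         seed = 1) {
  train_x <- as.matrix(train_x); val_x <- as.matrix(val_x)
  train_y <- as.integer(train_y); val_y <- as.integer(val_y)
  if (min(table(train_y)) < folds)
    stop("need at least `folds` patients per class in the training set")
  keep <- apply(train_x, 2, stats::sd) > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance feature(s) dropped")
  train_x <- train_x[, keep, drop = FALSE]
  ctr <- colMeans(train_x); scl <- apply(train_x, 2, stats::sd)
  zx <- scale(train_x, ctr, scl)
  zv <- scale(val_x[, colnames(train_x), drop = FALSE], ctr, scl)

  learners <- learners[order(names(learners))]
  cv_rows <- list(); fits <- list(); val_auc <- c()
  for (id in names(learners)) {
    ln <- learners[[id]]
    grid_auc <- vapply(seq_len(nrow(ln$grid)), function(g)
      .cv_auc(zx, train_y, ln, ln$grid[g, , drop = FALSE], folds, repeats,
              seed + match(id, names(learners))),
      numeric(1))
    best <- which.max(grid_auc)
    set.seed(as.integer(seed) + 7L * match(id, names(learners)))
    model <- ln$fit(zx, train_y, ln$grid[best, , drop = FALSE])
    pr <- ln$predict(model, zv)
    val_auc[id] <- roc_auc(pr, val_y)
    fits[[id]] <- model
    cv_rows[[id]] <- data.frame(learner = id,
                                params = paste(names(ln$grid),
                                               unlist(ln$grid[best, ]),
                                               sep = "=", collapse = ","),
                                cv_auc = grid_auc[best])
  }
  chosen <- names(val_auc)[which.max(val_auc)]  # which.max -> first on ties
  structure(list(chosen = chosen, val_auc = val_auc,
                 cv = do.call(rbind, c(cv_rows, list(make.row.names = FALSE))),
                 model = fits[[chosen]], learner = learners[[chosen]],
                 center = ctr, scale = scl, features = colnames(train_x)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chosen: %s (validation AUC %.3f)\n",
              x$chosen, x$val_auc[x$chosen]))
  invisible(x)
}

#' Score of the selected model on a new feature matrix
#' @param selection a `model_selection`.
#' @param x patients x genes matrix; genes missing from the model's
#'   feature space are imputed to the training mean (with a message).
#' @return numeric vector of predicted responder probabilities.
#' @export
predict_response <- function(selection, x) {
  x <- as.matrix(x)
  missing <- setdiff(selection$features, colnames(x))
  if (length(missing)) {
    message(length(missing), " gene(s) missing; imputed to training mean")
    fill <- matrix(rep(selection$center[missing], each = nrow(x)),
                   nrow = nrow(x), dimnames = list(rownames(x), missing))
    x <- cbind(x, fill)
  }
  z <- scale(x[, selection$features, drop = FALSE],
             selection$center, selection$scale)
  selection$learner$predict(selection$model, z)
}

#' Evaluate the selected model on independent cohorts
#'
#' @param selection a `model_selection` from [train_select()].
#' @param cohorts named list; each element a list with `x` (patients x
#'   genes) and `y` (0/1 response). Cohorts with a single class are
#'   skipped with a warning.
#' @return data.frame (cohort, n, auc) with a final `pooled` row
#'   computed on the concatenated predictions.
#' @export
evaluate_cohorts <- function(selection, cohorts) {
  rows <- list(); all_pr <- c(); all_y <- c()
  for (id in names(cohorts)) {
    co <- cohorts[[id]]
    if (length(unique(co$y)) < 2) {
      warning("cohort ", id, " has a single response class; skipped")
      next
    }
    pr <- predict_response(selection, co$x)
    rows[[id]] <- data.frame(cohort = id, n = length(co$y),
                             auc = roc_auc(pr, co$y))
    all_pr <- c(all_pr, pr); all_y <- c(all_y, co$y)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cohort = character(0), n = integer(0), auc = numeric(0)))
  if (length(all_y) && length(unique(all_y)) > 1)
    out <- rbind(out, data.frame(cohort = "pooled", n = length(all_y),
                                 auc = roc_auc(all_pr, all_y)))
  rownames(out) <- NULL
  out
}

#' Merge ICI cohorts into one expression/response dataset
#'
#' Optionally removes per-cohort location/scale batch effects: `"combat"`
#' uses the empirical-Bayes batch adjustment from the sva package (if
#' installed), `"standardize"` z-scores each gene within each cohort,
#' `"none"` concatenates unchanged. The method actually applied is
#' recorded in the `batch_method` attribute.
#'
#' @param cohorts named list of lists with `x` (patients x genes) and `y`.
#' @param batch one of `"none"`, `"standardize"`, `"combat"`.
#' @return list with `x`, `y`, `cohort` (per-patient id) and attribute
#'   `batch_method`.
#' @export
merge_cohorts <- function(cohorts, batch = c("none", "standardize", "combat")) {
  batch <- match.arg(batch)
  x <- do.call(rbind, lapply(cohorts, `[[`, "x"))
  y <- unlist(lapply(cohorts, `[[`, "y"), use.names = FALSE)
  cohort <- rep(names(cohorts), vapply(cohorts, function(c) length(c$y), 0L))
  applied <- batch
  if (batch == "combat") {
    if (requireNamespace("sva", quietly = TRUE)) {
      x <- t(sva::ComBat(t(x), batch = factor(cohort)))
    } else {
      applied <- "standardize"
      warning("sva not available; falling back to per-cohort standardization")
    }
  }
  if (applied == "standardize") {
    for (id in unique(cohort)) {
      ii <- cohort == id
      x[ii, ] <- scale(x[ii, , drop = FALSE])
    }
    x[is.na(x)] <- 0
  }
  out <- list(x = x, y = y, cohort = cohort)
  attr(out, "batch_method") <- applied
  out
}

#' Design sizes of the nine-cohort ICI compendium
#'
#' The per-cohort patient counts of the public immune-checkpoint-inhibitor
#' RNA-seq compendium the harness emulates: five cohorts merged into the
#' model-building set and four held out as external tests.
#'
#' @return data.frame (cohort, cancer_type, n, role).
#' @export
ici_cohort_sizes <- function() {
  data.frame(
    cohort = c("Braun_RCC", "Mariathasan_UC", "Liu_SKCM", "Gide_SKCM", "Hugo_SKCM",
               "Riaz_SKCM", "Van_SKCM", "Kim_GC", "Snyder_UC"),
    cancer_type = c("RCC", "UC", "SKCM", "SKCM", "SKCM", "SKCM", "SKCM", "GC", "UC"),
    n = c(181L, 348L, 121L, 73L, 26L, 49L, 36L, 45L, 25L),
    role = c(rep("merged", 5), rep("external", 4)),
    stringsAsFactors = FALSE)
}
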