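#' Consensus gene selection for the survival risk model
#'
#' Three feature selectors are run independently and their selected gene
#' sets intersected: an L1-penalized Cox model (glmnet, genes with
#' non-zero coefficients at the cross-validated lambda.min), a random
#' survival forest (ranger, genes with positive permutation importance),
#' and gradient-boosted Cox trees (xgboost survival:cox objective, genes
#' with non-zero gain). If the three-way intersection is empty, the
#' union of the pairwise intersections is used instead (with a warning).
#'
#' @param x patients x genes numeric matrix.
#' @param surv a [survival_table()] aligned to `rownames(x)`.
#' @param selectors subset of `c("l1_cox", "rsf_importance", "boosted_cox")`.
#' @param seed integer seed for the stochastic selectors.
#' @return character vector of selected genes, with the per-selector
#'   sets in the `per_selector` attribute.
#' @export
consensus_select <- function(x, surv,
                             selectors = c("l1_cox", "rsf_importance", "boosted_cox"),
                             seed = 1) {
  x <- as.matrix(x)
  if (!all(rownames(x) == surv$patient)) stop("x rows must match surv patients")
  if (sum(surv$event) < 2) stop("need at least 2 events")
  selectors <- match.arg(selectors, several.ok = TRUE)
  y <- survival::Surv(surv$time, surv$event)
  sets <- list()
  if ("l1_cox" %in% selectors) {
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = 5)
    b <- as.matrix(stats::coef(cv, s = "lambda.min"))
    sets$l1_cox <- rownames(b)[b[, 1] != 0]
  }
  if ("rsf_importance" %in% selectors) {
    d <- data.frame(time = surv$time, event = surv$event, x, check.names = FALSE)
    rf <- ranger::ranger(survival::Surv(time, event) ~ ., data = d,
                         num.trees = 300, importance = "permutation",
                         seed = as.integer(seed) + 1L)
    imp <- rf$variable.importance
    sets$rsf_importance <- names(imp)[imp > 0]
  }
  if ("boosted_cox" %in% selectors) {
    label <- ifelse(surv$event == 1, surv$time, -surv$time)
    set.seed(as.integer(seed) + 2L)
    dm <- xgboost::xgb.DMatrix(x, label = label)
    bst <- xgboost::xgb.train(params = list(objective = "survival:cox",
                                            max_depth = 2, eta = 0.1, nthread = 1),
                              data = dm, nrounds = 100, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    sets$boosted_cox <- imp$Feature[imp$Gain > 0]
  }
  common <- Reduce(intersect, sets)
  if (!length(common) && length(sets) > 1) {
    warning("empty consensus; falling back to the union of pairwise intersections")
    pairs <- utils::combn(names(sets), 2, simplify = FALSE)
    common <- unique(unlist(lapply(pairs, function(p)
      intersect(sets[[p[1]]], sets[[p[2]]]))))
  }
  structure(common, per_selector = sets)
}

#' Bidirectional stepwise Cox model by AIC
#'
#' Starts from the null model and adds/drops candidates (processed in
#' the fixed input order, so the procedure is deterministic) by AIC.
#' Ties in the partial likelihood are handled by Efron's method. A
#' candidate that breaks convergence is dropped with a message.
#'
#' @param x patients x genes matrix.
#' @param surv a [survival_table()] aligned to `rownames(x)`.
#' @param candidates character vector of candidate genes (non-empty).
#' @return list of class `risk_model`: `coef` (named, possibly empty),
#'   `fit` (the final `coxph`, or `NULL` for the empty model),
#'   `candidates`.
#' @export
stepwise_cox <- function(x, surv, candidates) {
  if (!length(candidates)) stop("candidates must be non-empty")
  x <- as.matrix(x)
  if (!all(candidates %in% colnames(x)))
    stop("candidates missing from x: ",
         paste(setdiff(candidates, colnames(x)), collapse = ", "))
  d <- data.frame(time = surv$time, event = surv$event,
                  x[, candidates, drop = FALSE], check.names = FALSE)
  ok <- candidates
  for (g in candidates) {
    fit1 <- tryCatch(survival::coxph(survival::Surv(time, event) ~ .,
                                     data = d[, c("time", "event", g)]),
                     warning = function(w)
                       if (grepl("infinite|converge", conditionMessage(w))) w
                       else suppressWarnings(
                         survival::coxph(survival::Surv(time, event) ~ .,
                                         data = d[, c("time", "event", g)])),
                     error = function(e) e)
    if (inherits(fit1, "condition")) {
      message("candidate dropped (no stable univariate fit): ", g)
      ok <- setdiff(ok, g)
    }
  }
  if (!length(ok))
    return(structure(list(coef = stats::setNames(numeric(0), character(0)),
                          fit = NULL, candidates = candidates),
                     class = "risk_model"))
  d <- d[, c("time", "event", ok), drop = FALSE]
  null_fit <- survival::coxph(survival::Surv(time, event) ~ 1, data = d)
  scope <- stats::as.formula(paste("~", paste(sprintf("`%s`", ok), collapse = " + ")))
  step_fit <- suppressWarnings(
    MASS::stepAIC(null_fit, scope = list(lower = ~1, upper = scope),
                  direction = "both", trace = 0))
  cf <- stats::coef(step_fit)
  if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
  names(cf) <- gsub("`", "", names(cf))
  structure(list(coef = cf,
                 fit = if (length(cf)) step_fit else NULL,
                 candidates = candidates),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d of %d candidates retained\n",
              length(x$coef), length(x$candidates)))
  if (length(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' Linear risk score: sum of coefficient x expression
#'
#' @param x patients x genes matrix; every model gene must be present
#'   (missing genes are an error, never imputed).
#' @param model a `risk_model` (or any named coefficient vector).
#' @return named numeric vector of per-patient risk scores (identically
#'   0 for an empty model).
#' @export
risk_score <- function(x, model) {
  cf <- if (inherits(model, "risk_model")) model$coef else model
  x <- as.matrix(x)
  if (!length(cf)) return(stats::setNames(rep(0, nrow(x)), rownames(x)))
  missing <- setdiff(names(cf), colnames(x))
  if (length(missing))
    stop("model genes missing from expression: ", paste(missing, collapse = ", "))
  drop(x[, names(cf), drop = FALSE] %*% cf)
}

#' Median-split Kaplan-Meier curves and log-rank test
#'
#' Patients are split at the median score (strictly greater = high; the
#' package-wide tie rule), so any strictly monotone transform of the
#' score gives the same groups. Reports the product-limit curves and the
#' 1-df log-rank chi-square.
#'
#' @param scores named per-patient numeric scores.
#' @param surv a [survival_table()] covering the same patients.
#' @return list: `groups`, `fit` (a `survfit`), `chisq`, `p.value`.
#' @export
km_logrank <- function(scores, surv) {
  if (!setequal(names(scores), surv$patient)) stop("scores must cover surv patients")
  scores <- scores[surv$patient]
  group <- median_split(scores)
  if (min(table(group)) < 2) stop("need at least 2 patients per group")
  d <- data.frame(time = surv$time, event = surv$event, group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(groups = group,
       fit = survival::survfit(survival::Surv(time, event) ~ group, data = d),
       chisq = unname(sd_$chisq),
       p.value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox regression with risk-factor classification
#'
#' Single-covariate partial-likelihood fit (Efron ties); Wald p and 95%
#' CI. Classification per the conventional reading: `"risk"` when
#' p < 0.05 and HR > 1, `"protective"` when p < 0.05 and HR < 1,
#' `"ns"` otherwise; a zero-variance feature returns `"undefined"`.
#'
#' @param feature named per-patient numeric covariate.
#' @param surv a [survival_table()].
#' @return list: `hr`, `ci` (length 2), `p.value`, `log_hr`, `class`.
#' @export
univariate_cox <- function(feature, surv) {
  if (!is.null(names(feature))) feature <- feature[surv$patient]
  if (stats::sd(feature) == 0)
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p.value = NA_real_,
                log_hr = NA_real_, class = "undefined"))
  d <- data.frame(time = surv$time, event = surv$event, x = feature)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
  s <- summary(fit)
  hr <- unname(s$conf.int[1, "exp(coef)"])
  ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
  p <- unname(s$coefficients[1, "Pr(>|z|)"])
  cls <- if (p < 0.05 && hr > 1) "risk" else if (p < 0.05 && hr < 1) "protective" else "ns"
  list(hr = hr, ci = ci, p.value = p, log_hr = unname(stats::coef(fit)[1]),
       class = cls)
}

#' Nomogram score combining risk score and clinical stage
#'
#' Multivariable Cox linear predictor over the risk score and ordinal
#' stage (1-4; `stage_categorical = TRUE` instead enters stage as a
#' factor). Patients without a stage are excluded (with a message).
#' Calibration compares the Breslow-baseline predicted survival
#' probability with the Kaplan-Meier observed probability within
#' predictor deciles at the requested horizons.
#'
#' @param risk named per-patient risk scores.
#' @param surv a [survival_table()] with a `stage` column.
#' @param times horizons (same units as `surv$time`) for calibration.
#' @param n_groups number of predictor groups for calibration (default
#'   10, i.e. deciles; reduced automatically for small cohorts).
#' @param stage_categorical treat stage as a factor.
#' @return list of class `nomogram_result`: `score` (linear predictor),
#'   `fit`, `calibration` (data.frame time/group/n/predicted/observed),
#'   `excluded` (patients without stage).
#' @export
nomogram_score <- function(risk, surv, times, n_groups = 10,
                           stage_categorical = FALSE) {
  if (!"stage" %in% names(surv)) stop("surv must carry a stage column")
  risk <- risk[surv$patient]
  has_stage <- !is.na(surv$stage)
  if (!all(has_stage))
    message(sum(!has_stage), " patient(s) without stage excluded")
  surv <- surv[has_stage, , drop = FALSE]
  risk <- risk[has_stage]
  stage <- if (stage_categorical) factor(surv$stage) else as.numeric(surv$stage)
  d <- data.frame(time = surv$time, event = surv$event, risk = risk, stage = stage)
  fit <- survival::coxph(survival::Surv(time, event) ~ risk + stage, data = d)
  lp <- unname(predict(fit, type = "lp"))
  names(lp) <- surv$patient
  # Breslow baseline cumulative hazard at the mean-zero linear predictor
  bh <- survival::basehaz(fit, centered = TRUE)
  H0 <- stats::stepfun(bh$time, c(0, bh$hazard))
  lp_c <- lp - mean(lp)
  grp <- cut(rank(lp, ties.method = "first"),
             breaks = min(n_groups, max(2, floor(length(lp) / 5))),
             labels = FALSE)
  cal <- list()
  for (t0 in times) {
    for (g in sort(unique(grp))) {
      ii <- grp == g
      pred <- mean(exp(-H0(t0) * exp(lp_c[ii])))
      kmf <- survival::survfit(survival::Surv(time, event) ~ 1,
                               data = d[ii, , drop = FALSE])
      obs <- summary(kmf, times = t0, extend = TRUE)$surv
      cal[[length(cal) + 1]] <- data.frame(time = t0, group = g, n = sum(ii),
                                           predicted = pred, observed = obs)
    }
  }
  structure(list(score = lp, fit = fit, calibration = do.call(rbind, cal),
                 excluded = sum(!has_stage)),
            class = "nomogram_result")
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases are
#' patients with an observed event at or before `t` (weighted by
#' 1/G(T-)), controls are patients still at risk after `t` (weighted by
#' 1/G(t)), where G is the Kaplan-Meier estimator of the censoring
#' distribution. With no censoring every weight is 1 and the quantity
#' reduces to [roc_auc()] of the scores against `I(time <= t)`.
#'
#' @param scores per-patient risk scores (higher = earlier event).
#' @param surv a [survival_table()].
#' @param t evaluation horizon; needs at least one event at or before
#'   `t` and one patient at risk after `t`, otherwise `NA` is returned
#'   with a warning.
#' @return AUC(t) in \[0, 1\], ties counted 1/2.
#' @export
time_dependent_auc <- function(scores, surv, t) {
  if (!is.null(names(scores))) scores <- scores[surv$patient]
  time <- surv$time; event <- surv$event
  case <- time <= t & event == 1
  ctrl <- time > t
  if (!any(case) || !any(ctrl)) {
    warning("no evaluable cases or controls at t = ", t)
    return(NA_real_)
  }
  # censoring KM: G(u) = P(C > u)
  gfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(gfit$time, c(1, gfit$surv))
  Gminus <- function(u) G(u - 1e-9)
  wc <- 1 / pmax(Gminus(time[case]), 1e-9)
  wd <- rep(1 / pmax(G(t), 1e-9), sum(ctrl))
  sc <- scores[case]; sd_ <- scores[ctrl]
  num <- 0
  for (i in seq_along(sc)) {
    num <- num + wc[i] * sum(wd * ((sc[i] > sd_) + 0.5 * (sc[i] == sd_)))
  }
  num / (sum(wc) * sum(wd))
}
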