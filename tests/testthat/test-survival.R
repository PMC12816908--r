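test_that("risk scores are exact linear combinations", {
  x <- matrix(c(2, 1, 4, 3), 2, 2,
              dimnames = list(c("p1", "p2"), c("gA", "gB")))
  model <- c(gA = 0.5, gB = -0.2)
  rs <- risk_score(x, model)
  expect_equal(unname(rs["p1"]), 0.5 * 2 - 0.2 * 4)
  expect_equal(risk_score(x, model * 2), rs * 2)
  expect_equal(unname(risk_score(x, c(gA = 0, gB = 0))), c(0, 0))
  expect_error(risk_score(x, c(gA = 1, gZ = 1)), "gZ")
})

test_that("log-rank on the six-patient fixture equals the hand oracle", {
  surv <- six_patient_surv()
  scores <- six_patient_scores()
  kl <- km_logrank(scores, surv)
  in_high <- kl$groups == "high"
  expect_equal(kl$chisq,
               logrank_oracle(surv$time, surv$event, in_high),
               tolerance = 1e-9)
  # KM starts at 1
  expect_true(all(summary(kl$fit, times = 0, extend = TRUE)$surv == 1))
  # identical survival in both groups -> statistic near 0
  s2 <- survival_table(data.frame(patient = paste0("q", 1:10),
                                  time = rep(c(2, 4, 6, 8, 10), 2),
                                  event = rep(c(1, 0, 1, 0, 1), 2)))
  sc2 <- stats::setNames(rep(c(1, 2), each = 5), s2$patient)
  kl2 <- km_logrank(sc2, s2)
  expect_lt(kl2$chisq, 1e-9)
  # monotone-transform invariance: groups depend on ranks only
  kl3 <- km_logrank(exp(scores), surv)
  expect_identical(kl3$groups, kl$groups)
  expect_equal(kl3$chisq, kl$chisq)
})

test_that("univariate Cox recovers a known hazard ratio and flags degeneracy", {
  set.seed(9)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  tt <- rexp(n, rate = 0.01 * exp(grp))   # true log HR = 1
  surv <- survival_table(data.frame(patient = paste0("p", 1:n),
                                    time = tt, event = 1))
  uc <- univariate_cox(stats::setNames(grp, surv$patient), surv)
  expect_lt(abs(uc$log_hr - 1), 0.1)
  expect_identical(uc$class, "risk")
  uc0 <- univariate_cox(stats::setNames(rep(1, n), surv$patient), surv)
  expect_identical(uc0$class, "undefined")
})

test_that("stepwise selection keeps signal and discards pure noise", {
  sim <- make_survival(n = 400, n_genes = 8, n_causal = 2, causal_beta = 1,
                       seed = 6)
  x <- t(as_matrix(sim$expr))
  rm_ <- stepwise_cox(x, sim$surv, candidates = colnames(x))
  planted <- names(sim$truth$beta)[sim$truth$beta != 0]
  expect_true(all(planted %in% names(rm_$coef)))
  expect_true(all(rm_$coef[planted] > 0))   # correct sign
  # null candidates: few retained on average over seeds
  retained <- vapply(1:5, function(s) {
    sim0 <- make_survival(n = 300, n_genes = 10, n_causal = 0, seed = 100 + s)
    x0 <- t(as_matrix(sim0$expr))
    length(stepwise_cox(x0, sim0$surv, candidates = colnames(x0))$coef)
  }, numeric(1))
  expect_lt(mean(retained), 2)
})

test_that("consensus selection intersects selectors and handles agreement", {
  sim <- make_survival(n = 500, n_genes = 12, n_causal = 3, seed = 8)
  x <- t(as_matrix(sim$expr))
  sel <- consensus_select(x, sim$surv, seed = 8)
  per <- attr(sel, "per_selector")
  expect_length(per, 3)
  manual <- Reduce(intersect, per)
  expect_setequal(sel, manual)
  planted <- names(sim$truth$beta)[sim$truth$beta != 0]
  expect_gte(sum(planted %in% sel), 2)
  # a single selector returns its own set unchanged
  one <- consensus_select(x, sim$surv, selectors = "l1_cox", seed = 8)
  expect_setequal(one, attr(one, "per_selector")$l1_cox)
})

test_that("nomogram scores track risk when stage is uninformative and calibrate", {
  sim <- make_survival(n = 600, n_genes = 6, n_causal = 2, stage_cor = 0,
                       seed = 14)
  x <- t(as_matrix(sim$expr))
  rs <- stats::setNames(drop(x %*% sim$truth$beta), rownames(x))
  nr <- nomogram_score(rs, sim$surv, times = c(365, 730))
  # risk dominates: nomogram score ordering close to risk ordering
  expect_gt(cor(nr$score[names(rs)], rs, method = "spearman"), 0.95)
  cal <- nr$calibration
  expect_true(all(cal$predicted >= 0 & cal$predicted <= 1))
  # calibration slope near 1 on well-specified data
  fit <- lm(observed ~ predicted, data = cal[is.finite(cal$observed), ])
  expect_gt(coef(fit)[2], 0.8)
  expect_lt(coef(fit)[2], 1.2)
  # missing stage excluded with a message
  surv2 <- sim$surv; surv2$stage[1:10] <- NA
  expect_message(nr2 <- nomogram_score(rs, surv2, times = 365), "without stage")
  expect_equal(length(nr2$score), nrow(sim$surv) - 10)
})

test_that("time-dependent AUC reduces to plain AUC without censoring", {
  sim <- make_survival(n = 300, censor_rate = 0, seed = 5)
  x <- t(as_matrix(sim$expr))
  rs <- stats::setNames(drop(x %*% sim$truth$beta), rownames(x))
  t0 <- median(sim$surv$time)
  expect_equal(time_dependent_auc(rs, sim$surv, t0),
               roc_auc(rs, sim$surv$time <= t0), tolerance = 1e-9)
  # perfect score = -time gives AUC 1 at any evaluable horizon
  perfect <- stats::setNames(-sim$surv$time, sim$surv$patient)
  for (tq in quantile(sim$surv$time, c(0.25, 0.5, 0.75)))
    expect_equal(time_dependent_auc(perfect, sim$surv, tq), 1)
  # censored data stays close to the uncensored value on the same latents
  simc <- make_survival(n = 2000, censor_rate = 0.3, seed = 15)
  simu <- make_survival(n = 2000, censor_rate = 0, seed = 15)
  xs <- t(as_matrix(simu$expr))
  sc <- stats::setNames(drop(xs %*% simu$truth$beta), rownames(xs))
  tmid <- median(simu$surv$time)
  expect_lt(abs(time_dependent_auc(sc, simc$surv, tmid) -
                time_dependent_auc(sc, simu$surv, tmid)), 0.03)
  expect_warning(expect_true(is.na(
    time_dependent_auc(sc, simu$surv, min(simu$surv$time) / 2))), "evaluable")
})
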