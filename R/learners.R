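# Binary-classification learner registry for the ICI harness.
#
# Each learner is a list(grid, fit(x, y, params) -> model,
# predict(model, x) -> P(class 1)). x is a numeric matrix (patients x
# features, already z-scored by the harness), y is a 0/1 integer vector.
# Grids are deliberately small; the harness (not the learners) owns the
# repeated cross-validation that picks among grid points.

.fit_stump <- function(x, y, w) {
  d <- data.frame(y = y, x)
  rpart::rpart(y ~ ., data = d, weights = w,
               method = "class",
               control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                              minsplit = 2, xval = 0))
}

# AdaBoost.M1 with decision stumps (exponential reweighting).
.adaboost_fit <- function(x, y, iters = 50) {
  n <- length(y)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  stumps <- vector("list", iters)
  alpha <- numeric(iters)
  used <- 0
  for (m in seq_len(iters)) {
    st <- .fit_stump(x, factor(y, levels = 0:1), w)
    pred <- as.integer(as.character(predict(st, data.frame(x), type = "class")))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1) break
    a <- 0.5 * log((1 - err) / err)
    pp <- ifelse(pred == 1, 1, -1)
    w <- w * exp(-a * yy * pp)
    w <- w / sum(w)
    stumps[[m]] <- st; alpha[m] <- a; used <- m
  }
  list(stumps = stumps[seq_len(used)], alpha = alpha[seq_len(used)])
}

.adaboost_predict <- function(model, x) {
  if (!length(model$stumps)) return(rep(0.5, nrow(x)))
  f <- rowSums(vapply(seq_along(model$stumps), function(m) {
    pred <- as.integer(as.character(
      predict(model$stumps[[m]], data.frame(x), type = "class")))
    model$alpha[m] * ifelse(pred == 1, 1, -1)
  }, numeric(nrow(x))))
  stats::plogis(2 * f)
}

# LogitBoost with decision stumps (Newton steps on the binomial
# log-likelihood; working responses capped as usual).
.logitboost_fit <- function(x, y, iters = 50, shrink = 0.5) {
  n <- length(y)
  f <- rep(0, n)
  stumps <- vector("list", iters)
  for (m in seq_len(iters)) {
    p <- stats::plogis(2 * f)
    w <- pmax(p * (1 - p), 1e-5)
    z <- pmin(pmax((y - p) / w, -4), 4)
    d <- data.frame(z = z, x)
    st <- rpart::rpart(z ~ ., data = d, weights = w, method = "anova",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2, xval = 0))
    f <- f + shrink * 0.5 * predict(st, data.frame(x))
    stumps[[m]] <- st
  }
  list(stumps = stumps, shrink = shrink)
}

.logitboost_predict <- function(model, x) {
  f <- rep(0, nrow(x))
  for (st in model$stumps) f <- f + model$shrink * 0.5 * predict(st, data.frame(x))
  stats::plogis(2 * f)
}

#' Default learner specifications for the ICI response harness
#'
#' Six binary classifiers: a random forest, naive Bayes, AdaBoost with
#' decision stumps, k-nearest neighbors, a class-weighted RBF support
#' vector machine, and boosted logistic regression (LogitBoost stumps).
#' Each specification carries a small tuning grid searched by the
#' harness's repeated cross-validation.
#'
#' @return named list of learner specifications (alphabetical order; the
#'   harness breaks selection ties by this order).
#' @export
ici_learners <- function() {
  list(
    adaboost = list(
      grid = data.frame(iters = c(25, 50)),
      fit = function(x, y, params) .adaboost_fit(x, y, iters = params$iters),
      predict = .adaboost_predict),
    boosted_logistic = list(
      grid = data.frame(iters = c(25, 50)),
      fit = function(x, y, params) .logitboost_fit(x, y, iters = params$iters),
      predict = .logitboost_predict),
    knn = list(
      grid = data.frame(k = c(5, 15)),
      fit = function(x, y, params) list(x = x, y = y, k = params$k),
      predict = function(model, x) {
        k <- min(model$k, nrow(model$x))
        pr <- class::knn(model$x, x, factor(model$y, levels = 0:1),
                         k = k, prob = TRUE)
        pwin <- attr(pr, "prob")
        ifelse(pr == "1", pwin, 1 - pwin)
      }),
    naive_bayes = list(
      grid = data.frame(laplace = 0),
      fit = function(x, y, params)
        e1071::naiveBayes(x, factor(y, levels = 0:1), laplace = params$laplace),
      predict = function(model, x) predict(model, x, type = "raw")[, "1"]),
    random_forest = list(
      grid = data.frame(mtry_frac = c(0.33, 0.8)),
      fit = function(x, y, params)
        randomForest::randomForest(x, factor(y, levels = 0:1), ntree = 300,
                                   mtry = max(1, floor(params$mtry_frac * sqrt(ncol(x)) * 2))),
      predict = function(model, x) predict(model, x, type = "prob")[, "1"]),
    svm_rbf_weighted = list(
      grid = data.frame(cost = c(1, 10)),
      fit = function(x, y, params) {
        cw <- length(y) / (2 * table(factor(y, levels = 0:1)))
        e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                   cost = params$cost, probability = TRUE,
                   class.weights = stats::setNames(as.numeric(cw), names(cw)))
      },
      predict = function(model, x) {
        pr <- predict(model, x, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      })
  )
}
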