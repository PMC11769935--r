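# Classifier registry for the seven-algorithm bench.
#
# Every learner is a function(x_train, y_train, seed) returning an object
# with a score(x_new) method yielding P(positive) in [0, 1]. Margin-only
# classifiers map their decision value through a logistic link so that a
# 0.5 threshold is meaningful. All learners are single-threaded and fully
# determined by (data, seed).

.learner_svm <- function(x, y, seed) {
  fit <- with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)),
                                    kernel = "radial", cost = 1,
                                    scale = FALSE))
  # orient the decision value toward the positive class
  flip <- if (fit$labels[1] == 2) 1 else -1  # levels c(0,1): index 2 is "1"
  list(score = function(xn) {
    dv <- attr(stats::predict(fit, xn, decision.values = TRUE),
               "decision.values")[, 1]
    stats::plogis(flip * dv)
  })
}

.learner_random_forest <- function(x, y, seed) {
  fit <- with_seed(seed, randomForest::randomForest(
    x, factor(y, levels = c(0, 1)), ntree = 300))
  list(score = function(xn)
    stats::predict(fit, xn, type = "prob")[, "1"])
}

.learner_extra_trees <- function(x, y, seed) {
  d <- data.frame(x, .y = factor(y, levels = c(0, 1)))
  fit <- ranger::ranger(dependent.variable.name = ".y", data = d,
                        num.trees = 300, splitrule = "extratrees",
                        probability = TRUE, num.threads = 1,
                        seed = as.integer(seed))
  list(score = function(xn)
    stats::predict(fit, data.frame(xn), num.threads = 1)$predictions[, "1"])
}

.xgb_learner <- function(eta, max_depth, nrounds) {
  function(x, y, seed) {
    dtr <- xgboost::xgb.DMatrix(x, label = y)
    fit <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = eta,
                    max_depth = max_depth, nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0))
    list(score = function(xn)
      stats::predict(fit, xgboost::xgb.DMatrix(xn)))
  }
}

# Discrete AdaBoost (SAMME for two classes) over depth-1 rpart stumps.
.learner_adaboost <- function(x, y, seed, n_rounds = 50L) {
  n <- nrow(x)
  d <- data.frame(x)
  d$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                              minbucket = 1, xval = 0)
  with_seed(seed, for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = ctl)
    pred <- stats::predict(fit, d, type = "class")
    miss <- pred != d$.y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
    if (err < 1e-9) break
  })
  list(score = function(xn) {
    dn <- data.frame(xn)
    if (!length(stumps)) return(rep(0.5, nrow(dn)))
    f <- numeric(nrow(dn))
    for (m in seq_along(stumps)) {
      pm <- stats::predict(stumps[[m]], dn, type = "class")
      f <- f + alphas[m] * ifelse(pm == "1", 1, -1)
    }
    stats::plogis(2 * f)
  })
}

# Bootstrap-aggregated classification trees.
.learner_bagging <- function(x, y, seed, n_trees = 25L) {
  d <- data.frame(x)
  d$.y <- factor(y, levels = c(0, 1))
  ctl <- rpart::rpart.control(cp = 0.01, minsplit = 4, xval = 0)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    repeat {  # redraw degenerate single-class bootstrap samples
      idx <- sample(nrow(d), nrow(d), replace = TRUE)
      if (length(unique(d$.y[idx])) == 2L) break
    }
    rpart::rpart(.y ~ ., data = d[idx, , drop = FALSE], method = "class",
                 control = ctl)
  }))
  list(score = function(xn) {
    dn <- data.frame(xn)
    p <- vapply(trees, function(tr) stats::predict(tr, dn, type = "prob")[, "1"],
                numeric(nrow(dn)))
    rowMeans(matrix(p, nrow = nrow(dn)))
  })
}

#' The seven-algorithm classifier registry
#'
#' Named list of learner constructors used by the classification bench:
#' `adaboost`, `bagging`, `extra_trees`, `gradient_boosting`,
#' `random_forest`, `svm`, `xgboost`. Each is called as
#' `fn(x_train, y_train, seed)` and returns `list(score = function(x_new))`
#' producing positive-class scores in `[0, 1]`.
#'
#' @param algorithms Character subset to return (default all seven).
#' @return Named list of learner constructors.
#' @export
classifier_registry <- function(algorithms = NULL) {
  reg <- list(
    adaboost = .learner_adaboost,
    bagging = .learner_bagging,
    extra_trees = .learner_extra_trees,
    gradient_boosting = .xgb_learner(eta = 0.1, max_depth = 3, nrounds = 100),
    random_forest = .learner_random_forest,
    svm = .learner_svm,
    xgboost = .xgb_learner(eta = 0.3, max_depth = 6, nrounds = 50)
  )
  if (is.null(algorithms)) return(reg)
  unknown <- setdiff(algorithms, names(reg))
  if (length(unknown))
    stop_arg("unknown algorithm(s): %s", paste(unknown, collapse = ", "))
  reg[algorithms]
}
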