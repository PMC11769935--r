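#' Configuration of the classification bench
#'
#' Defaults mirror the evaluation protocol used for the canine
#' hemangiosarcoma cohort: all seven algorithms, ten repeated stratified
#' 70/30 hold-out splits, and stratified 10-fold cross-validation, with
#' hemangiosarcoma as the positive class.
#'
#' @param algorithms Character vector of algorithm names (see
#'   [classifier_registry()]).
#' @param n_repeats Hold-out repeats (default 10).
#' @param train_fraction Training fraction per repeat (default 0.7).
#' @param k_folds Folds for cross-validation (default 10).
#' @param threshold Score cut for accuracy/sensitivity/specificity
#'   (default 0.5).
#' @param seed Master seed; repeats and folds derive their own subseeds.
#' @return A `bench_config` object.
#' @export
bench_config <- function(algorithms = names(classifier_registry()),
                         n_repeats = 10L, train_fraction = 0.7,
                         k_folds = 10L, threshold = 0.5, seed = 1L) {
  check_number(n_repeats, "n_repeats", lower = 1)
  check_number(train_fraction, "train_fraction", lower = 1e-6, upper = 1 - 1e-6)
  check_number(k_folds, "k_folds", lower = 2)
  classifier_registry(algorithms)  # validates names
  structure(list(algorithms = algorithms, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, k_folds = as.integer(k_folds),
                 threshold = threshold, seed = as.integer(seed)),
            class = "bench_config")
}

#' Binary classification metrics
#'
#' AUC is the probability that a uniformly chosen positive sample outscores
#' a uniformly chosen negative one, with ties counted 1/2 (computed via
#' mid-ranks, equivalent to exhaustive pair counting). Accuracy,
#' sensitivity (TP / (TP + FN)) and specificity (TN / (TN + FP)) are taken
#' at the score threshold, with the positive class = 1 (hemangiosarcoma).
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @param threshold Classification cut (default 0.5; scores >= threshold
#'   are called positive).
#' @return Named numeric vector `auc`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @examples
#' binary_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop_arg("labels/scores length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_arg("AUC undefined: both classes must be present")
  r <- rank(scores)  # mid-ranks give ties weight 1/2
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  c(auc = auc,
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / n_pos,
    specificity = tn / n_neg)
}

# stratified fold assignment: shuffles within class, deals into k folds
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

.run_learners <- function(x_tr, y_tr, x_te, config, seed) {
  reg <- classifier_registry(config$algorithms)
  std <- .standardize(x_tr, x_te)
  out <- list()
  for (alg in names(reg)) {
    model <- reg[[alg]](std$train, y_tr, derive_seed(seed, alg))
    out[[alg]] <- as.numeric(model$score(std$test))
  }
  out
}

#' Repeated stratified hold-out evaluation
#'
#' For each repeat, draws a stratified train subset of the configured
#' fraction, fits every configured algorithm on it and scores the held-out
#' samples; reports per-algorithm mean and sd of AUC, accuracy, sensitivity
#' and specificity over the repeats.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param config A [bench_config()].
#' @return A `bench_report`: data frame with one row per algorithm
#'   (columns `algorithm`, `auc`, `accuracy`, `sensitivity`, `specificity`
#'   and their `_sd` companions), with attributes `scheme` and `config`.
#' @export
repeated_holdout <- function(fm, config = bench_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "bench_config"))
  tab <- table(factor(fm$labels, levels = c(0, 1)))
  if (min(tab) < 2L) stop_arg("need at least 2 samples per class")
  per_rep <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rs <- derive_seed(config$seed, paste0("holdout_", r))
    idx <- with_seed(rs, .stratified_sample(fm$labels, config$train_fraction))
    test <- setdiff(seq_along(fm$labels), idx)
    if (length(unique(fm$labels[test])) < 2L)
      stop_arg("test split lost a class; reduce train_fraction")
    scores <- .run_learners(fm$values[idx, , drop = FALSE], fm$labels[idx],
                            fm$values[test, , drop = FALSE], config, rs)
    per_rep[[r]] <- t(vapply(scores, function(s)
      binary_metrics(fm$labels[test], s, config$threshold), numeric(4)))
  }
  .aggregate_bench(per_rep, config, scheme = "repeated_holdout")
}

#' Stratified k-fold cross-validation
#'
#' Assigns samples to stratified folds, scores each fold out-of-fold with
#' every algorithm, pools the out-of-fold scores and computes one set of
#' metrics per algorithm on the pooled scores. If `k_folds` exceeds the
#' minority-class count, k is reduced to it with a warning.
#'
#' @inheritParams repeated_holdout
#' @return A `bench_report` (sd columns are NA: pooled scoring yields one
#'   estimate per algorithm).
#' @export
kfold_cv <- function(fm, config = bench_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "bench_config"))
  k <- config$k_folds
  minority <- min(table(factor(fm$labels, levels = c(0, 1))))
  if (minority < 2L) stop_arg("need at least 2 samples per class")
  if (k > minority) {
    warning(sprintf("k reduced from %d to minority-class count %d", k, minority))
    k <- minority
  }
  fold <- with_seed(derive_seed(config$seed, "kfold"),
                    .stratified_folds(fm$labels, k))
  pooled <- stats::setNames(
    rep(list(numeric(length(fm$labels))), length(config$algorithms)),
    config$algorithms)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    scores <- .run_learners(fm$values[tr, , drop = FALSE], fm$labels[tr],
                            fm$values[te, , drop = FALSE], config,
                            derive_seed(config$seed, paste0("fold_", f)))
    for (alg in config$algorithms) pooled[[alg]][te] <- scores[[alg]]
  }
  rows <- t(vapply(pooled, function(s)
    binary_metrics(fm$labels, s, config$threshold), numeric(4)))
  .aggregate_bench(list(rows), config, scheme = sprintf("%d-fold_cv", k))
}

.aggregate_bench <- function(per_rep, config, scheme) {
  arr <- simplify2array(per_rep)  # alg x metric x repeat
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L),
                                           dimnames = c(dimnames(arr), NULL))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (dim(arr)[3] > 1L) apply(arr, c(1, 2), stats::sd)
  else matrix(NA_real_, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  out <- data.frame(algorithm = rownames(mu), mu, sdv, row.names = NULL)
  names(out) <- c("algorithm", colnames(mu), paste0(colnames(mu), "_sd"))
  structure(out, scheme = scheme, config = config,
            class = c("bench_report", "data.frame"))
}

#' @export
print.bench_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classification bench (%s, positive = hemangiosarcoma)\n",
              attr(x, "scheme")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
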