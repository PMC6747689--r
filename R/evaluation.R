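#' Classification metrics for a binary QSAR model
#'
#' Computes the confusion counts and the standard metric set: accuracy
#' ACC = (TP+TN)/(TP+TN+FP+FN), sensitivity SE = TP/(TP+FN) (recall on
#' hepatotoxicants), specificity SP = TN/(TN+FP) (recall on
#' non-hepatotoxicants), the Matthews correlation coefficient on
#' `[-1, 1]`, and — when probabilities are supplied — AUC by the
#' Mann-Whitney rank statistic (ties credited 0.5). A metric whose
#' denominator is zero is reported as `NA`, never as 0.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels.
#' @param y_prob optional vector of positive-class probabilities for AUC.
#' @return an object of class `dili_metrics`: list with `counts`
#'   (TP, TN, FP, FN) and `ACC`, `SE`, `SP`, `AUC`, `MCC`.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred lengths differ")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) abort("labels must be 0/1")
  if (!is.null(y_prob)) {
    if (length(y_prob) != length(y_true)) abort("y_prob length differs")
    if (any(y_prob < 0 | y_prob > 1)) abort("y_prob outside [0, 1]")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  structure(list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    ACC = safe_div(tp + tn, tp + tn + fp + fn),
    SE  = safe_div(tp, tp + fn),
    SP  = safe_div(tn, tn + fp),
    AUC = if (is.null(y_prob)) NA_real_ else rank_auc(y_true, y_prob),
    MCC = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_),
    class = "dili_metrics")
}

#' @export
print.dili_metrics <- function(x, ...) {
  cat(sprintf("<dili_metrics> TP=%d TN=%d FP=%d FN=%d\n", x$counts["TP"],
              x$counts["TN"], x$counts["FP"], x$counts["FN"]))
  cat(sprintf("  ACC=%.4f SE=%.4f SP=%.4f AUC=%s MCC=%s\n", x$ACC, x$SE,
              x$SP, format(x$AUC, digits = 4), format(x$MCC, digits = 4)))
  invisible(x)
}

#' AUC by the Mann-Whitney rank statistic
#'
#' The probability that a uniformly chosen positive receives a higher score
#' than a uniformly chosen negative, with ties counted 1/2. Exactly equals
#' the trapezoidal area under the empirical ROC curve, without choosing a
#' threshold grid, and is invariant under strictly monotone transforms of
#' the scores.
#'
#' @param y_true 0/1 vector.
#' @param y_prob numeric scores.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
rank_auc <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validation configuration
#'
#' @param folds number of folds (default 5).
#' @param repeats number of independent repetitions of the whole CV
#'   (default 1000, the full study protocol; analyses at package scale use
#'   far fewer — see the vignette).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param seed base seed; per-repeat fold seeds and per-member fit seeds
#'   are derived from it with [derive_seed()].
#' @return an object of class `dili_cv_config`.
#' @export
cv_config <- function(folds = 5, repeats = 1000, stratified = TRUE, seed = 1L) {
  if (folds < 2) abort("folds must be >= 2")
  if (repeats < 1) abort("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "dili_cv_config")
}

# held-out index sets, one per fold; stratified via caret
make_folds <- function(y, cv, seed) {
  if (cv$stratified && min(table(y)) < cv$folds)
    abort("stratification infeasible: smallest class (%d) < folds (%d)",
          min(table(y)), cv$folds)
  set.seed(seed)
  if (cv$stratified)
    caret::createFolds(factor(y), k = cv$folds, list = TRUE,
                       returnTrain = FALSE)
  else
    split(sample(seq_along(y)),
          rep_len(seq_len(cv$folds), length(y))[order(sample(seq_along(y)))])
}

# out-of-fold soft-vote probabilities of a set of specs on one design matrix
oof_probs <- function(X, y, specs, folds, base_seed) {
  p <- rep(NA_real_, length(y))
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    member_probs <- vapply(specs, function(s) {
      fit <- fit_classifier(s, X[-test, , drop = FALSE], y[-test],
                            seed = derive_seed(base_seed, s$algorithm, i))
      predict_proba(fit, X[test, , drop = FALSE])
    }, numeric(length(test)))
    p[test] <- rowMeans(matrix(member_probs, nrow = length(test)))
  }
  p
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, partitions the compounds into `cv$folds` stratified
#' folds, holds each fold out once, and computes the metric set on the
#' pooled out-of-fold predictions of that repeat (pooling, rather than
#' averaging per-fold metrics, keeps SE/SP well-defined when a fold is
#' small). The aggregate is the mean and sd over repeats.
#'
#' @param dataset a `dili_dataset`.
#' @param builder `function(train_dataset, seed)` returning a prediction
#'   function `function(test_dataset) -> probabilities`.
#' @param cv a [cv_config()].
#' @param threshold classification threshold passed to [classify()]
#'   (default 0.5).
#' @return an object of class `dili_cv_result`: `per_repeat` (data.frame of
#'   ACC/SE/SP/AUC/MCC per repeat) and `aggregate` (mean and sd rows).
#' @export
cross_validate <- function(dataset, builder, cv, threshold = 0.5) {
  validate_dataset(dataset)
  y <- as.integer(dataset$labels)
  reps <- lapply(seq_len(cv$repeats), function(r) {
    fold_seed <- derive_seed(cv$seed, "folds", r)
    folds <- make_folds(y, cv, fold_seed)
    p <- rep(NA_real_, length(y))
    for (i in seq_along(folds)) {
      test <- folds[[i]]
      predict_fun <- builder(dataset_subset(dataset, -test),
                             derive_seed(cv$seed, "fit", r, i))
      p[test] <- predict_fun(dataset_subset(dataset, test, check = FALSE))
    }
    m <- compute_metrics(y, classify(p, threshold), p)
    data.frame(repeat_id = r, ACC = m$ACC, SE = m$SE, SP = m$SP,
               AUC = m$AUC, MCC = m$MCC)
  })
  per_repeat <- do.call(rbind, reps)
  metric_cols <- c("ACC", "SE", "SP", "AUC", "MCC")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(per_repeat[metric_cols], mean, 0, na.rm = TRUE),
    sd = vapply(per_repeat[metric_cols], stats::sd, 0, na.rm = TRUE),
    row.names = NULL)
  structure(list(per_repeat = per_repeat, aggregate = aggregate, cv = cv),
            class = "dili_cv_result")
}

#' @export
print.dili_cv_result <- function(x, ...) {
  cat(sprintf("<dili_cv_result> %d-fold CV x %d repeat(s)\n", x$cv$folds,
              x$cv$repeats))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stratified train/test holdout split
#'
#' Randomly reserves `test_fraction` of the compounds as an independent
#' test set, stratified by class with largest-remainder rounding so the
#' test size is exactly `round(n * test_fraction)` — a 450-compound set at
#' fraction 1/9 yields a 50-compound test set (20 positives, 30 negatives
#' at the 182/268 prior).
#'
#' @param dataset a `dili_dataset`.
#' @param test_fraction fraction held out (default 1/9).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `dili_dataset`s.
#' @export
holdout_split <- function(dataset, test_fraction = 1 / 9, seed = 1L) {
  validate_dataset(dataset)
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("test_fraction must be in (0, 1)")
  y <- as.integer(dataset$labels)
  n <- length(y)
  n_test <- as.integer(round_half_up(n * test_fraction, 0))
  if (n_test < 1 || n_test >= n) abort("holdout split leaves an empty side")
  classes <- sort(unique(y), decreasing = TRUE)  # positives first
  ideal <- vapply(classes, function(c) sum(y == c) * test_fraction, 0)
  base <- floor(ideal)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(-(ideal - base), seq_along(classes))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  set.seed(derive_seed(seed, "holdout"))
  test_idx <- unlist(lapply(seq_along(classes), function(k) {
    pool <- which(y == classes[k])
    sample(pool, base[k])
  }))
  test_idx <- sort(test_idx)
  list(train = dataset_subset(dataset, setdiff(seq_len(n), test_idx)),
       test = dataset_subset(dataset, test_idx))
}
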