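# build 0/1 vectors realising a given confusion table
vectors_from_counts <- function(tp, tn, fp, fn) {
  list(y_true = c(rep(1, tp + fn), rep(0, tn + fp)),
       y_pred = c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp)))
}

test_that("confusion-table metrics follow their defining formulas", {
  v <- vectors_from_counts(3, 4, 1, 2)
  m <- compute_metrics(v$y_true, v$y_pred)
  expect_equal(unname(m$counts), c(3, 4, 1, 2))
  expect_equal(m$ACC, 0.7)
  expect_equal(m$SE, 0.6)
  expect_equal(m$SP, 0.8)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(99)
  for (i in 1:1000) {
    cts <- rmultinom(1, sample(4:60, 1), prob = runif(4, 0.05, 1))
    v <- vectors_from_counts(cts[1], cts[2], cts[3], cts[4])
    m <- compute_metrics(v$y_true, v$y_pred)
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    expect_equal(m$ACC, (tp + tn) / sum(cts))
    if (tp + fn > 0) expect_equal(m$SE, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$SP, tn / (tn + fp))
    if (tp + fn > 0 && tn + fp > 0) {
      expect_gte(m$ACC, min(m$SE, m$SP) - 1e-12)
      expect_lte(m$ACC, max(m$SE, m$SP) + 1e-12)
      # exact decomposition ACC = (P*SE + N*SP) / (P + N)
      expect_equal(m$ACC, ((tp + fn) * m$SE + (tn + fp) * m$SP) / sum(cts))
    }
  }
})

test_that("undefined metrics are NA, not zero", {
  m <- compute_metrics(c(0, 0, 0), c(0, 1, 0))
  expect_true(is.na(m$SE))
  expect_true(is.na(m$AUC))
  expect_true(is.na(m$MCC))
  expect_false(is.na(m$SP))
})

test_that("MCC equals its independent phi-coefficient oracle", {
  set.seed(5)
  for (i in 1:50) {
    y_true <- rbinom(20, 1, 0.5)
    y_pred <- rbinom(20, 1, 0.5)
    m <- compute_metrics(y_true, y_pred)
    oracle <- suppressWarnings(cor(y_true, y_pred))  # phi == MCC
    if (is.na(oracle)) expect_true(is.na(m$MCC))
    else expect_equal(m$MCC, oracle, tolerance = 1e-12)
  }
})

test_that("rank AUC handles separation, ties, and matches pROC", {
  y <- c(0, 0, 1, 1)
  expect_equal(rank_auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(rank_auc(y, rep(0.4, 4)), 0.5)
  expect_true(is.na(rank_auc(c(1, 1), c(0.1, 0.2))))
  set.seed(8)
  for (i in 1:20) {
    yt <- rbinom(30, 1, 0.4)
    if (length(unique(yt)) < 2) next
    pr <- runif(30)
    expect_equal(rank_auc(yt, pr),
                 as.numeric(suppressMessages(
                   pROC::auc(yt, pr, direction = "<", levels = c(0, 1)))))
    # invariance under strictly monotone transforms
    expect_equal(rank_auc(yt, pr), rank_auc(yt, qlogis(pr)))
    expect_equal(rank_auc(yt, pr), rank_auc(yt, pr^3))
  }
})

test_that("cross-validation partitions every compound exactly once per repeat", {
  ds <- tiny_dataset(n = 60, seed = 3)
  seen <- list()
  builder <- function(train, seed) {
    train_ids <- train$compound_ids
    function(test) {
      seen[[length(seen) + 1]] <<- test$compound_ids
      expect_length(intersect(train_ids, test$compound_ids), 0)
      rep(0.5, length(test$compound_ids))
    }
  }
  cv <- cv_config(folds = 4, repeats = 2, seed = 6)
  res <- cross_validate(ds, builder, cv)
  expect_equal(nrow(res$per_repeat), 2)
  per_repeat_ids <- list(unlist(seen[1:4]), unlist(seen[5:8]))
  for (ids in per_repeat_ids) expect_setequal(ids, ds$compound_ids)
  expect_false(anyDuplicated(per_repeat_ids[[1]]) > 0)
  # different repeats use different partitions
  expect_false(identical(seen[1:4], seen[5:8]))
})

test_that("null data scores at the majority rate within Monte-Carlo error", {
  ds <- tiny_dataset(n = 200, seed = 41,
                     signal = list())  # no planted signal anywhere
  builder <- function(train, seed) {
    fit <- fit_classifier(classifier_spec("RF", list(ntree = 200)),
                          concat_blocks(train, "ExtendedFP"),
                          train$labels, seed = seed)
    function(test) predict_proba(fit, concat_blocks(test, "ExtendedFP"))
  }
  res <- cross_validate(ds, builder, cv_config(folds = 5, repeats = 2,
                                               seed = 10))
  majority <- max(mean(ds$labels), 1 - mean(ds$labels))
  acc <- res$aggregate$mean[res$aggregate$metric == "ACC"]
  expect_lt(abs(acc - majority), 0.09)
})

test_that("holdout split is stratified with largest-remainder rounding", {
  ds <- tiny_dataset(n = 450, seed = 2)
  expect_equal(sum(ds$labels == 1), 182)
  sp <- holdout_split(ds, test_fraction = 1 / 9, seed = 7)
  expect_equal(length(sp$test$compound_ids), 50)
  expect_equal(length(sp$train$compound_ids), 400)
  expect_equal(sum(sp$test$labels == 1), 20)  # round(182/9)
  expect_equal(sum(sp$test$labels == 0), 30)
  expect_setequal(c(sp$train$compound_ids, sp$test$compound_ids),
                  ds$compound_ids)

  ds10 <- tiny_dataset(n = 10, seed = 4)
  sp10 <- holdout_split(ds10, test_fraction = 0.5, seed = 1)
  expect_equal(length(sp10$test$compound_ids), 5)
  expect_error(holdout_split(ds, test_fraction = 0), "test_fraction")
})
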