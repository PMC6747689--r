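# independent oracle: repeatedly pick the maximum, earliest column wins ties
oracle_top_k <- function(vals, algos, k = 5) {
  chosen <- integer(0)
  for (i in seq_len(k)) {
    remaining <- setdiff(seq_along(vals), chosen)
    best <- remaining[vals[remaining] == max(vals[remaining])][1]
    chosen <- c(chosen, best)
  }
  algos[sort(chosen)]
}

test_that("top-5 selection matches a brute-force oracle on random grids", {
  algos <- dili_algorithms()
  set.seed(7)
  for (trial in 1:25) {
    m <- matrix(round(runif(3 * 9, 0.6, 0.8), 2), 3, 9,
                dimnames = list(paste0("f", 1:3), algos))
    g <- accuracy_grid(m)
    for (f in g$fingerprints)
      expect_identical(top5_per_fingerprint(g, f),
                       oracle_top_k(m[f, ], algos))
    counts <- count_algorithm_selections(g)
    expect_equal(sum(counts), 5 * nrow(m))
  }
})

test_that("ties are broken by column order", {
  algos <- dili_algorithms()
  m <- matrix(0.7, 1, 9, dimnames = list("flat", algos))
  g <- accuracy_grid(m)
  expect_identical(top5_per_fingerprint(g, "flat"),
                   c("LR", "SVM", "GDBT", "AdaBT", "XGBT"))
  counts <- setNames(rep(3L, 9), algos)
  expect_identical(select_top_algorithms(counts, 5),
                   c("LR", "SVM", "GDBT", "AdaBT", "XGBT"))
  # RF and CatBT tie at 11: RF (earlier column) is listed first
  expect_identical(select_top_algorithms(table1_counts_printed, 2),
                   c("RF", "CatBT"))
  expect_error(select_top_algorithms(counts, 10), "exceeds")
})

test_that("single-row grids and single-algorithm rankings degenerate sanely", {
  algos <- dili_algorithms()
  m <- matrix(seq(0.61, 0.69, by = 0.01), 1, 9,
              dimnames = list("only", algos))
  g <- accuracy_grid(m)
  counts <- count_algorithm_selections(g)
  expect_equal(unname(counts[top5_per_fingerprint(g, "only")]), rep(1L, 5))
  expect_equal(sum(counts), 5)
  r <- rank_fingerprints(table1_grid(), "CatBT")
  expect_identical(r$block_id[1], "ExtendedFP")  # CatBT column max 0.7933
  expect_equal(r$avg_accuracy,
               sort(table1_grid()$acc[, "CatBT"], decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("the packaged printed grid reproduces its own selection tier", {
  g <- table1_grid()
  expect_identical(top5_per_fingerprint(g, "ExtendedFP"),
                   c("LR", "XGBT", "RF", "LGBT", "CatBT"))
  # LGBT/CatBT tie at 0.7033 in the nAP2DFP row: one slot, earlier column
  sel <- top5_per_fingerprint(g, "nAP2DFP")
  expect_true("LGBT" %in% sel)
  expect_false("CatBT" %in% sel)
  expect_identical(count_algorithm_selections(g), table1_counts_printed)
})

test_that("evaluate_grid produces calibrated accuracies", {
  # planted leak: one block contains the label itself; the other is noise
  n <- 300
  set.seed(31)
  y <- rep(c(0L, 1L), n / 2)
  leak <- feature_block("LEAK", "binary",
                        cbind(y, matrix(rbinom(n * 3, 1, 0.3), n)),
                        compound_ids = sprintf("c%03d", 1:n),
                        feature_names = paste0("L", 1:4))
  noise <- feature_block("NOISE", "binary", matrix(rbinom(n * 6, 1, 0.4), n),
                         compound_ids = sprintf("c%03d", 1:n),
                         feature_names = paste0("N", 1:6))
  ds <- suppressMessages(assemble_dataset(
    list(leak, noise), setNames(y, sprintf("c%03d", 1:n))))
  g <- evaluate_grid(ds, algorithms = c("XGBT", "RF"),
                     cv = cv_config(folds = 2, repeats = 1, seed = 4))
  expect_equal(dim(g$acc), c(2, 2))
  expect_true(all(g$acc >= 0 & g$acc <= 1))
  expect_true(all(g$acc["LEAK", ] > 0.95))
  expect_true(all(abs(g$acc["NOISE", ] - 0.5) < 0.12))
})

test_that("greedy forward addition finds the signal prefix", {
  cfg <- generator_config(
    n_compounds = 150, block_specs = tiny_block_specs(),
    signal = list(ExtendedFP = list(n_informative = 3, p1 = 0.85, p0 = 0.15),
                  KRFP = list(n_informative = 3, p1 = 0.85, p0 = 0.15)),
    seed = 21)
  ds <- generate_dili_data(cfg)
  ranked <- c("ExtendedFP", "KRFP", "MaccsFP", "nKRFP")
  res <- greedy_fingerprint_addition(
    ds, ranked, c("XGBT", "RF"),
    cv = cv_config(folds = 3, repeats = 1, seed = 8), repeats = 3)
  expect_equal(nrow(res$curve), 4)
  expect_true(all(res$curve$accuracy >= 0 & res$curve$accuracy <= 1))
  expect_true(res$chosen_prefix %in% c(1, 2, 3))
  expect_gt(res$curve$accuracy[2], 0.75)

  one <- greedy_fingerprint_addition(
    ds, "ExtendedFP", "RF",
    cv = cv_config(folds = 3, repeats = 1, seed = 8), repeats = 2)
  expect_equal(one$chosen_prefix, 1)

  # renaming compounds must not change the curve
  ds2 <- ds
  new_ids <- paste0("x", ds$compound_ids)
  ds2$compound_ids <- new_ids
  ds2$labels <- setNames(ds2$labels, new_ids)
  ds2$blocks <- lapply(ds2$blocks, function(b) { b$compound_ids <- new_ids; b })
  res2 <- greedy_fingerprint_addition(
    ds2, ranked, c("XGBT", "RF"),
    cv = cv_config(folds = 3, repeats = 1, seed = 8), repeats = 3)
  expect_equal(res2$curve$accuracy, res$curve$accuracy)
})

test_that("weight search respects its grid and tie rule", {
  ds <- tiny_dataset(n = 80, seed = 13)
  res <- search_weight(ds, fp_block_ids = c("ExtendedFP", "KRFP"),
                       selected_algorithms = "XGBT",
                       cv = cv_config(folds = 3, repeats = 1, seed = 2),
                       weight_grid = 0.5)
  expect_equal(res$best_w, 0.5)
  expect_equal(nrow(res$curve), 1)
  expect_error(search_weight(ds, "ExtendedFP",
                             selected_algorithms = "RF",
                             cv = cv_config(3, 1, seed = 1),
                             weight_grid = c(-0.1, 0.5)),
               "weight_grid")
})

test_that("selection_report assembles a consistent report", {
  rep <- selection_report(table1_grid())
  expect_equal(lengths(rep$top5_sets), setNames(rep(5L, 12),
                                                table1_grid()$fingerprints))
  expect_equal(sum(rep$algo_counts), 60)
  expect_setequal(rep$selected_algorithms,
                  c("XGBT", "CatBT", "RF", "GDBT", "LGBT"))
  expect_true(all(diff(rep$ranked_fingerprints$avg_accuracy) <= 0))
  expect_equal(rep$chosen_prefix, 8L)
  expect_equal(rep$chosen_weight, 0.7)
  tf <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep, tf)
  parsed <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(parsed$chosen_prefix, 8)
})
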