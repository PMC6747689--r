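#' Construct an accuracy grid
#'
#' The fingerprint-by-algorithm table of mean cross-validated accuracies
#' that drives both selection tiers: rows are fingerprint blocks, columns
#' the nine algorithms in canonical order.
#'
#' @param acc numeric matrix of accuracies in `[0, 1]`, with fingerprints
#'   as rownames and algorithms as colnames.
#' @param cv_meta optional list recording folds/repeats/seed.
#' @return an object of class `dili_accuracy_grid`.
#' @export
accuracy_grid <- function(acc, cv_meta = NULL) {
  acc <- as.matrix(acc)
  if (is.null(rownames(acc)) || is.null(colnames(acc)))
    abort("accuracy grid needs fingerprint rownames and algorithm colnames")
  if (any(acc < 0 | acc > 1)) abort("accuracies must lie in [0, 1]")
  structure(list(fingerprints = rownames(acc), algorithms = colnames(acc),
                 acc = acc, cv_meta = cv_meta),
            class = "dili_accuracy_grid")
}

#' @export
print.dili_accuracy_grid <- function(x, ...) {
  cat(sprintf("<dili_accuracy_grid> %d fingerprints x %d algorithms\n",
              length(x$fingerprints), length(x$algorithms)))
  print(round(x$acc, 4))
  invisible(x)
}

#' Read / write an accuracy grid as CSV
#'
#' The CSV layout mirrors the printed grid: first column the fingerprint
#' id, remaining columns one per algorithm.
#'
#' @param path CSV path.
#' @return [read_accuracy_grid()] returns a `dili_accuracy_grid`.
#' @export
read_accuracy_grid <- function(path) {
  if (!file.exists(path)) abort("grid file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  accuracy_grid(m)
}

#' @rdname read_accuracy_grid
#' @param grid a `dili_accuracy_grid`.
#' @export
write_accuracy_grid <- function(grid, path) {
  df <- data.frame(Fingerprint = grid$fingerprints, check.names = FALSE)
  df[grid$algorithms] <- as.data.frame(grid$acc, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate the algorithm-by-fingerprint accuracy grid
#'
#' Trains every algorithm on every fingerprint block alone and records the
#' mean cross-validated accuracy: cell (f, a) is the mean over repeats of
#' the pooled out-of-fold accuracy of algorithm a on block f. Fold
#' assignments and fit seeds are derived per (block, algorithm, repeat,
#' fold) from `cv$seed`.
#'
#' @param dataset a `dili_dataset`.
#' @param algorithms character vector of algorithm names (default: all 9).
#' @param cv a [cv_config()].
#' @param block_ids blocks to evaluate (default: every block except
#'   `"DESCRIPTORS"`).
#' @param hyperparameters optional per-algorithm overrides
#'   ([read_spec_config()]).
#' @return a `dili_accuracy_grid`.
#' @export
evaluate_grid <- function(dataset, algorithms = dili_algorithms(), cv,
                          block_ids = setdiff(names(dataset$blocks),
                                              "DESCRIPTORS"),
                          hyperparameters = list()) {
  validate_dataset(dataset)
  y <- as.integer(dataset$labels)
  specs <- as_specs(algorithms, hyperparameters)
  acc <- matrix(NA_real_, length(block_ids), length(algorithms),
                dimnames = list(block_ids, algorithms))
  for (f in block_ids) {
    X <- concat_blocks(dataset, f)
    for (a in algorithms) {
      cell <- tryCatch({
        per_rep <- vapply(seq_len(cv$repeats), function(r) {
          folds <- make_folds(y, cv, derive_seed(cv$seed, "grid", f, a, r))
          p <- oof_probs(X, y, specs[a], folds,
                         derive_seed(cv$seed, "gridfit", f, a, r))
          mean(classify(p) == y)
        }, 0)
        mean(per_rep)
      }, error = function(e)
        abort("grid cell (%s, %s): %s", f, a, conditionMessage(e)))
      acc[f, a] <- cell
    }
  }
  accuracy_grid(acc, cv_meta = list(folds = cv$folds, repeats = cv$repeats,
                                    seed = cv$seed))
}

#' Top-5 algorithms for one fingerprint row
#'
#' The five algorithms with the largest accuracies in the row; a tie at the
#' fifth place is broken by column order (the earlier column wins).
#'
#' @param grid a `dili_accuracy_grid`.
#' @param row fingerprint block id.
#' @param k number of algorithms to keep (default 5).
#' @return character vector of `k` algorithm names, in column order.
#' @export
top5_per_fingerprint <- function(grid, row, k = 5) {
  if (!row %in% grid$fingerprints) abort("no grid row '%s'", row)
  vals <- grid$acc[row, ]
  keep <- order(-vals, seq_along(vals))[seq_len(k)]
  grid$algorithms[sort(keep)]
}

#' Count how often each algorithm enters a per-fingerprint top 5
#'
#' @param grid a `dili_accuracy_grid`.
#' @param k top-set size (default 5).
#' @return named integer vector over the grid's algorithms; sums to
#'   `k * nrow`.
#' @export
count_algorithm_selections <- function(grid, k = 5) {
  counts <- stats::setNames(integer(length(grid$algorithms)),
                            grid$algorithms)
  for (f in grid$fingerprints) {
    sel <- top5_per_fingerprint(grid, f, k)
    counts[sel] <- counts[sel] + 1L
  }
  counts
}

#' Select the overall top algorithms by selection count
#'
#' @param counts named counts from [count_algorithm_selections()].
#' @param k how many algorithms to keep (default 5).
#' @return character vector of `k` names, ordered by descending count with
#'   ties broken by the counts' (column) order.
#' @export
select_top_algorithms <- function(counts, k = 5) {
  if (k > length(counts)) abort("k exceeds the number of algorithms")
  names(counts)[order(-counts, seq_along(counts))[seq_len(k)]]
}

#' Rank fingerprints by the selected algorithms' average accuracy
#'
#' Per fingerprint, the arithmetic mean of the selected algorithms' grid
#' cells; the reported average is rounded half-up to 4 decimals (internal
#' ordering uses full precision, ties broken by row order).
#'
#' @param grid a `dili_accuracy_grid`.
#' @param selected character vector of algorithm names (subset of the
#'   grid's columns).
#' @return data.frame with columns `block_id`, `avg_accuracy`, sorted in
#'   non-increasing order.
#' @export
rank_fingerprints <- function(grid, selected) {
  missing <- setdiff(selected, grid$algorithms)
  if (length(missing))
    abort("selected algorithm(s) not in grid: %s",
          paste(missing, collapse = ", "))
  avg <- rowMeans(grid$acc[, selected, drop = FALSE])
  ord <- order(-avg, seq_along(avg))
  data.frame(block_id = grid$fingerprints[ord],
             avg_accuracy = round_half_up(avg[ord], 4),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Greedy forward addition of ranked fingerprints
#'
#' Starting from the best-ranked fingerprint, adds one ranked block at a
#' time (column-wise concatenation) and evaluates the soft vote of the
#' selected algorithms on each prefix by repeated cross-validation. The
#' chosen prefix is the argmax of the mean accuracy curve, ties going to
#' the smaller prefix.
#'
#' @param dataset a `dili_dataset`.
#' @param ranked ranking from [rank_fingerprints()] (or a character vector
#'   of block ids, best first).
#' @param selected_algorithms algorithm names voted within each prefix.
#' @param cv a [cv_config()]; its `repeats` is overridden by `repeats`.
#' @param repeats CV repetitions per prefix (default 20).
#' @param hyperparameters optional per-algorithm overrides.
#' @return list with `chosen_prefix` (integer) and `curve` (data.frame
#'   `prefix`, `accuracy`).
#' @export
greedy_fingerprint_addition <- function(dataset, ranked, selected_algorithms,
                                        cv, repeats = 20,
                                        hyperparameters = list()) {
  if (is.data.frame(ranked)) ranked <- ranked$block_id
  if (length(ranked) == 0) abort("ranked fingerprint list is empty")
  validate_dataset(dataset)
  y <- as.integer(dataset$labels)
  specs <- as_specs(selected_algorithms, hyperparameters)
  curve <- vapply(seq_along(ranked), function(p) {
    X <- concat_blocks(dataset, ranked[seq_len(p)])
    per_rep <- vapply(seq_len(repeats), function(r) {
      folds <- make_folds(y, cv, derive_seed(cv$seed, "greedy", p, r))
      probs <- oof_probs(X, y, specs, folds,
                         derive_seed(cv$seed, "greedyfit", p, r))
      mean(classify(probs) == y)
    }, 0)
    mean(per_rep)
  }, 0)
  list(chosen_prefix = which.max(curve),
       curve = data.frame(prefix = seq_along(ranked), accuracy = curve))
}

#' Search the fingerprint : descriptor fusion weight
#'
#' Evaluates the dual-block ensemble's cross-validated accuracy over a
#' grid of weights w (fingerprint side weighted w, descriptor side 1 - w).
#' The per-fold member fits are shared across all weights — only the
#' fusion changes — so the search costs one CV run. Ties on the maximum go
#' to the larger w (favouring the fingerprint side).
#'
#' @param dataset a `dili_dataset`.
#' @param fp_block_ids fingerprint block ids (concatenated as one side).
#' @param desc_block_id descriptor block id (default `"DESCRIPTORS"`).
#' @param selected_algorithms algorithm names voted within each side.
#' @param cv a [cv_config()].
#' @param weight_grid candidate weights in `[0, 1]` (default 0, 0.1, ..., 1).
#' @param hyperparameters optional per-algorithm overrides.
#' @return list with `best_w` and `curve` (data.frame `weight`, `accuracy`).
#' @export
search_weight <- function(dataset, fp_block_ids,
                          desc_block_id = "DESCRIPTORS",
                          selected_algorithms, cv,
                          weight_grid = seq(0, 1, by = 0.1),
                          hyperparameters = list()) {
  if (length(weight_grid) == 0 || any(weight_grid < 0 | weight_grid > 1))
    abort("weight_grid must be a non-empty subset of [0, 1]")
  validate_dataset(dataset)
  y <- as.integer(dataset$labels)
  specs <- as_specs(selected_algorithms, hyperparameters)
  X_fp <- concat_blocks(dataset, fp_block_ids)
  X_desc <- concat_blocks(dataset, desc_block_id)
  acc_w <- matrix(NA_real_, cv$repeats, length(weight_grid))
  for (r in seq_len(cv$repeats)) {
    folds <- make_folds(y, cv, derive_seed(cv$seed, "weight", r))
    p_fp <- oof_probs(X_fp, y, specs, folds,
                      derive_seed(cv$seed, "weightfp", r))
    p_desc <- oof_probs(X_desc, y, specs, folds,
                        derive_seed(cv$seed, "weightdesc", r))
    acc_w[r, ] <- vapply(weight_grid, function(w)
      mean(classify(fuse_blocks(p_fp, p_desc, w)) == y), 0)
  }
  acc <- colMeans(acc_w)
  best <- max(which(acc >= max(acc) - 1e-12))
  list(best_w = weight_grid[best],
       curve = data.frame(weight = weight_grid, accuracy = acc))
}

#' Full two-tier selection report
#'
#' Convenience wrapper producing the per-fingerprint top-5 sets, algorithm
#' counts, the selected algorithms, and the fingerprint ranking from an
#' accuracy grid, plus the chosen fingerprint prefix and fusion weight
#' (either supplied or re-derived from data with
#' [greedy_fingerprint_addition()] / [search_weight()]).
#'
#' @param grid a `dili_accuracy_grid`.
#' @param k_algorithms number of algorithms to select (default 5).
#' @param chosen_prefix number of top fingerprints retained (default 8).
#' @param chosen_weight fingerprint-side fusion weight (default 0.7).
#' @return an object of class `dili_selection_report`.
#' @export
selection_report <- function(grid, k_algorithms = 5, chosen_prefix = 8,
                             chosen_weight = 0.7) {
  top5 <- lapply(grid$fingerprints, function(f) top5_per_fingerprint(grid, f))
  names(top5) <- grid$fingerprints
  counts <- count_algorithm_selections(grid)
  selected <- select_top_algorithms(counts, k_algorithms)
  ranked <- rank_fingerprints(grid, selected)
  chosen_prefix <- min(max(1L, as.integer(chosen_prefix)),
                       length(grid$fingerprints))
  structure(list(top5_sets = top5, algo_counts = counts,
                 selected_algorithms = selected,
                 ranked_fingerprints = ranked,
                 chosen_prefix = chosen_prefix,
                 chosen_weight = chosen_weight),
            class = "dili_selection_report")
}

#' @export
print.dili_selection_report <- function(x, ...) {
  cat("<dili_selection_report>\n  selected algorithms:",
      paste(x$selected_algorithms, collapse = ", "), "\n")
  cat("  fingerprint ranking:\n")
  print(x$ranked_fingerprints, row.names = FALSE)
  cat(sprintf("  chosen prefix: %d   chosen weight: %.2f\n",
              x$chosen_prefix, x$chosen_weight))
  invisible(x)
}

#' Write a selection report as JSON
#'
#' @param report a `dili_selection_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(
    list(top5_sets = report$top5_sets,
         algo_counts = as.list(report$algo_counts),
         selected_algorithms = report$selected_algorithms,
         ranked_fingerprints = report$ranked_fingerprints,
         chosen_prefix = report$chosen_prefix,
         chosen_weight = report$chosen_weight),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
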