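#' Soft vote: average class probabilities
#'
#' Element-wise arithmetic mean of one probability vector per member
#' classifier — the "soft" voting rule, which uses the members' confidence
#' rather than their hard labels.
#'
#' @param probability_vectors list of equal-length numeric vectors in
#'   `[0, 1]` (a matrix with members in columns is also accepted).
#' @return numeric vector of averaged probabilities.
#' @export
soft_vote <- function(probability_vectors) {
  if (is.matrix(probability_vectors))
    probability_vectors <- asplit(probability_vectors, 2)
  if (length(probability_vectors) < 1) abort("need at least one vector")
  lens <- lengths(probability_vectors)
  if (length(unique(lens)) != 1) abort("probability vector lengths differ")
  m <- matrix(unlist(probability_vectors), nrow = lens[1])
  if (any(m < 0 | m > 1)) abort("probabilities outside [0, 1]")
  rowMeans(m)
}

#' Fuse fingerprint-side and descriptor-side probabilities
#'
#' Convex combination `w * p_fp + (1 - w) * p_desc`. `w = 0.7` is the 7:3
#' fingerprint : descriptor trade-off used by default.
#'
#' @param p_fp fingerprint-side probabilities.
#' @param p_desc descriptor-side probabilities.
#' @param w fingerprint-side weight in `[0, 1]`.
#' @return fused probability vector.
#' @export
fuse_blocks <- function(p_fp, p_desc, w) {
  if (!is_scalar_number(w) || w < 0 || w > 1)
    abort("w must be a single number in [0, 1]")
  if (length(p_fp) != length(p_desc))
    abort("probability vector lengths differ")
  w * p_fp + (1 - w) * p_desc
}

#' Threshold probabilities into class labels
#'
#' A compound is called hepatotoxic (1) iff its probability is strictly
#' greater than the threshold; a probability exactly at the threshold is
#' classed 0.
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return integer vector of 0/1.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  as.integer(probabilities > threshold)
}

#' Fit a single-block soft voter
#'
#' Fits each selected algorithm on the concatenation of `block_ids` and
#' predicts by soft vote. This is one "side" of the dual-block ensemble;
#' [fit_ensemble()] builds one voter per side with seed tags `"fp"` and
#' `"desc"`, so a voter fitted here with the same tag is bit-for-bit
#' identical to the corresponding ensemble side.
#'
#' @param dataset a `dili_dataset`.
#' @param block_ids blocks concatenated into the design matrix.
#' @param algorithms member algorithm names.
#' @param seed base seed; member seeds are derived as
#'   `derive_seed(seed, seed_tag, algorithm)`.
#' @param seed_tag tag naming the side (default `"fp"`).
#' @param hyperparameters optional per-algorithm overrides.
#' @return an object of class `dili_voter`.
#' @export
fit_voter <- function(dataset, block_ids, algorithms, seed = 1L,
                      seed_tag = "fp", hyperparameters = list()) {
  validate_dataset(dataset)
  X <- concat_blocks(dataset, block_ids)
  y <- as.integer(dataset$labels)
  specs <- as_specs(algorithms, hyperparameters)
  members <- lapply(specs, function(s)
    fit_classifier(s, X, y, seed = derive_seed(seed, seed_tag, s$algorithm)))
  structure(list(block_ids = block_ids, algorithms = algorithms,
                 members = members, seed = as.integer(seed),
                 seed_tag = seed_tag),
            class = "dili_voter")
}

voter_matrix <- function(voter, newdata) {
  if (inherits(newdata, "dili_dataset") ||
      (is.list(newdata) && !is.matrix(newdata)))
    concat_blocks(as_block_container(newdata), voter$block_ids)
  else as.matrix(newdata)
}

as_block_container <- function(x) {
  if (inherits(x, "dili_dataset")) return(x)
  # bare named list of feature blocks (e.g. unlabelled prediction input)
  blocks <- x
  names(blocks) <- vapply(blocks, `[[`, "", "block_id")
  ids <- blocks[[1]]$compound_ids
  structure(list(compound_ids = ids,
                 labels = stats::setNames(rep(NA_integer_, length(ids)), ids),
                 blocks = blocks),
            class = "dili_dataset")
}

#' @export
predict_proba.dili_voter <- function(model, newdata) {
  X <- voter_matrix(model, newdata)
  soft_vote(lapply(model$members, predict_proba, newdata = X))
}

#' Fit the weighted dual-block soft-voting ensemble
#'
#' The final predictor: the selected algorithms are fitted twice — once on
#' the concatenated fingerprint blocks, once on the descriptor block — and
#' each side predicts by soft vote; the two sides are fused as
#' `w * p_fingerprint + (1 - w) * p_descriptor` and thresholded. With the
#' default configuration the fingerprint side holds the top 8 ranked
#' fingerprints and `w = 0.7` (the 7:3 trade-off).
#'
#' @param dataset a `dili_dataset` containing all configured blocks.
#' @param fingerprint_blocks block ids for the fingerprint side.
#' @param descriptor_block block id for the descriptor side (default
#'   `"DESCRIPTORS"`).
#' @param algorithms member algorithms (default GDBT, XGBT, RF, LGBT,
#'   CatBT — the five selected in the reference analysis).
#' @param weight fingerprint-side fusion weight (default 0.7).
#' @param threshold decision threshold (default 0.5).
#' @param seed base seed for the member fits.
#' @param hyperparameters optional per-algorithm overrides.
#' @return an object of class `dili_ensemble`.
#' @export
fit_ensemble <- function(dataset, fingerprint_blocks,
                         descriptor_block = "DESCRIPTORS",
                         algorithms = c("GDBT", "XGBT", "RF", "LGBT",
                                        "CatBT"),
                         weight = 0.7, threshold = 0.5, seed = 1L,
                         hyperparameters = list()) {
  validate_dataset(dataset)
  if (!is_scalar_number(weight) || weight < 0 || weight > 1)
    abort("weight must lie in [0, 1]")
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    abort("threshold must lie in (0, 1)")
  fp_side <- fit_voter(dataset, fingerprint_blocks, algorithms, seed,
                       seed_tag = "fp", hyperparameters = hyperparameters)
  desc_side <- fit_voter(dataset, descriptor_block, algorithms, seed,
                         seed_tag = "desc", hyperparameters = hyperparameters)
  structure(list(fingerprint_blocks = fingerprint_blocks,
                 descriptor_block = descriptor_block,
                 algorithms = algorithms, weight = weight,
                 threshold = threshold, seed = as.integer(seed),
                 hyperparameters = hyperparameters,
                 fp_side = fp_side, desc_side = desc_side),
            class = "dili_ensemble")
}

#' @export
predict_proba.dili_ensemble <- function(model, newdata) {
  fuse_blocks(predict_proba(model$fp_side, newdata),
              predict_proba(model$desc_side, newdata),
              model$weight)
}

#' Predict method for the dual-block ensemble
#'
#' @param object a `dili_ensemble`.
#' @param newdata a `dili_dataset` or named list of feature blocks covering
#'   the configured block ids.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   thresholded 0/1 labels.
#' @param ... unused.
#' @return numeric or integer vector, one value per compound.
#' @export
predict.dili_ensemble <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else classify(p, object$threshold)
}

#' @export
print.dili_ensemble <- function(x, ...) {
  cat("<dili_ensemble>\n")
  cat("  fingerprint side:", paste(x$fingerprint_blocks, collapse = " + "),
      "\n  descriptor side: ", x$descriptor_block, "\n")
  cat(sprintf("  members: %s\n  weight: %.2f (fp) : %.2f (desc)   threshold: %.2f\n",
              paste(x$algorithms, collapse = ", "), x$weight, 1 - x$weight,
              x$threshold))
  invisible(x)
}

#' Ensemble manifest: everything needed to retrain deterministically
#'
#' The manifest records block ids, member algorithms, hyperparameter
#' overrides, fusion weight, threshold and the base seed — retraining from
#' it on the same dataset reproduces the ensemble exactly.
#'
#' @param model a `dili_ensemble`.
#' @param path optional path: when given the manifest is written as JSON.
#' @return the manifest list (invisibly when written to `path`).
#' @export
ensemble_manifest <- function(model, path = NULL) {
  manifest <- list(fingerprint_blocks = model$fingerprint_blocks,
                   descriptor_block = model$descriptor_block,
                   algorithms = model$algorithms,
                   hyperparameters = model$hyperparameters,
                   weight = model$weight, threshold = model$threshold,
                   seed = model$seed)
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

#' Retrain an ensemble from a manifest
#'
#' @param manifest a manifest list or path to a manifest JSON file.
#' @param dataset the training `dili_dataset`.
#' @return a `dili_ensemble`, identical to the one the manifest describes
#'   when fitted on the same data.
#' @export
fit_from_manifest <- function(manifest, dataset) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  fit_ensemble(dataset,
               fingerprint_blocks = manifest$fingerprint_blocks,
               descriptor_block = manifest$descriptor_block,
               algorithms = manifest$algorithms,
               weight = manifest$weight, threshold = manifest$threshold,
               seed = manifest$seed,
               hyperparameters = lapply(manifest$hyperparameters, as.list))
}

#' Cross-validate the dual-block ensemble
#'
#' Runs [cross_validate()] with a builder that fits the full dual-block
#' ensemble on each training fold.
#'
#' @inheritParams fit_ensemble
#' @param cv a [cv_config()].
#' @return a `dili_cv_result`.
#' @export
cross_validate_ensemble <- function(dataset, fingerprint_blocks,
                                    descriptor_block = "DESCRIPTORS",
                                    algorithms = c("GDBT", "XGBT", "RF",
                                                   "LGBT", "CatBT"),
                                    weight = 0.7, threshold = 0.5, cv,
                                    hyperparameters = list()) {
  builder <- function(train, seed) {
    model <- fit_ensemble(train, fingerprint_blocks, descriptor_block,
                          algorithms, weight, threshold, seed,
                          hyperparameters)
    function(test) predict_proba(model, test)
  }
  cross_validate(dataset, builder, cv, threshold = threshold)
}
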