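#' The nine base classification algorithms
#'
#' Canonical names, in grid column order: logistic regression (LR),
#' RBF-kernel support vector machine (SVM), vanilla gradient-boosted trees
#' (GDBT), AdaBoost with decision stumps (AdaBT), regularised gradient
#' boosting (XGBT), random forest (RF), extremely randomised trees
#' (ExtraTrees), histogram/leaf-wise gradient boosting (LGBT), and a
#' depth-wise, slow-learning-rate, strongly L2-regularised gradient
#' boosting configuration (CatBT). Column order doubles as the tie-break
#' order throughout the selection module.
#'
#' @return character vector of the 9 algorithm names.
#' @export
dili_algorithms <- function() {
  c("LR", "SVM", "GDBT", "AdaBT", "XGBT", "RF", "ExtraTrees", "LGBT", "CatBT")
}

#' Specify a base classifier
#'
#' @param algorithm one of [dili_algorithms()].
#' @param hyperparameters named list of overrides merged over the
#'   algorithm's defaults (empty = defaults).
#' @param seed integer seed used when the spec is fitted directly.
#' @return an object of class `dili_classifier_spec`.
#' @export
classifier_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, dili_algorithms())
  structure(list(algorithm = algorithm,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "dili_classifier_spec")
}

# named list of specs from algorithm names, with shared hyperparameter map
as_specs <- function(algorithms, hyperparameters = list(), seed = 1L) {
  specs <- lapply(algorithms, function(a)
    classifier_spec(a, hyperparameters[[a]] %||% list(), seed))
  stats::setNames(specs, algorithms)
}

#' Read a classifier hyperparameter configuration file
#'
#' JSON or YAML mapping algorithm name to a named list of hyperparameter
#' overrides, e.g. `{"RF": {"ntree": 1000}}`. Unknown algorithm names are
#' an error.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return named list suitable for the `hyperparameters` argument of the
#'   grid/ensemble functions.
#' @export
read_spec_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), dili_algorithms())
  if (length(unknown))
    abort("unknown algorithm(s) in config: %s", paste(unknown, collapse = ", "))
  lapply(cfg, as.list)
}

# per-algorithm default hyperparameters; boosting variants are xgboost
# configurations distinguished by split strategy, growth policy, learning
# rate and regularisation
zoo_defaults <- function(algorithm) {
  switch(algorithm,
    LR         = list(lambda = NULL),           # ridge penalty, default 1/n
    SVM        = list(cost = 1, gamma = NULL),  # default gamma 1/p
    GDBT       = list(nrounds = 100, eta = 0.1, max_depth = 3,
                      lambda = 0, tree_method = "exact"),
    AdaBT      = list(n_estimators = 50, max_depth = 1),
    XGBT       = list(nrounds = 100, eta = 0.3, max_depth = 6, lambda = 1),
    RF         = list(ntree = 500),
    ExtraTrees = list(num.trees = 500),
    LGBT       = list(nrounds = 100, eta = 0.1, max_leaves = 31),
    CatBT      = list(nrounds = 200, eta = 0.05, max_depth = 6, lambda = 3)
  )
}

# algorithms whose inputs are standardised (scale-sensitive learners)
needs_scaling <- function(algorithm) algorithm %in% c("LR", "SVM")

#' Fit a base classifier
#'
#' Fits `spec` on a numeric design matrix. For the scale-sensitive learners
#' (LR, SVM) the columns are standardised with means/sds estimated on this
#' training data only; tree and boosting learners see raw features. Fits
#' are deterministic given `(seed, X, y)`: all backends run single-threaded
#' with an explicit seed.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix (rows = compounds); column names are recorded
#'   and enforced at prediction time.
#' @param y 0/1 vector, both classes present.
#' @param seed fit seed (default: the spec's own seed).
#' @return an object of class `dili_fitted_classifier`.
#' @export
fit_classifier <- function(spec, X, y, seed = spec$seed) {
  stopifnot(inherits(spec, "dili_classifier_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(y)
  if (nrow(X) != length(y)) abort("X has %d rows but y has length %d",
                                  nrow(X), length(y))
  if (anyNA(X) || any(!is.finite(X))) abort("NaN or non-finite values in X")
  if (!all(y %in% c(0L, 1L))) abort("y must be 0/1")
  if (length(unique(y)) < 2) abort("single-class y: cannot fit a classifier")
  hp <- utils::modifyList(zoo_defaults(spec$algorithm), spec$hyperparameters)
  scaler <- NULL
  if (needs_scaling(spec$algorithm)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    X <- scale(X, center = ctr, scale = scl)
  }
  fit <- fit_backend(spec$algorithm, X, y, hp, seed)
  structure(list(spec = spec, feature_names = colnames(X), scaler = scaler,
                 fit = fit, seed = as.integer(seed)),
            class = "dili_fitted_classifier")
}

fit_backend <- function(algorithm, X, y, hp, seed) {
  switch(algorithm,
    LR = {
      lam <- hp$lambda %||% (1 / nrow(X))
      list(type = "glmnet", lambda = lam,
           model = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                  lambda = lam, standardize = FALSE))
    },
    SVM = {
      set.seed(seed)
      list(type = "svm",
           model = e1071::svm(X, factor(y, levels = c(0, 1)),
                              kernel = "radial", cost = hp$cost,
                              gamma = hp$gamma %||% (1 / ncol(X)),
                              probability = TRUE))
    },
    RF = {
      set.seed(seed)
      list(type = "rf",
           model = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                              ntree = hp$ntree))
    },
    ExtraTrees = {
      list(type = "ranger",
           model = ranger::ranger(
             x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
             probability = TRUE, splitrule = "extratrees",
             num.random.splits = 1, replace = FALSE, sample.fraction = 1,
             num.trees = hp$num.trees, seed = seed, num.threads = 1,
             verbose = FALSE))
    },
    AdaBT = fit_adaboost(X, y, n_estimators = hp$n_estimators,
                         max_depth = hp$max_depth),
    # remaining three are gradient-boosting configurations
    {
      params <- switch(algorithm,
        GDBT = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, lambda = hp$lambda,
                    tree_method = hp$tree_method),
        XGBT = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, lambda = hp$lambda),
        LGBT = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = hp$max_leaves, max_depth = 0),
        CatBT = list(objective = "binary:logistic", eta = hp$eta,
                     max_depth = hp$max_depth, lambda = hp$lambda,
                     tree_method = "hist"))
      params$nthread <- 1
      params$seed <- seed
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      list(type = "xgb",
           model = xgboost::xgb.train(params = params, data = dm,
                                      nrounds = hp$nrounds, verbose = 0))
    }
  )
}

#' Predicted probability of the positive class
#'
#' @param model a fitted model (`dili_fitted_classifier`, `dili_voter` or
#'   `dili_ensemble`).
#' @param newdata a numeric matrix (for fitted classifiers/voters) or a
#'   `dili_dataset`/named block list (for ensembles).
#' @return numeric vector of P(class = 1), one per row, all in `[0, 1]`.
#' @export
predict_proba <- function(model, newdata) UseMethod("predict_proba")

#' @export
predict_proba.dili_fitted_classifier <- function(model, newdata) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!identical(colnames(X), model$feature_names)) {
    if (setequal(colnames(X), model$feature_names))
      X <- X[, model$feature_names, drop = FALSE]
    else
      abort("feature names differ from those the model was trained on")
  }
  if (!is.null(model$scaler))
    X <- scale(X, center = model$scaler$center, scale = model$scaler$scale)
  fit <- model$fit
  p <- switch(fit$type,
    glmnet = as.numeric(stats::predict(fit$model, X, type = "response",
                                       s = fit$lambda)),
    svm = {
      pr <- stats::predict(fit$model, X, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    rf = as.numeric(stats::predict(fit$model, X, type = "prob")[, "1"]),
    ranger = as.numeric(stats::predict(fit$model, data = as.data.frame(X),
                                       num.threads = 1)$predictions[, "1"]),
    adaboost = predict_adaboost(fit, X),
    xgb = as.numeric(stats::predict(fit$model, X)))
  pmin(pmax(p, 0), 1)
}
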