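# AdaBoost (SAMME) over rpart decision stumps.
#
# Two-class SAMME: stage m fits a weighted stump h_m, its weighted error
# e_m gives the stage weight alpha_m = log((1 - e_m) / e_m); misclassified
# points are up-weighted by exp(alpha_m). The positive-class probability is
# the alpha-weighted fraction of stumps voting 1, which is monotone in the
# ensemble's decision score and lies in [0, 1] by construction.
#
# Deterministic: rpart's greedy split search has no random component.

fit_adaboost <- function(X, y, n_estimators = 50, max_depth = 1) {
  n <- nrow(X)
  # internal syntactic column names so arbitrary feature names survive the
  # rpart formula interface; restored mapping is positional
  df <- as.data.frame(X)
  colnames(df) <- paste0("x", seq_len(ncol(df)))
  yf <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = yf), weights = w,
                        method = "class", control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != yf
    err <- sum(w[miss])
    if (err >= 0.5) break              # no better than chance: stop
    if (err < 1e-12) {                 # perfect stage: dominate the vote
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, log(1e12))
      break
    }
    alpha <- log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(type = "adaboost", stumps = stumps, alphas = alphas,
       p1 = ncol(X), fallback = mean(y))
}

predict_adaboost <- function(fit, X) {
  if (length(fit$stumps) == 0)
    return(rep(fit$fallback, nrow(X)))
  df <- as.data.frame(X)
  colnames(df) <- paste0("x", seq_len(ncol(df)))
  votes <- vapply(fit$stumps, function(s)
    as.integer(stats::predict(s, df, type = "class") == "1"),
    integer(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}
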