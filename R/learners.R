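#' Boosting stage configuration
#'
#' Hyperparameters for one classification stage. Defaults are the Stage 1
#' settings of the reference pipeline: 400 boosting rounds with 50-round
#' early-stopping patience, depth 10, learning rate 0.03, L2 regularization
#' 3.0, random strength 1.0 and 254 histogram borders. Stage 2 sub-classifiers
#' default to 300 rounds at depth 8 (see [equiboost()]).
#'
#' `random_strength` and `border_count` parameterize the learner contract;
#' border_count maps to the histogram bin count of tree learners that support
#' it, while random_strength is learner-specific and ignored by learners
#' without an equivalent.
#'
#' @param iterations Boosting rounds (> 0).
#' @param depth Tree depth (> 0).
#' @param learning_rate Shrinkage per round.
#' @param l2_reg L2 leaf regularization.
#' @param random_strength Split-score randomization strength.
#' @param border_count Histogram discretization borders.
#' @param early_stopping_patience Rounds without validation improvement before
#'   stopping (0 disables early stopping).
#' @param seed Learner seed (filled in by [equiboost()] when `NULL`).
#' @return Object of class `stage_config`.
#' @export
stage_config <- function(iterations = 400, depth = 10, learning_rate = 0.03,
                         l2_reg = 3.0, random_strength = 1.0,
                         border_count = 254, early_stopping_patience = 50,
                         seed = NULL) {
  stopifnot(iterations > 0, depth > 0, early_stopping_patience >= 0,
            learning_rate > 0)
  structure(list(iterations = as.integer(iterations), depth = as.integer(depth),
                 learning_rate = learning_rate, l2_reg = l2_reg,
                 random_strength = random_strength,
                 border_count = as.integer(border_count),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = seed),
            class = "stage_config")
}

#' Base-learner contract
#'
#' A base learner is any sample-weighted, probabilistic classifier exposed as a
#' list with fields `name`, `early_stopping` (logical), `fit(x, y, weights,
#' config, valid)` returning a fitted object, and `predict_prob(fit, x)`
#' returning a probability matrix with one named column per class level.
#' `learner_xgboost()` is the shipped gradient-boosted-tree default;
#' `learner_rpart()` is a dependency-light single-tree fallback (ignores the
#' boosting fields of the config beyond `depth`). `default_learner()` picks
#' xgboost when available.
#'
#' @param nthread Threads for xgboost (default 1 for reproducibility).
#' @return A learner object of class `eq_learner`.
#' @export
learner_xgboost <- function(nthread = 1) {
  structure(list(
    name = "xgboost",
    early_stopping = TRUE,
    fit = function(x, y, weights, config, valid = NULL) {
      lev <- levels(y)
      k <- length(lev)
      params <- list(
        eta = config$learning_rate,
        max_depth = config$depth,
        lambda = config$l2_reg,
        max_bin = config$border_count,
        tree_method = "hist",
        nthread = nthread,
        seed = config$seed %||% 0
      )
      if (k == 2) {
        params$objective <- "binary:logistic"
      } else {
        params$objective <- "multi:softprob"
        params$num_class <- k
      }
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y) - 1L,
                                     weight = weights)
      args <- list(params = params, data = dtrain,
                   nrounds = config$iterations, verbose = 0)
      if (!is.null(valid) && config$early_stopping_patience > 0) {
        args$evals <- list(val = xgboost::xgb.DMatrix(
          as.matrix(valid$x), label = as.integer(valid$y) - 1L))
        args$early_stopping_rounds <- config$early_stopping_patience
      }
      list(booster = do.call(xgboost::xgb.train, args), levels = lev)
    },
    predict_prob = function(fit, x) {
      p <- stats::predict(fit$booster, xgboost::xgb.DMatrix(as.matrix(x)))
      if (length(fit$levels) == 2) p <- cbind(1 - p, p)
      colnames(p) <- fit$levels
      p
    }
  ), class = "eq_learner")
}

#' @rdname learner_xgboost
#' @export
learner_rpart <- function() {
  structure(list(
    name = "rpart",
    early_stopping = FALSE,
    fit = function(x, y, weights, config, valid = NULL) {
      df <- as.data.frame(as.matrix(x))
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$.y <- y
      w <- weights
      list(tree = rpart::rpart(
             .y ~ ., data = df, weights = w, method = "class",
             control = rpart::rpart.control(maxdepth = min(config$depth, 30),
                                            cp = 1e-4, xval = 0)),
           levels = levels(y))
    },
    predict_prob = function(fit, x) {
      df <- as.data.frame(as.matrix(x))
      names(df) <- paste0("f", seq_len(ncol(df)))
      p <- stats::predict(fit$tree, newdata = df, type = "prob")
      # rpart drops absent classes; reinstate zero columns in level order
      out <- matrix(0, nrow(df), length(fit$levels),
                    dimnames = list(NULL, fit$levels))
      out[, colnames(p)] <- p
      out
    }
  ), class = "eq_learner")
}

#' @rdname learner_xgboost
#' @export
default_learner <- function() {
  if (requireNamespace("xgboost", quietly = TRUE)) learner_xgboost()
  else learner_rpart()
}

# stratified holdout indices for early-stopping validation; returns NULL when
# any class is too small to split safely
.stratified_holdout <- function(y, fraction, seed) {
  if (min(table(y)) < 10) return(NULL)
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    sample(ix, max(1L, floor(fraction * length(ix))))
  }), use.names = FALSE)
  sort(idx)
}
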