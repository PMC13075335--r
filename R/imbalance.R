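#' Balanced class weights inversely proportional to class frequency
#'
#' Computes `w_c = N / (k * n_c)` for each class, where `N` is the total
#' sample count, `k` the number of classes and `n_c` the class count. The
#' weights satisfy the conservation identity `sum_c n_c * w_c = N`, so the
#' total effective sample size is unchanged while each class contributes
#' equally to the weighted loss.
#'
#' @param counts Named vector of positive per-class counts.
#' @return Object of class `class_weights`: list with `weights` (named numeric),
#'   `N` and `k`.
#' @export
#' @examples
#' class_weights(c(affiliative = 34897, neutral = 13463, avoidant = 1910))
class_weights <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named by class")
  if (any(counts <= 0)) {
    stop("zero or negative count for class(es): ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  N <- sum(counts)
  k <- length(counts)
  w <- stats::setNames(as.numeric(N / (k * counts)), names(counts))
  structure(list(weights = w, N = N, k = k), class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat("Balanced class weights (N =", x$N, ", k =", x$k, ")\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Class-weighted multinomial log loss
#'
#' `L = sum_i w_{c_i} * (-log p_i[y_i])`, the weighted cross-entropy the
#' cost-sensitive learner minimizes. True-class probabilities are clipped at
#' `eps` (with a warning) so the loss stays finite.
#'
#' @param labels Vector of true class labels.
#' @param probs Matrix of predicted probabilities with one column per class
#'   (named by class); rows must sum to 1.
#' @param weights A `class_weights` object (or named numeric of per-class
#'   weights).
#' @param eps Clipping floor for true-class probabilities.
#' @return Non-negative scalar loss.
#' @export
weighted_log_loss <- function(labels, probs, weights, eps = 1e-15) {
  w <- if (inherits(weights, "class_weights")) weights$weights else weights
  labels <- as.character(labels)
  if (is.null(colnames(probs))) stop("probs must have class column names")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  p <- probs[cbind(seq_along(labels), match(labels, colnames(probs)))]
  if (anyNA(p)) stop("label not among probability columns")
  if (any(p < eps)) {
    warning("true-class probability of 0 clipped at eps = ", eps)
    p <- pmax(p, eps)
  }
  sum(w[labels] * (-log(p)))
}

#' Accuracy and balanced accuracy of the always-majority predictor
#'
#' A classifier that always predicts the most frequent class attains accuracy
#' `max(n_c) / N` but balanced accuracy `1/k` (one class at 100% recall, all
#' others at 0), which is why balanced accuracy is the primary metric under
#' severe imbalance.
#'
#' @param counts Named vector of per-class counts.
#' @return List with `accuracy` and `balanced_accuracy` (proportions in
#'   `[0, 1]`).
#' @export
#' @examples
#' naive_baseline(c(a = 34897, n = 13463, v = 1910))
naive_baseline <- function(counts) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  list(accuracy = max(counts) / sum(counts),
       balanced_accuracy = 1 / length(counts))
}

#' Imbalance diagnostics for a two-level taxonomy
#'
#' Max:min count ratio and per-class percentage shares, at the leaf level and
#' (derived via [leaf_parent()] unless supplied) the parent level.
#'
#' @param leaf_counts Named vector of leaf counts.
#' @param parent_counts Optional named vector of parent counts; derived from
#'   `leaf_counts` when `NULL`.
#' @return List of two lists (`leaf`, `parent`), each with `ratio` (max:min)
#'   and `share_pct` (named percentages).
#' @export
imbalance_report <- function(leaf_counts, parent_counts = NULL) {
  if (any(leaf_counts <= 0)) stop("counts must be positive")
  if (is.null(parent_counts)) {
    parent_counts <- tapply(leaf_counts, leaf_parent(names(leaf_counts)), sum)
    parent_counts <- parent_counts[behavior_parents()]
  }
  lvl <- function(counts) {
    list(ratio = max(counts) / min(counts),
         share_pct = 100 * counts / sum(counts))
  }
  list(leaf = lvl(leaf_counts), parent = lvl(parent_counts))
}

#' Accounting for balancing by random undersampling
#'
#' Undersampling every class to the minority count retains `k * min(n_c)`
#' samples; the rest of the training signal is discarded. Provided as a
#' diagnostic for why undersampling is rejected in favor of cost-sensitive
#' weighting.
#'
#' @param counts Named vector of positive per-class counts.
#' @return List with `retained` (sample count) and `discarded_fraction`.
#' @export
#' @examples
#' undersample_plan(c(a = 34897, n = 13463, v = 1910))  # retains 5730
undersample_plan <- function(counts) {
  stopifnot(all(counts > 0))
  retained <- length(counts) * min(counts)
  list(retained = retained, discarded_fraction = 1 - retained / sum(counts))
}

#' SMOTE interpolation kernel (comparator only)
#'
#' The convex combination `x_i + lambda * (x_nn - x_i)` used by synthetic
#' minority oversampling. Shipped only as a comparator: the default pipeline
#' uses cost-sensitive weighting, since interpolated samples represent
#' hypothetical rather than observed behavior.
#'
#' @param x_i,x_nn Equal-length numeric vectors (a minority sample and a
#'   neighbor).
#' @param lambda Interpolation weight in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @export
smote_interpolate <- function(x_i, x_nn, lambda) {
  if (length(x_i) != length(x_nn)) stop("vectors must have equal dimension")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  x_i + lambda * (x_nn - x_i)
}
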