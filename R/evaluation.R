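#' Confusion matrix over a fixed label alphabet
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Label alphabet; defaults to the canonical behavior order for
#'   known labels, otherwise the sorted union.
#' @return A square contingency table (rows = truth, columns = predicted).
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (is.null(levels)) {
    seen <- unique(c(truth, pred))
    canon <- c(behavior_parents(), behavior_leaves())
    levels <- if (all(seen %in% canon)) intersect(canon, seen) else sort(seen)
  }
  table(truth = factor(truth, levels = levels),
        pred = factor(pred, levels = levels))
}

#' Balanced accuracy (mean per-class recall)
#'
#' The unweighted mean over true classes of the per-class recall
#' `diagonal / row sum`. Equals `1/k` for any majority-only predictor with k
#' classes, making it the metric of choice under severe class imbalance.
#'
#' @param cm Square confusion matrix (rows = truth), or a truth vector if
#'   `pred` is given.
#' @param pred Optional predicted labels; when supplied, `cm` is interpreted
#'   as the truth vector.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(matrix(c(8, 4, 2, 6), 2))  # 0.7
balanced_accuracy <- function(cm, pred = NULL) {
  if (!is.null(pred)) cm <- confusion_matrix(cm, pred)
  cm <- as.matrix(cm)
  support <- rowSums(cm)
  if (any(support == 0)) {
    stop("balanced accuracy undefined: class(es) with zero support: ",
         paste(rownames(cm)[support == 0], collapse = ", "))
  }
  mean(diag(cm) / support)
}

#' Per-class precision, recall and F1 with macro and weighted averages
#'
#' Standard one-vs-rest definitions from a confusion matrix. A class never
#' predicted gets precision 0 (with a warning); F1 is 0 when precision and
#' recall are both 0. The support-weighted recall equals plain accuracy.
#'
#' @param cm Square confusion matrix (rows = truth, columns = predicted).
#' @return List with `per_class` (data.frame: class, precision, recall, f1,
#'   support), `macro` and `weighted` (named numeric vectors), and `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (is.null(rownames(cm))) {
    rownames(cm) <- colnames(cm) <- paste0("class", seq_len(nrow(cm)))
  }
  support <- rowSums(cm)
  predicted <- colSums(cm)
  if (any(predicted == 0)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(colnames(cm)[predicted == 0], collapse = ", "))
  }
  precision <- ifelse(predicted > 0, diag(cm) / predicted, 0)
  recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = rownames(cm), precision = precision,
                          recall = recall, f1 = f1, support = as.integer(support),
                          row.names = NULL, stringsAsFactors = FALSE)
  wt <- support / sum(support)
  list(per_class = per_class,
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       weighted = c(precision = sum(wt * precision), recall = sum(wt * recall),
                    f1 = sum(wt * f1)),
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Build a cross-validation split plan
#'
#' Three protocols: `stratified_kfold` deals each class's samples across k
#' folds so per-fold class counts differ by at most one from exact
#' stratification; `grouped_kfold` stratifies whole videos into folds by each
#' video's majority label, so no video spans folds; `lovo` (leave-one-video-out)
#' makes one fold per video.
#'
#' @param labels Sample labels used for stratification.
#' @param video_ids Video (group) id per sample; required for grouped/lovo.
#' @param protocol `"stratified_kfold"`, `"grouped_kfold"` or `"lovo"`.
#' @param k Number of folds (ignored for lovo).
#' @param seed Seed for the shuffling.
#' @return Object of class `split_plan`: list with `protocol`, `k`, `fold`
#'   (integer fold id per sample) and `groups`.
#' @export
make_splits <- function(labels, video_ids = NULL,
                        protocol = c("stratified_kfold", "grouped_kfold", "lovo"),
                        k = 5, seed = 1) {
  protocol <- match.arg(protocol)
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (protocol != "lovo" && k < 2) stop("k must be >= 2")
  if (protocol != "stratified_kfold" && is.null(video_ids)) {
    stop(protocol, " requires video_ids")
  }
  set.seed(seed)
  fold <- integer(n)
  if (protocol == "stratified_kfold") {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < k) {
        warning("class '", cl, "' has fewer samples (", length(idx),
                ") than folds (", k, "); packed into fewer folds")
      }
      off <- sample.int(k, 1)
      fold[idx] <- (seq_along(idx) + off) %% k + 1L
    }
  } else if (protocol == "grouped_kfold") {
    vids <- unique(video_ids)
    vmaj <- vapply(vids, function(v) {
      names(which.max(table(labels[video_ids == v])))
    }, character(1))
    vfold <- integer(length(vids))
    pos <- 0L
    for (cl in unique(vmaj)) {
      vi <- sample(which(vmaj == cl))
      vfold[vi] <- (seq_along(vi) + pos) %% k + 1L
      pos <- pos + length(vi)
    }
    fold <- vfold[match(video_ids, vids)]
  } else {
    vids <- unique(video_ids)
    k <- length(vids)
    fold <- match(video_ids, vids)
  }
  structure(list(protocol = protocol, k = as.integer(k), fold = fold,
                 groups = video_ids, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", x$protocol, "with", x$k, "folds over",
      length(x$fold), "samples\n")
  print(table(fold = x$fold))
  invisible(x)
}

#' Out-of-fold predictions under a split plan
#'
#' For every fold, fits a model on the other folds via `factory` and predicts
#' the held-out fold, so each sample is predicted exactly once by a model never
#' trained on its fold (nor on its video, under grouped/lovo plans). Any
#' preprocessing done inside `factory` (e.g. the scaler fit by [equiboost()])
#' is therefore fit on training folds only.
#'
#' @param x Feature matrix/data.frame.
#' @param y Labels.
#' @param plan A [make_splits()] plan covering all rows of `x`.
#' @param factory Function `(x_train, y_train, fold)` returning a fitted model.
#' @param predict_fn Function `(model, x_test)` returning labels; defaults to
#'   `predict`.
#' @return List with `predictions` (character, one per sample), `fold`, and
#'   `fold_scores` (per-fold balanced accuracy).
#' @export
cross_val_predict <- function(x, y, plan, factory,
                              predict_fn = function(m, d) predict(m, d)) {
  if (length(plan$fold) != nrow(x)) stop("plan does not cover all samples")
  y <- as.character(y)
  preds <- character(length(y))
  scores <- numeric(0)
  for (f in sort(unique(plan$fold))) {
    te <- which(plan$fold == f)
    tr <- which(plan$fold != f)
    model <- factory(x[tr, , drop = FALSE], y[tr], f)
    p <- as.character(predict_fn(model, x[te, , drop = FALSE]))
    preds[te] <- p
    sc <- try(balanced_accuracy(confusion_matrix(y[te], p)), silent = TRUE)
    scores <- c(scores, if (inherits(sc, "try-error")) NA_real_ else sc)
  }
  list(predictions = preds, fold = plan$fold, fold_scores = scores)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n Success and trial counts, `0 <= successes <= n`.
#' @param confidence Confidence level (default 0.95).
#' @return Numeric `c(low, high)` within `[0, 1]`.
#' @export
#' @examples
#' wilson_ci(0, 10)  # upper bound z^2 / (n + z^2)
wilson_ci <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' McNemar's test on discordant pair counts
#'
#' Chi-square statistic `(b - c)^2 / (b + c)` on the two discordant cells of a
#' paired-prediction table, without continuity correction by default (set
#' `correction = TRUE` for the corrected variant), with the p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param b,c Discordant pair counts (model A right & B wrong, and vice versa).
#' @param correction Apply the continuity correction.
#' @return List with `statistic`, `p_value`, `correction`.
#' @export
#' @examples
#' mcnemar_test(15, 5)$statistic  # 5
mcnemar_test <- function(b, c, correction = FALSE) {
  if (b + c == 0) {
    warning("no discordant pairs; statistic is 0")
    return(list(statistic = 0, p_value = 1, correction = correction))
  }
  adj <- if (correction) 1 else 0
  stat <- (max(abs(b - c) - adj, 0))^2 / (b + c)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       correction = correction)
}

#' Paired t-test on per-fold scores
#'
#' Standard paired t statistic on the fold-wise score differences of two
#' pipelines evaluated on identical splits. Zero variance of the differences is
#' flagged degenerate (identical vectors give t = 0; a constant non-zero
#' difference gives an infinite statistic).
#'
#' @param scores_a,scores_b Equal-length (>= 2) per-fold score vectors.
#' @return List with `statistic`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_fold_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(statistic = stat, p_value = if (stat == 0) 1 else 0,
                df = n - 1, mean_diff = mean(d), degenerate = TRUE))
  }
  stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = stat,
       p_value = 2 * stats::pt(-abs(stat), df = n - 1),
       df = n - 1, mean_diff = mean(d), degenerate = FALSE)
}

#' One-vs-rest ROC AUC and average precision per class
#'
#' Rank-based AUC (ties counted half) and non-interpolated average precision
#' for each class against the rest, from a class-probability matrix.
#'
#' @param labels True labels.
#' @param probs Probability matrix with one named column per class; rows sum
#'   to 1.
#' @return Data.frame with `class`, `auc`, `average_precision`, plus macro
#'   averages in the `macro` attribute.
#' @export
ovr_curves <- function(labels, probs) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("one-vs-rest curves undefined for single-class labels")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  classes <- colnames(probs)
  res <- lapply(classes, function(cl) {
    s <- probs[, cl]
    pos <- labels == cl
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) {
      return(c(auc = NA_real_, ap = NA_real_))
    }
    r <- rank(s)
    auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    ord <- order(s, decreasing = TRUE)
    hits <- pos[ord]
    prec_at <- cumsum(hits) / seq_along(hits)
    c(auc = auc, ap = sum(prec_at[hits]) / n_pos)
  })
  res <- do.call(rbind, res)
  out <- data.frame(class = classes, auc = res[, "auc"],
                    average_precision = res[, "ap"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "macro") <- c(auc = mean(res[, "auc"], na.rm = TRUE),
                          average_precision = mean(res[, "ap"], na.rm = TRUE))
  out
}
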