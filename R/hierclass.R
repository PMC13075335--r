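#' Fit a (hierarchical) cost-sensitive behavior classifier
#'
#' The central fitting function. With `architecture = "hierarchical"` (the
#' default) it fits the two-stage model: Stage 1 is a three-way classifier over
#' parent valence categories (affiliative / neutral / avoidant), and Stage 2
#' holds one binary classifier per parent, each trained only on samples whose
#' ground-truth parent matches, discriminating that parent's two leaves. Every
#' stage is trained with balanced class weights `w_c = N/(k n_c)` computed on
#' its own label alphabet (k = 3 for Stage 1, k = 2 per Stage 2 model), so
#' misclassifying a rare avoidant sample costs roughly the imbalance ratio
#' times an affiliative one. `architecture = "flat"` fits a single six-way
#' model as the non-hierarchical baseline; `architecture = "parent"` fits
#' Stage 1 only.
#'
#' Features are robust-scaled (median/IQR, fitted on the training data passed
#' here) and missing values imputed at the scaled center before reaching the
#' learner. When the learner supports early stopping and the stage config has
#' positive patience, a 20% stratified holdout of the training data is used as
#' the validation set and the stage is fit on the remaining 80%.
#'
#' @param x Feature matrix or data.frame (rows = samples), typically from
#'   [extract_features()]; `NA` marks missing values.
#' @param y Leaf labels (character or factor over [behavior_leaves()]).
#' @param architecture `"hierarchical"`, `"flat"` or `"parent"`.
#' @param stage1,stage2 [stage_config()] objects; defaults are 400 rounds at
#'   depth 10 for Stage 1 and 300 rounds at depth 8 for Stage 2.
#' @param learner A base learner satisfying the [learner_xgboost()] contract.
#' @param class_weighting `"balanced"` (cost-sensitive, default) or `"none"`.
#' @param holdout_fraction Fraction held out for early-stopping validation.
#' @param seed Master seed; child seeds for each stage and the holdout split
#'   are derived from it by fixed offsets.
#' @return An object of class `equiboost` with [predict.equiboost()],
#'   `print()` and `summary()` methods.
#' @export
#' @examples
#' sim <- simulate_dyads(c(affiliative_active = 60, affiliative_subtle = 60,
#'                         neutral_horse = 60, neutral_human = 60,
#'                         avoidant_horse = 60, avoidant_human = 60),
#'                       seed = 1)
#' feats <- extract_features(sim$frames)
#' fit <- equiboost(feats, sim$labels$leaf, learner = learner_rpart(),
#'                  stage1 = stage_config(iterations = 5, depth = 4),
#'                  stage2 = stage_config(iterations = 5, depth = 4))
#' table(predict(fit, feats), sim$labels$leaf)
equiboost <- function(x, y,
                      architecture = c("hierarchical", "flat", "parent"),
                      stage1 = stage_config(),
                      stage2 = stage_config(iterations = 300, depth = 8),
                      learner = default_learner(),
                      class_weighting = c("balanced", "none"),
                      holdout_fraction = 0.2, seed = 1) {
  architecture <- match.arg(architecture)
  class_weighting <- match.arg(class_weighting)
  stopifnot(inherits(stage1, "stage_config"), inherits(stage2, "stage_config"))
  y <- as.character(y)
  if (!all(y %in% behavior_leaves())) {
    stop("labels must be leaf categories; unknown: ",
         paste(setdiff(unique(y), behavior_leaves()), collapse = ", "))
  }
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  leaves <- intersect(behavior_leaves(), unique(y))
  parents <- intersect(behavior_parents(), unique(leaf_parent(leaves)))
  cnt <- table(factor(y, levels = leaves))
  if (any(cnt < 2)) {
    stop("need at least 2 samples per leaf; too few: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  if (architecture == "hierarchical") {
    per_parent <- table(leaf_parent(leaves))
    lonely <- names(per_parent)[per_parent < 2]
    if (length(lonely)) {
      stop("parent(s) with only one leaf represented: ",
           paste(lonely, collapse = ", "))
    }
  }

  scaler <- fit_scaler(x)
  xs <- predict(scaler, x)
  parent_y <- leaf_parent(y)

  fit_one <- function(rows, labels, levels, cfg, child_seed) {
    cfg$seed <- cfg$seed %||% (seed + child_seed)
    yy <- factor(labels, levels = levels)
    w <- if (class_weighting == "balanced") {
      cw <- class_weights(table(yy))
      as.numeric(cw$weights[as.character(yy)])
    } else rep(1, length(yy))
    xx <- xs[rows, , drop = FALSE]
    valid <- NULL
    if (learner$early_stopping && cfg$early_stopping_patience > 0) {
      ho <- .stratified_holdout(yy, holdout_fraction, seed + child_seed + 100L)
      if (!is.null(ho)) {
        valid <- list(x = xx[ho, , drop = FALSE], y = yy[ho])
        xx <- xx[-ho, , drop = FALSE]
        w <- w[-ho]
        yy <- yy[-ho]
      }
    }
    list(fit = learner$fit(xx, yy, w, cfg, valid), levels = levels,
         config = cfg)
  }

  stage1_fit <- stage2_fits <- flat_fit <- NULL
  if (architecture %in% c("hierarchical", "parent")) {
    stage1_fit <- fit_one(seq_along(y), parent_y, parents, stage1, 1L)
  }
  if (architecture == "hierarchical") {
    stage2_fits <- list()
    for (i in seq_along(parents)) {
      p <- parents[i]
      rows <- which(parent_y == p)
      kids <- intersect(behavior_leaves(), unique(y[rows]))
      stage2_fits[[p]] <- fit_one(rows, y[rows], kids, stage2, 1L + i)
    }
  }
  if (architecture == "flat") {
    flat_fit <- fit_one(seq_along(y), y, leaves, stage1, 9L)
  }

  structure(list(architecture = architecture, scaler = scaler,
                 leaves = leaves, parents = parents,
                 stage1 = stage1_fit, stage2 = stage2_fits, flat = flat_fit,
                 configs = list(stage1 = stage1, stage2 = stage2),
                 class_weighting = class_weighting,
                 counts = cnt, learner = learner, seed = seed,
                 n = nrow(x)),
            class = "equiboost")
}

.stage_prob <- function(object, stage, x) {
  p <- object$learner$predict_prob(stage$fit, x)
  p[, stage$levels, drop = FALSE]
}

.argmax_label <- function(prob) {
  colnames(prob)[max.col(prob, ties.method = "first")]
}

#' Predict behavior categories from a fitted model
#'
#' For hierarchical models, `routing` selects how samples reach Stage 2:
#' `"cascaded"` (default) routes each sample by Stage 1's predicted parent —
#' the end-to-end deployment mode, where Stage 1 errors propagate and
#' cross-parent leaf errors become possible; `"oracle"` routes by the supplied
#' ground-truth parent (`true_parent`), isolating within-parent discrimination,
#' so the leaf confusion matrix is block-diagonal by construction. In both
#' modes the predicted leaf is always a child of the routing parent. Argmax
#' ties are broken by the canonical class order.
#'
#' @param object Fitted [equiboost()] model.
#' @param newdata Feature matrix/data.frame with the training columns.
#' @param type `"leaf"` (default), `"parent"`, `"prob"` (composed leaf
#'   probabilities `P(parent) * P(leaf | parent)` for hierarchical models) or
#'   `"parent_prob"` (Stage 1 probabilities).
#' @param routing `"cascaded"` or `"oracle"` (hierarchical only).
#' @param true_parent Ground-truth parent labels, required for oracle routing.
#' @param ... Unused.
#' @return Factor of predicted labels, or a probability matrix for the prob
#'   types.
#' @export
predict.equiboost <- function(object, newdata,
                              type = c("leaf", "parent", "prob", "parent_prob"),
                              routing = c("cascaded", "oracle"),
                              true_parent = NULL, ...) {
  type <- match.arg(type)
  routing <- match.arg(routing)
  xs <- predict(object$scaler, newdata)
  n <- nrow(xs)

  if (object$architecture == "flat") {
    p <- .stage_prob(object, object$flat, xs)
    if (type == "prob") return(p)
    leaf <- .argmax_label(p)
    if (type == "leaf") return(factor(leaf, levels = object$leaves))
    return(factor(leaf_parent(leaf), levels = object$parents))
  }

  p1 <- .stage_prob(object, object$stage1, xs)
  if (type == "parent_prob") return(p1)
  if (object$architecture == "parent") {
    if (type %in% c("leaf", "prob")) {
      stop("parent-only model: leaf predictions unavailable")
    }
    return(factor(.argmax_label(p1), levels = object$parents))
  }

  if (type == "prob") {
    out <- matrix(0, n, length(object$leaves),
                  dimnames = list(NULL, object$leaves))
    for (p in object$parents) {
      p2 <- .stage_prob(object, object$stage2[[p]], xs)
      out[, colnames(p2)] <- p1[, p] * p2
    }
    return(out)
  }

  route <- if (routing == "oracle") {
    if (is.null(true_parent)) stop("oracle routing requires true_parent")
    true_parent <- as.character(true_parent)
    bad <- setdiff(unique(true_parent), object$parents)
    if (length(bad)) stop("unknown parent label(s): ", paste(bad, collapse = ", "))
    true_parent
  } else {
    .argmax_label(p1)
  }
  if (type == "parent") return(factor(route, levels = object$parents))

  leaf <- character(n)
  for (p in object$parents) {
    rows <- which(route == p)
    if (!length(rows)) next
    p2 <- .stage_prob(object, object$stage2[[p]], xs[rows, , drop = FALSE])
    leaf[rows] <- .argmax_label(p2)
  }
  # hierarchy consistency guard: every leaf must be a child of its route
  stopifnot(all(leaf_parent(leaf) == route))
  factor(leaf, levels = object$leaves)
}

#' @export
print.equiboost <- function(x, ...) {
  cat("Cost-sensitive behavior classifier (", x$architecture,
      " architecture)\n", sep = "")
  cat("  base learner: ", x$learner$name,
      "; class weighting: ", x$class_weighting, "\n", sep = "")
  cat("  trained on ", x$n, " samples, ", length(x$leaves), " leaf / ",
      length(x$parents), " parent categories\n", sep = "")
  if (x$architecture %in% c("hierarchical", "parent")) {
    cat("  stage 1: ", x$configs$stage1$iterations, " rounds, depth ",
        x$configs$stage1$depth, "\n", sep = "")
  }
  if (x$architecture == "hierarchical") {
    cat("  stage 2: ", x$configs$stage2$iterations, " rounds, depth ",
        x$configs$stage2$depth, " (", length(x$stage2), " binary models)\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.equiboost <- function(object, ...) {
  w_parent <- if (object$architecture != "flat") {
    class_weights(tapply(object$counts, leaf_parent(names(object$counts)),
                         sum)[object$parents])$weights
  } else NULL
  out <- list(architecture = object$architecture,
              learner = object$learner$name,
              class_weighting = object$class_weighting,
              counts = object$counts,
              parent_weights = w_parent,
              configs = object$configs, n = object$n)
  class(out) <- "summary.equiboost"
  out
}

#' @export
print.summary.equiboost <- function(x, ...) {
  cat("equiboost", x$architecture, "model,", x$learner, "learner,",
      x$n, "training samples\n")
  cat("leaf counts:\n"); print(x$counts)
  if (!is.null(x$parent_weights)) {
    cat("stage-1 balanced class weights:\n")
    print(round(x$parent_weights, 3))
  }
  invisible(x)
}
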