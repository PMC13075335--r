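#' Fit a robust median/IQR scaler
#'
#' Per-column robust scaling statistics: the median and the interquartile range
#' `IQR = Q3 - Q1`, computed on observed (non-missing) entries only, with
#' quantiles by linear interpolation between order statistics. Robust scaling
#' is preferred over z-scoring here because pose-estimation failures produce
#' outliers that would distort a mean/sd fit.
#'
#' @param x Numeric matrix or data.frame of features (rows = samples); `NA`
#'   marks missing entries.
#' @return An object of class `robust_scaler` with elements `median`, `iqr`
#'   and `features`.
#' @export
#' @examples
#' sc <- fit_scaler(data.frame(a = c(1, 2, 3, 4, 5)))
#' sc$median  # 3
#' sc$iqr     # 2
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a scaler")
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  q <- apply(x, 2, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE,
             type = 7, names = FALSE)
  structure(list(median = med, iqr = q[2, ] - q[1, ],
                 features = colnames(x)),
            class = "robust_scaler")
}

#' @export
print.robust_scaler <- function(x, ...) {
  cat("Robust median/IQR scaler for", length(x$median), "features\n")
  cat("  zero-IQR (center-only) columns:", sum(x$iqr == 0), "\n")
  invisible(x)
}

#' Apply a robust scaler to a feature matrix
#'
#' Observed entries become `(x - median) / IQR`; columns with zero IQR are
#' centered only (no division). Missing entries are imputed with 0 after
#' scaling, i.e. at the robust center of the training distribution.
#'
#' @param object A `robust_scaler` from [fit_scaler()].
#' @param newdata Matrix or data.frame with the same columns, in the same
#'   order, as the training data.
#' @param ... Unused.
#' @return Numeric matrix of scaled features with no missing entries.
#' @export
predict.robust_scaler <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$median)) {
    stop("dimension mismatch: scaler has ", length(object$median),
         " features, data has ", ncol(x))
  }
  if (!is.null(colnames(x)) && !is.null(object$features) &&
      !identical(colnames(x), object$features)) {
    stop("column order does not match the fitted scaler")
  }
  denom <- ifelse(object$iqr > 0, object$iqr, 1)
  out <- sweep(sweep(x, 2, object$median, "-"), 2, denom, "/")
  out[is.na(out)] <- 0
  out
}

#' Serialize / restore a robust scaler as a plain data.frame
#'
#' @param scaler A `robust_scaler`.
#' @param df A data.frame with columns `feature`, `median`, `iqr`.
#' @return `scaler_to_df()`: a data.frame; `scaler_from_df()`: a
#'   `robust_scaler`.
#' @export
scaler_to_df <- function(scaler) {
  data.frame(feature = scaler$features %||% names(scaler$median),
             median = unname(scaler$median), iqr = unname(scaler$iqr),
             stringsAsFactors = FALSE)
}

#' @rdname scaler_to_df
#' @export
scaler_from_df <- function(df) {
  structure(list(median = stats::setNames(df$median, df$feature),
                 iqr = stats::setNames(df$iqr, df$feature),
                 features = df$feature),
            class = "robust_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
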