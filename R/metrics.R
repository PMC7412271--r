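# Classification performance measures and the source reduction rate.

#' Confusion-based performance report
#'
#' Computes the confusion counts and the four performance measures, with
#' class +1 as "positive": accuracy (correct / total), sensitivity
#' (TP / (TP + FN)), specificity (TN / (TN + FP)) and their geometric mean.
#' All measures are percentages and are kept at full precision; rounding to
#' two decimals happens only in `print()`/`format()`. A ratio with a zero
#' denominator (no positive or no negative samples) is reported as 0 and the
#' report is flagged `degenerate`, so elimination curves never crash on
#' pathological subsets.
#'
#' @param y_true,y_pred label vectors of equal length with values in
#'   \{-1, +1\}.
#' @return An object of class `performance_report` with fields `tp`, `tn`,
#'   `fp`, `fn`, `accuracy`, `sensitivity`, `specificity`, `geo_mean`
#'   (percentages) and `degenerate`.
#' @examples
#' score(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    mkl_stop("parameter", "y_true and y_pred must have equal length")
  if (!all(c(y_true, y_pred) %in% c(-1, 1)))
    mkl_stop("label", "labels must take values in {-1, +1}")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  safe_ratio <- function(num, den) if (den == 0) 0 else 100 * num / den
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = 100 * (tp + tn) / length(y_true),
    sensitivity = sens, specificity = spec,
    geo_mean = geo_mean(sens, spec),
    degenerate = (tp + fn == 0) || (tn + fp == 0)
  ), class = "performance_report")
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(sensitivity * specificity)`, on the same percentage scale as its
#' arguments. Robust to class imbalance; used as the tuning objective.
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @return The geometric mean percentage.
#' @examples
#' geo_mean(78.57, 100)   # 88.6397...
#' @export
geo_mean <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0))
    mkl_stop("parameter", "sensitivity and specificity must be non-negative")
  sqrt(sensitivity * specificity)
}

#' Source reduction rate
#'
#' `1 - n_selected / n_total`: the fraction of information sources discarded
#' by a selection. 0 means nothing was discarded; values near 1 mean the
#' task is solved with very few sources.
#'
#' @param n_selected number of sources kept (`0 <= n_selected <= n_total`).
#' @param n_total total number of sources (`>= 1`).
#' @return A rate in `[0, 1]`.
#' @examples
#' reduction_rate(2, 22)   # 0.909...
#' @export
reduction_rate <- function(n_selected, n_total) {
  if (!is_count(n_total) || n_total < 1)
    mkl_stop("parameter", "n_total must be a positive integer")
  if (!is_count(n_selected) || n_selected < 0 || n_selected > n_total)
    mkl_stop("parameter", "n_selected must lie in [0, n_total]")
  1 - n_selected / n_total
}

#' @export
format.performance_report <- function(x, ...) {
  sprintf("acc %.2f%% | geo-mean %.2f%% | sens %.2f%% | spec %.2f%%%s",
          x$accuracy, x$geo_mean, x$sensitivity, x$specificity,
          if (x$degenerate) " [degenerate: one class absent]" else "")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("performance_report:", format(x), "\n")
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
             accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, geo_mean = x$geo_mean,
             degenerate = x$degenerate)
}

# JSON-ready plain list.
report_to_list <- function(x) unclass(x)
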