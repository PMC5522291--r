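#' Confusion counts for a two-class site predictor
#'
#' Bookkeeping follows the misclassification-count parameterization: the
#' number of true sites tested (`n_pos`), true non-sites tested (`n_neg`),
#' true sites predicted negative (`fn`) and non-sites predicted positive
#' (`fp`).
#'
#' @param n_pos,n_neg class sizes (>= 0 integers).
#' @param fn false negatives, 0 <= fn <= n_pos.
#' @param fp false positives, 0 <= fp <= n_neg.
#' @return object of class `m5c_confusion`.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  v <- c(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp)
  if (any(v != round(v)) || any(v < 0)) stop("counts must be non-negative integers")
  if (fn > n_pos) stop("fn cannot exceed n_pos")
  if (fp > n_neg) stop("fp cannot exceed n_neg")
  structure(as.list(as.integer(v)), names = names(v), class = "m5c_confusion")
}

as_binary_labels <- function(y, what = "labels") {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  if (!all(y %in% c("pos", "neg")))
    stop(what, " must be binary ('pos'/'neg' or logical)")
  factor(y, levels = c("pos", "neg"))
}

#' Confusion counts from paired label vectors
#'
#' @param y_true,y_pred equal-length vectors of `"pos"`/`"neg"` (or
#'   logical) labels.
#' @return an `m5c_confusion`.
#' @export
counts_from_predictions <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  yt <- as_binary_labels(y_true, "y_true")
  yp <- as_binary_labels(y_pred, "y_pred")
  confusion_counts(n_pos = sum(yt == "pos"), n_neg = sum(yt == "neg"),
                   fn = sum(yt == "pos" & yp == "neg"),
                   fp = sum(yt == "neg" & yp == "pos"))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' The four metrics in their misclassification-count form:
#' \deqn{Sn = 1 - fn/N^+, \quad Sp = 1 - fp/N^-, \quad
#'       Acc = 1 - (fn + fp)/(N^+ + N^-),}
#' \deqn{MCC = \frac{1 - (fn/N^+ + fp/N^-)}
#'   {\sqrt{(1 + (fp - fn)/N^+)\,(1 + (fn - fp)/N^-)}},}
#' algebraically identical to the classical Matthews correlation on
#' TP/FP/TN/FN.  When the MCC denominator is zero (all predictions in one
#' class), MCC is reported as 0 with a warning.
#'
#' @param counts an `m5c_confusion` (see [confusion_counts()]); `n_pos`
#'   and `n_neg` must both be >= 1.
#' @return object of class `m5c_metrics`: list with `sn`, `sp`, `acc`,
#'   `mcc` and the input `counts`.
#' @examples
#' metrics_from_counts(confusion_counts(475, 1425, fn = 143, fp = 2))
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "m5c_confusion"))
  np <- counts$n_pos; nn <- counts$n_neg
  fn <- counts$fn;    fp <- counts$fp
  if (np < 1L || nn < 1L) stop("both classes must be represented (n >= 1)")
  sn <- 1 - fn / np
  sp <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  f1 <- np + fp - fn   # n_pos * (1 + (fp - fn)/n_pos)
  f2 <- nn + fn - fp
  if (f1 == 0L || f2 == 0L) {
    warning("MCC denominator is zero (one-class predictions); reporting 0")
    mcc <- 0
  } else {
    mcc <- (1 - (fn / np + fp / nn)) / sqrt((f1 / np) * (f2 / nn))
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc, counts = counts),
            class = "m5c_metrics")
}

#' Metric set from paired label vectors
#' @inheritParams counts_from_predictions
#' @return an `m5c_metrics`.
#' @export
metrics_from_predictions <- function(y_true, y_pred) {
  metrics_from_counts(counts_from_predictions(y_true, y_pred))
}

#' @export
print.m5c_confusion <- function(x, ...) {
  cat(sprintf("confusion counts: N+ = %d (fn = %d), N- = %d (fp = %d)\n",
              x$n_pos, x$fn, x$n_neg, x$fp))
  invisible(x)
}

#' @export
print.m5c_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Sn = %.*f   Sp = %.*f   Acc = %.*f   MCC = %.*f\n",
              digits, x$sn, digits, x$sp, digits, x$acc, digits, x$mcc))
  print(x$counts)
  invisible(x)
}

#' ROC curve and AUC
#'
#' Thresholds the score vector at every distinct value (high scores mean
#' "positive"), giving a step curve from (0, 0) to (1, 1) in (false
#' positive rate, true positive rate) space; the AUC is computed by the
#' trapezoid rule, which under this tie-grouping equals the rank
#' statistic P(score of a random positive > score of a random negative),
#' ties counted one half.
#'
#' @param y_true `"pos"`/`"neg"` (or logical) labels; both classes must be
#'   present.
#' @param scores finite numeric scores, higher = more site-like.
#' @return object of class `m5c_roc`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  y <- as_binary_labels(y_true, "y_true")
  if (length(y) != length(scores)) stop("length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  np <- sum(y == "pos"); nn <- sum(y == "neg")
  if (np == 0L || nn == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; ypos <- y[o] == "pos"
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(ypos)[last]
  fpos <- cumsum(!ypos)[last]
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fpos / nn), tpr = c(0, tp / np))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "m5c_roc")
}

#' @export
print.m5c_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @rdname roc_curve
#' @param x an `m5c_roc`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.m5c_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate (1 - Sp)",
                 ylab = "true positive rate (Sn)",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
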