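#' Confusion counts for binary detection
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param positive the positive-class label (default `"tumor"`).
#' @return object of class `"confusion_counts"` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth, positive = "tumor") {
  if (length(pred) != length(truth)) stop_schema("pred/truth length mismatch")
  p <- pred == positive
  t <- truth == positive
  structure(
    list(
      TP = sum(p & t), FP = sum(p & !t),
      TN = sum(!p & !t), FN = sum(!p & t)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

as_confusion <- function(c) {
  if (!inherits(c, "confusion_counts")) {
    if (is.list(c) && all(c("TP", "FP", "TN", "FN") %in% names(c))) {
      c <- structure(c[c("TP", "FP", "TN", "FN")], class = "confusion_counts")
    } else {
      stop_schema("expected confusion_counts (or list with TP/FP/TN/FN)")
    }
  }
  if (any(unlist(c) < 0)) stop_range("confusion counts must be non-negative")
  c
}

#' Detection accuracy, (TP+TN)/(TP+TN+FP+FN)
#' @param c confusion counts.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  c <- as_confusion(c)
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop_degenerate("no observations")
  (c$TP + c$TN) / total
}

#' Precision (positive predictive value), TP/(TP+FP)
#' @param c confusion counts.
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(c) {
  c <- as_confusion(c)
  if (c$TP + c$FP == 0) {
    abort_lnq("precision undefined: no positive predictions",
              "lnqdetect_undefined_metric_error")
  }
  c$TP / (c$TP + c$FP)
}

#' Specificity (true-negative rate), TN/(TN+FP)
#' @param c confusion counts.
#' @return fraction in `[0, 1]`.
#' @export
specificity <- function(c) {
  c <- as_confusion(c)
  if (c$TN + c$FP == 0) {
    abort_lnq("specificity undefined: no true-negative or false-positive cases",
              "lnqdetect_undefined_metric_error")
  }
  c$TN / (c$TN + c$FP)
}

#' Dice overlap between two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param pred,truth 0/1 matrices of the same shape.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) stop_schema("mask shapes differ")
  a <- sum(pred)
  b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred == 1L & truth == 1L) / (a + b)
}

#' Training/evaluation loss from best-correct similarities
#'
#' Mean over samples of `1 - S_correct`, where `S_correct` is the best
#' similarity between a sample and the reference vectors of its true
#' class. This is the loss curve tracked during [lnq()] training.
#'
#' @param s_correct numeric vector of best-correct similarities in
#'   `[0, 1]`.
#' @return loss in `[0, 1]`.
#' @export
epoch_loss <- function(s_correct) {
  if (length(s_correct) < 1L) stop_degenerate("need at least one sample")
  if (any(s_correct < 0 | s_correct > 1)) {
    stop_range("similarities must lie in [0, 1]")
  }
  mean(1 - s_correct)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("evaluation report\n")
  cat(sprintf("  accuracy    %.4f\n", x$accuracy))
  if (!is.null(x$precision)) cat(sprintf("  precision   %.4f\n", x$precision))
  if (!is.null(x$specificity)) cat(sprintf("  specificity %.4f\n", x$specificity))
  if (!is.null(x$mean_dice)) {
    cat(sprintf("  mean Dice over %d tumor case(s): %.4f\n",
                x$n_tumor_cases, x$mean_dice))
  }
  invisible(x)
}
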