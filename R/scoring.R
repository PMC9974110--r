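# Operating-point selection, the slide-level IC score, and evaluation
# metrics. Conventions pinned here and asserted by tests:
#  - "positive" always means the IC class;
#  - predicted-positive means score STRICTLY greater than the threshold,
#    at both the patch (P > P0) and slide (S_IC > threshold) level;
#  - threshold ties break to the smallest maximizer;
#  - ratios with a zero denominator are reported as NA, never as 0.

f1_at_threshold <- function(scores, y, t) {
  pred <- scores > t
  tp <- sum(pred & y)
  fp <- sum(pred & !y)
  fn <- sum(!pred & y)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Select a decision threshold by F1 maximization
#'
#' Exhaustively searches the sorted unique scores (plus 0 and 1) and
#' returns the smallest threshold attaining the maximum F1 of the IC
#' class, with predicted-positive meaning score > threshold. An ROC-based
#' alternative (Youden's J) is available via `method = "roc"`.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels IC/Rest labels, same length.
#' @param level `"patch"` or `"slide"` (recorded in the fit).
#' @param method `"f1"` (default) or `"roc"`.
#' @return an object of class `threshold_fit` with fields `threshold`,
#'   `achieved_f1`, `candidates`, `level`, `method`.
#' @export
select_threshold <- function(scores, labels, level = c("patch", "slide"),
                             method = c("f1", "roc")) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (length(scores) != length(labels)) stop("data error: length mismatch", call. = FALSE)
  y <- labels_to_binary(labels) == 1
  if (length(unique(y)) < 2L) {
    stop("data error: threshold selection needs both classes", call. = FALSE)
  }
  cand <- sort(unique(c(0, scores, 1)))
  obj <- if (method == "f1") {
    vapply(cand, function(t) f1_at_threshold(scores, y, t), numeric(1))
  } else {
    vapply(cand, function(t) {
      pred <- scores > t
      tpr <- sum(pred & y) / sum(y)
      fpr <- sum(pred & !y) / sum(!y)
      tpr - fpr
    }, numeric(1))
  }
  best <- which(obj >= max(obj) - 1e-12)[1L]  # smallest maximizer
  structure(list(threshold = cand[best],
                 achieved_f1 = f1_at_threshold(scores, y, cand[best]),
                 candidates = cand, level = level, method = method),
            class = "threshold_fit")
}

#' Slide-level IC score
#'
#' S_IC = sum of the scores of patches classified as IC (P > P0) divided
#' by N, the total number of epithelial patches on the slide.
#'
#' @param patch_scores numeric patch scores in \[0, 1\].
#' @param p0 patch threshold.
#' @return S_IC in \[0, 1\].
#' @export
slide_score <- function(patch_scores, p0) {
  if (length(patch_scores) == 0L) {
    stop("no-epithelium slide: S_IC is undefined without epithelial patches",
         call. = FALSE)
  }
  sum(patch_scores[patch_scores > p0]) / length(patch_scores)
}

#' Binary slide call
#'
#' IC iff S_IC is strictly above the slide threshold.
#' @param s_ic slide score.
#' @param slide_threshold threshold in \[0, 1\].
#' @return `"IC"` or `"Rest"`.
#' @export
classify_slide <- function(s_ic, slide_threshold) {
  if (s_ic > slide_threshold) "IC" else "Rest"
}

#' Confusion counts and accuracy / precision / recall
#'
#' IC is the positive class. Accuracy = (TP+TN)/(TP+FP+FN+TN), precision =
#' TP/(TP+FP), recall = TP/(TP+FN); a ratio with zero denominator is NA.
#' @param predictions,truths IC/Rest vectors of equal length.
#' @param level `"patch"` or `"slide"`.
#' @return an object of class `eval_metrics`.
#' @export
evaluate <- function(predictions, truths, level = c("patch", "slide")) {
  level <- match.arg(level)
  if (length(predictions) != length(truths) || length(truths) == 0L) {
    stop("data error: predictions and truths must have equal positive length",
         call. = FALSE)
  }
  p <- labels_to_binary(predictions) == 1
  t <- labels_to_binary(truths) == 1
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(level = level, TP = tp, FP = fp, FN = fn, TN = tn,
                 accuracy = ratio(tp + tn, tp + fp + fn + tn),
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf("<eval_metrics %s> TP %d FP %d FN %d TN %d | acc %s prec %s rec %s\n",
              x$level, x$TP, x$FP, x$FN, x$TN,
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall)))
  invisible(x)
}
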