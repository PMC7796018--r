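#' ROC curve and AUC over a threshold sweep
#'
#' Sweeps every distinct score as a threshold (predict abnormal iff
#' score > threshold) and records TPR = TP / (TP + FN) against
#' FPR = FP / (FP + TN). Tied scores move together, so the curve steps
#' diagonally through ties and the trapezoid AUC equals the Mann-Whitney
#' rank statistic with ties counted 1/2.
#'
#' @param scores numeric anomaly scores (higher = more abnormal).
#' @param truth logical (or 0/1) ground-truth abnormal flags; both classes
#'   must be present.
#' @return list of class `roc_result`: `points` (data frame `threshold`,
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop("ROC needs at least one positive and one negative instance")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))              # tie groups of distinct scores
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(threshold = s[last],
                    fpr = fp[last] / nneg, tpr = tp[last] / npos)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", nrow(x$points), " points, AUC = ",
      formatC(x$auc, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Macro-averaged classification metrics
#'
#' Per-class precision `TP_i / TI_i` (total inferred as class i) and recall
#' `TP_i / TT_i` (total truly class i) are averaged unweighted over classes,
#' so rare classes count as much as frequent ones; a class never predicted
#' contributes precision 0. `F = 2PR / (P + R)` on the macro averages;
#' accuracy is the plain fraction `sum_i TP_i / Total`.
#'
#' @param predicted,true integer class indices in `1..n_classes` (or factors
#'   with common levels).
#' @param n_classes number of classes.
#' @return list with `precision`, `recall`, `f_measure`, `accuracy`.
#' @export
macro_metrics <- function(predicted, true, n_classes) {
  predicted <- as.integer(predicted); true <- as.integer(true)
  if (length(predicted) != length(true)) stop("length mismatch")
  if (any(c(predicted, true) < 1 | c(predicted, true) > n_classes)) {
    stop("labels outside 1..", n_classes)
  }
  cm <- table(factor(true, levels = seq_len(n_classes)),
              factor(predicted, levels = seq_len(n_classes)))
  tp <- diag(cm)
  ti <- colSums(cm)                           # inferred per class
  tt <- rowSums(cm)                           # true per class
  prec_i <- ifelse(ti > 0, tp / ti, 0)
  rec_i <- ifelse(tt > 0, tp / tt, 0)
  precision <- mean(prec_i)
  recall <- mean(rec_i)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f_measure = f,
       accuracy = sum(tp) / length(true))
}
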