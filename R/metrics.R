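# Confusion-matrix metrics and ROC/AUROC.

#' Accuracy, sensitivity, specificity and Matthews correlation
#'
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}
#' When any factor of the MCC denominator is zero the MCC is reported
#' as 0 (the conventional value for a degenerate margin); SN/SP are
#' `NaN` when their own denominator is empty.
#'
#' @param tp,tn,fp,fn non-negative confusion counts, summing > 0.
#' @return named list with `TP`, `TN`, `FP`, `FN`, `ACC`, `SN`, `SP`,
#'   `MCC`.
#' @examples
#' compute_metrics(80, 70, 30, 20)$ACC  # 0.75
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  cnt <- c(tp, tn, fp, fn)
  stopifnot(length(cnt) == 4, all(cnt >= 0), all(cnt == round(cnt)))
  if (sum(cnt) == 0) stop("all confusion counts are zero")
  tp <- as.double(tp); tn <- as.double(tn)
  fp <- as.double(fp); fn <- as.double(fn)
  den <- sqrt((tp + fn) * (tn + fp) * (tp + fp) * (tn + fn))
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       ACC = (tp + tn) / (tp + tn + fp + fn),
       SN = tp / (tp + fn),
       SP = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the unique decision values (higher value =
#' more positive) and integrates TPR against FPR by the trapezoidal
#' rule. The result equals the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counting one
#' half.
#'
#' @param scores numeric decision values.
#' @param labels class labels, +1/-1 (or 1/0).
#' @return list with `points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auroc`. Constant scores give AUROC 0.5 with a
#'   warning.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- ifelse(labels == 0, -1L, as.integer(labels))
  stopifnot(length(scores) == length(labels), length(scores) >= 2,
            all(labels %in% c(-1L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == -1L)
  if (np == 0 || nn == 0) stop("both classes required for a ROC curve")
  if (length(unique(scores)) == 1) {
    warning("constant decision values; AUROC undefined, reporting 0.5")
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auroc = 0.5))
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1L); fp <- cumsum(y == -1L)
  last <- cumsum(rle(s)$lengths)       # collapse tied thresholds
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auroc = auc)
}
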