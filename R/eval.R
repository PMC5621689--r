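# Evaluation protocols: jackknife (leave-one-out), stratified k-fold,
# parameter sweeps; all report ACC/SN/SP/MCC and ROC/AUROC.

make_eval_report <- function(truth, pred, decision) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == -1 & truth == -1)
  fp <- sum(pred == 1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
  roc <- roc_auroc(decision, truth)
  structure(list(metrics = compute_metrics(tp, tn, fp, fn),
                 roc = roc$points, auroc = roc$auroc,
                 predictions = data.frame(truth = truth, pred = pred,
                                          decision = decision)),
            class = "dbp_eval")
}

#' @export
print.dbp_eval <- function(x, digits = 4, ...) {
  m <- x$metrics
  cat("<dbp_eval>\n")
  cat(sprintf("  n = %d   TP %d  TN %d  FP %d  FN %d\n",
              m$TP + m$TN + m$FP + m$FN, m$TP, m$TN, m$FP, m$FN))
  cat(sprintf("  ACC %.*f   SN %.*f   SP %.*f   MCC %.*f   AUROC %.*f\n",
              digits, m$ACC, digits, m$SN, digits, m$SP, digits, m$MCC,
              digits, x$auroc))
  invisible(x)
}

#' Plot the ROC curve of an evaluation report
#' @param x a `dbp_eval` object.
#' @param ... passed to [plot()].
#' @export
plot.dbp_eval <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Every sample serves as the test set exactly once while all the
#' others train the predictor; the confusion matrix accumulates the n
#' held-out predictions. Feature standardization always uses
#' training-fold statistics only. When `select_k` is given, feature
#' ranking and selection are, by default, re-run inside every fold on
#' the training samples alone (`selection = "within-fold"`), so the
#' held-out sample never influences which features it is judged on;
#' `selection = "whole"` ranks once on the full matrix beforehand,
#' which is optimistic but mirrors ranking-then-validating practice.
#'
#' @param x feature matrix; `y` labels (+1/-1 or 1/0).
#' @param svm an [svm_control()]. Any tuning grid is resolved once on
#'   the full data before the folds, then held fixed per fold.
#' @param select_k optional number of features to select per fold.
#' @param rfe an [rfe_control()] used when `select_k` is given.
#' @param selection `"within-fold"` (default) or `"whole"`.
#' @return a `dbp_eval` report.
#' @export
jackknife_eval <- function(x, y, svm = svm_control(), select_k = NULL,
                           rfe = rfe_control(),
                           selection = c("within-fold", "whole")) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  y <- ifelse(y == 0, -1L, as.integer(y))
  n <- nrow(x)
  stopifnot(n >= 3, length(y) == n)
  if (length(unique(y)) < 2) stop("both classes required")
  svm <- resolve_tuning(x, y, svm)
  whole_map <- NULL
  if (!is.null(select_k) && selection == "whole") {
    rk <- rank_features(x, y, control = rfe, stop_at = select_k)
    whole_map <- select_top_k(rk, select_k, x)$map$index
  }
  pred <- integer(n); dv <- numeric(n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- y[-i]
    te_x <- x[i, , drop = FALSE]
    if (!is.null(select_k)) {
      idx <- if (selection == "whole") whole_map else {
        rk <- tryCatch(
          rank_features(tr_x, tr_y, control = rfe, stop_at = select_k),
          error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
        select_top_k(rk, select_k, tr_x)$map$index
      }
      tr_x <- tr_x[, idx, drop = FALSE]
      te_x <- te_x[, idx, drop = FALSE]
    }
    fit <- tryCatch(train_svm(tr_x, tr_y, control = svm),
                    error = function(e) stop("fold ", i, ": ",
                                             conditionMessage(e)))
    pr <- predict(fit, te_x)
    pred[i] <- pr[1]
    dv[i] <- attr(pr, "decision")[1]
  }
  make_eval_report(y, pred, dv)
}

# If the control carries grids, tune once on the given data and return
# a fixed-(C, gamma) control; tractable stand-in for per-fold tuning.
resolve_tuning <- function(x, y, svm) {
  if (is.null(svm$C_grid) && is.null(svm$gamma_grid)) return(svm)
  fit <- train_svm(x, y, control = svm)
  svm_control(C = fit$C, gamma = fit$gamma, seed = svm$seed)
}

#' Stratified k-fold cross-validated evaluation
#'
#' @param x feature matrix; `y` labels.
#' @param folds number of folds (default 5).
#' @param svm an [svm_control()].
#' @param select_k,rfe,selection as in [jackknife_eval()].
#' @param seed fold-assignment seed.
#' @return a `dbp_eval` report over the pooled held-out predictions.
#' @export
cv_eval <- function(x, y, folds = 5, svm = svm_control(), select_k = NULL,
                    rfe = rfe_control(),
                    selection = c("within-fold", "whole"), seed = 1) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  y <- ifelse(y == 0, -1L, as.integer(y))
  n <- nrow(x)
  if (length(unique(y)) < 2) stop("both classes required")
  svm <- resolve_tuning(x, y, svm)
  fold <- make_folds(y, folds, seed)
  whole_map <- NULL
  if (!is.null(select_k) && selection == "whole") {
    rk <- rank_features(x, y, control = rfe, stop_at = select_k)
    whole_map <- select_top_k(rk, select_k, x)$map$index
  }
  pred <- integer(n); dv <- numeric(n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    tr_x <- x[tr, , drop = FALSE]; tr_y <- y[tr]
    te_x <- x[!tr, , drop = FALSE]
    if (!is.null(select_k)) {
      idx <- if (selection == "whole") whole_map else {
        rk <- rank_features(tr_x, tr_y, control = rfe, stop_at = select_k)
        select_top_k(rk, select_k, tr_x)$map$index
      }
      tr_x <- tr_x[, idx, drop = FALSE]
      te_x <- te_x[, idx, drop = FALSE]
    }
    fit <- train_svm(tr_x, tr_y, control = svm)
    pr <- predict(fit, te_x)
    pred[!tr] <- pr
    dv[!tr] <- attr(pr, "decision")
  }
  make_eval_report(y, pred, dv)
}

#' Five-fold accuracy sweep over an encoder parameter
#'
#' Re-encodes the dataset for every candidate value of `lg` (maximum
#' autocorrelation lag, NMBAC features only) or `m` (retained DCT
#' coefficients, PSSM-DCT features only) and scores each encoding by
#' stratified cross-validated accuracy, the protocol used to fix the
#' defaults `lg = 30` and `m = 100`.
#'
#' @param param `"lg"` or `"m"`.
#' @param grid candidate values (non-empty).
#' @param records curated protein records (for `lg`).
#' @param pssms profile list (for `m`).
#' @param labels +1/-1 labels.
#' @param folds folds (default 5); `svm` an [svm_control()]; `seed`
#'   fold seed.
#' @return data.frame `value`, `ACC`, `MCC`, `SN`, `SP` with attribute
#'   `best` (value with maximal ACC, ties to the smaller value).
#' @export
param_sweep <- function(param = c("lg", "m"), grid, records = NULL,
                        pssms = NULL, labels, folds = 5,
                        svm = svm_control(), seed = 1) {
  param <- match.arg(param)
  if (length(grid) == 0) stop("empty parameter grid")
  rows <- lapply(grid, function(v) {
    x <- if (param == "lg") {
      encode_features(records, features = "nmbac", lg = v)
    } else {
      if (is.null(records)) {
        do.call(rbind, lapply(pssms, function(p) encode_pssm_dct(p, m = v)))
      } else {
        encode_features(records, pssms, features = "dct", m = v)
      }
    }
    ev <- cv_eval(x, labels, folds = folds, svm = svm, seed = seed)
    data.frame(value = v, ACC = ev$metrics$ACC, MCC = ev$metrics$MCC,
               SN = ev$metrics$SN, SP = ev$metrics$SP)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$value[order(-out$ACC, out$value)][1]
  out
}
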