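# RBF support vector machine: training, tuning, prediction.
# The quadratic program itself is delegated to LIBSVM via e1071.
# The import also guarantees e1071's predict methods are registered
# when models come back from disk via readRDS.

#' @importFrom e1071 svm
NULL

#' Control settings for the RBF support vector machine
#'
#' @param C soft-margin cost; the upper bound on the dual
#'   coefficients.
#' @param gamma RBF kernel width `exp(-gamma * ||x - x'||^2)`; `NULL`
#'   means `1 / p` on the standardized features.
#' @param C_grid,gamma_grid optional candidate sets; when both are
#'   given (or have length > 1) [train_svm()] picks the pair with the
#'   best inner cross-validated accuracy. Conventional wide defaults
#'   are `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`.
#' @param inner_folds folds for the tuning cross-validation.
#' @param seed fold-assignment seed for tuning.
#' @export
svm_control <- function(C = 1, gamma = NULL, C_grid = NULL,
                        gamma_grid = NULL, inner_folds = 5, seed = 1) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0, inner_folds >= 2)
  structure(list(C = C, gamma = gamma, C_grid = C_grid,
                 gamma_grid = gamma_grid, inner_folds = inner_folds,
                 seed = seed), class = "svm_control")
}

# stratified fold assignment, deterministic per seed
make_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# z-score statistics on training data (population SD, so replicating
# every sample leaves the scaling — and hence the decision function —
# unchanged); zero-variance columns get unit scale so they map to a
# constant 0 rather than NaN
scale_stats <- function(x) {
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(center = mu, scale = sdv)
}

apply_scale <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train an RBF-kernel support vector machine
#'
#' Features are standardized with training-set statistics (stored in
#' the model and re-applied at prediction, so no information leaks
#' from test folds). If `control` carries candidate grids for `C` and
#' `gamma`, the pair with the highest stratified inner-CV accuracy is
#' chosen first; ties go to the smaller `C`, then smaller `gamma`.
#'
#' @param x numeric feature matrix.
#' @param y labels, +1/-1 (or 1/0).
#' @param control an [svm_control()] object.
#' @return object of class `dbp_svm`: the fitted LIBSVM model, the
#'   scaling statistics and the resolved `(C, gamma)`.
#' @export
train_svm <- function(x, y, control = svm_control()) {
  x <- as.matrix(x)
  y <- ifelse(y == 0, -1L, as.integer(y))
  if (length(unique(y)) < 2) stop("both classes required to train")
  st <- scale_stats(x)
  xs <- apply_scale(x, st)
  gamma <- if (is.null(control$gamma)) 1 / ncol(x) else control$gamma
  C <- control$C
  tuning <- NULL
  Cg <- control$C_grid; gg <- control$gamma_grid
  if (!is.null(Cg) || !is.null(gg)) {
    if (is.null(Cg)) Cg <- C
    if (is.null(gg)) gg <- gamma
    grid <- expand.grid(C = Cg, gamma = gg)
    fold <- make_folds(y, control$inner_folds, control$seed)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      ok <- 0L
      for (f in sort(unique(fold))) {
        tr <- fold != f
        fit <- e1071::svm(xs[tr, , drop = FALSE], factor(y[tr]),
                          kernel = "radial", cost = grid$C[g],
                          gamma = grid$gamma[g], scale = FALSE)
        ok <- ok + sum(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
      }
      ok / length(y)
    }, 0)
    best <- order(-acc, grid$C, grid$gamma)[1]
    C <- grid$C[best]; gamma <- grid$gamma[best]
    tuning <- cbind(grid, acc = acc)
  }
  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)), kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, stats = st, C = C, gamma = gamma,
                 tuning = tuning, p = ncol(x)),
            class = "dbp_svm")
}

#' Predict with a trained [train_svm()] model
#'
#' @param object a `dbp_svm` model.
#' @param newdata feature matrix with the training column layout.
#' @param ... unused.
#' @return integer vector of +1/-1 predictions with attribute
#'   `decision` holding the signed margins (positive = class +1).
#' @export
predict.dbp_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("model expects ", object$p, " features, got ", ncol(newdata))
  }
  xs <- apply_scale(newdata, object$stats)
  pr <- predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  # LIBSVM orients the margin toward the first factor level of the pair
  # named in the column header; flip so positive always means class +1
  if (sub("/.*$", "", colnames(attr(pr, "decision.values"))[1]) == "-1") {
    dv <- -dv
  }
  out <- as.integer(as.character(pr))
  attr(out, "decision") <- unname(dv)
  out
}

#' @export
print.dbp_svm <- function(x, ...) {
  cat(sprintf("<dbp_svm> RBF SVM: C = %g, gamma = %g, %d features, %d SVs\n",
              x$C, x$gamma, x$p, nrow(x$fit$SV)))
  invisible(x)
}

# linear-kernel fit used by the feature ranker; returns squared weights
linear_svm_weights <- function(x, y, C = 1) {
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)[1, ]
  unname(w^2)
}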