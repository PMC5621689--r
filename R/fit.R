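# The user-facing model: encode -> (optionally) select -> train.

#' Fit a DNA-binding protein classifier
#'
#' The central fitting function. Takes an encoded feature matrix (see
#' [encode_features()]) with its +1/-1 labels, optionally ranks the
#' features by SVM-RFE+CBR and keeps the best `select_k`, then trains
#' the RBF-kernel support vector machine. The returned model carries
#' the feature index map, so [predict.dbp_model()] accepts either
#' already-selected matrices or full-width matrices (projected
#' automatically).
#'
#' @param x numeric feature matrix, one row per protein.
#' @param y class labels: +1 binding, -1 non-binding (1/0 accepted).
#' @param select_k number of features to keep after ranking; `NULL`
#'   (default) disables selection and trains on all columns.
#' @param rfe an [rfe_control()] for the ranking stage.
#' @param svm an [svm_control()] for the classifier (supply grids to
#'   tune `C`/`gamma` by inner cross-validation).
#' @return object of class `dbp_model` with elements `svm` (the
#'   trained `dbp_svm`), `ranked` (`ranked_features` or `NULL`), `map`
#'   (selected-column map or `NULL`), `k`, `p_in` (input width) and
#'   `call`.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(60 * 10), 60)
#' y <- rep(c(1, -1), each = 30)
#' x[y == 1, 1] <- x[y == 1, 1] + 3
#' fit <- dbp_fit(x, y, select_k = 4)
#' predict(fit, x[1:5, ])
#' @export
dbp_fit <- function(x, y, select_k = NULL, rfe = rfe_control(),
                    svm = svm_control()) {
  x <- as.matrix(x)
  y <- ifelse(y == 0, -1L, as.integer(y))
  ranked <- NULL; map <- NULL
  xt <- x
  if (!is.null(select_k)) {
    if (select_k < 1 || select_k > ncol(x)) {
      stop("select_k = ", select_k, " out of range [1, ", ncol(x), "]")
    }
    ranked <- rank_features(x, y, control = rfe)
    sel <- select_top_k(ranked, select_k, x)
    xt <- sel$matrix
    map <- sel$map
  }
  model <- train_svm(xt, y, control = svm)
  structure(list(svm = model, ranked = ranked, map = map,
                 k = if (is.null(select_k)) ncol(x) else select_k,
                 p_in = ncol(x), block_map = attr(x, "block_map"),
                 call = match.call()),
            class = "dbp_model")
}

#' Predict binding labels with a fitted [dbp_fit()] model
#'
#' @param object a `dbp_model`.
#' @param newdata feature matrix: either the model's full input width
#'   (selected columns are projected out via the stored index map) or
#'   already reduced to the selected `k` columns.
#' @param type `"class"` for a +1/-1 vector (with a `decision`
#'   attribute), `"decision"` for the signed margins themselves.
#' @param ... unused.
#' @export
predict.dbp_model <- function(object, newdata,
                              type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$map) && ncol(newdata) == object$p_in) {
    newdata <- newdata[, object$map$index, drop = FALSE]
  } else if (ncol(newdata) != object$k) {
    stop("incompatible feature matrix: model expects ", object$p_in,
         " (full) or ", object$k, " (selected) columns, got ",
         ncol(newdata))
  }
  pr <- predict(object$svm, newdata)
  if (type == "decision") attr(pr, "decision") else pr
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("<dbp_model> DNA-binding protein classifier\n")
  cat(sprintf("  features: %d in -> %d used%s\n", x$p_in, x$k,
              if (is.null(x$map)) " (no selection)" else " (SVM-RFE+CBR)"))
  cat(sprintf("  RBF SVM: C = %g, gamma = %g\n", x$svm$C, x$svm$gamma))
  invisible(x)
}

#' @export
summary.dbp_model <- function(object, ...) {
  print(object)
  if (!is.null(object$map)) {
    cat("  selected features per block:\n")
    tab <- table(object$map$block)
    for (b in names(tab)) cat(sprintf("    %-6s %d\n", b, tab[[b]]))
  }
  cat(sprintf("  support vectors: %d\n", nrow(object$svm$fit$SV)))
  invisible(object)
}

#' Plot feature-ranking scores of a fitted model
#'
#' Shows the final squared-weight score of each feature against its
#' original index, marking the selected set; requires a model fitted
#' with `select_k`.
#' @param x a `dbp_model`; `...` passed to [plot()].
#' @export
plot.dbp_model <- function(x, ...) {
  if (is.null(x$ranked)) stop("model was fitted without feature selection")
  sc <- x$ranked$score
  plot(seq_along(sc), sc, type = "h", xlab = "feature index",
       ylab = "squared SVM weight (final round)", ...)
  graphics::points(x$map$index, sc[x$map$index], col = 2, pch = 16,
                   cex = 0.5)
  invisible(x)
}
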