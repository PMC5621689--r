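# SVM-RFE with correlation-bias reduction (CBR) and top-k selection.

#' Control settings for recursive feature elimination
#'
#' @param step_fraction fraction of surviving features eliminated per
#'   round (at least one feature is always dropped).
#' @param corr_threshold absolute Pearson correlation at or above
#'   which surviving features count as one correlated group for CBR.
#' @param cbr set `FALSE` for plain SVM-RFE without correlation
#'   protection.
#' @param inner_C cost of the linear-kernel fit that scores features.
#' @param seed reserved for optional tie shuffling; ranking is
#'   deterministic (ties break by original column index) so the seed
#'   has no effect under the defaults.
#' @export
rfe_control <- function(step_fraction = 0.1, corr_threshold = 0.9,
                        cbr = TRUE, inner_C = 1, seed = 1) {
  stopifnot(step_fraction > 0, step_fraction <= 1,
            corr_threshold > 0, corr_threshold <= 1, inner_C > 0)
  structure(list(step_fraction = step_fraction,
                 corr_threshold = corr_threshold, cbr = cbr,
                 inner_C = inner_C, seed = seed), class = "rfe_control")
}

#' Rank features by SVM recursive elimination with CBR
#'
#' Repeatedly fits a linear-kernel maximum-margin classifier on the
#' surviving (internally z-scored) features, scores every feature by
#' its squared weight, and eliminates the lowest-scoring
#' `step_fraction` of the survivors. Correlation-bias reduction
#' addresses the weight dilution that plain RFE inflicts on groups of
#' mutually correlated features (pairwise `|r| >= corr_threshold`
#' among survivors, closed transitively): each member's weight is a
#' share of the group's, so individually they look weaker than the
#' group is. Under CBR a group is scored by its strongest member and
#' can only be eliminated as a whole, and only when the entire group
#' is bottom-ranked at that score; a group whose evidence survives
#' protects all its members from elimination in that round. Features
#' eliminated later rank better; survivors at `stop_at` are ranked by
#' their final scores.
#'
#' Constant columns cannot carry class information and are ranked last
#' with a warning.
#'
#' @param x numeric feature matrix (n x p).
#' @param y labels, +1/-1 (or 1/0); both classes required.
#' @param control an [rfe_control()] object.
#' @param stop_at stop eliminating once this many features survive
#'   (default 1). Use `stop_at = k` when only the top-k set is needed:
#'   the surviving set equals the top-k prefix of a full ranking.
#' @return object of class `ranked_features`: `order` (best-first
#'   permutation of 1..p), `round` (elimination round per feature, 0
#'   for survivors), `score` (final squared weight for survivors, last
#'   pre-elimination score otherwise) and `blocks` (per-feature block
#'   tags when `x` carries a block map).
#' @export
rank_features <- function(x, y, control = rfe_control(), stop_at = 1) {
  x <- as.matrix(x)
  y <- ifelse(y == 0, -1L, as.integer(y))
  if (length(unique(y)) < 2) stop("both classes required to rank features")
  p <- ncol(x)
  stopifnot(nrow(x) >= 4, stop_at >= 1, stop_at <= p)
  score <- numeric(p); round_tag <- integer(p)
  sdv <- apply(x, 2, stats::sd)
  constant <- which(!is.finite(sdv) | sdv == 0)
  if (length(constant) > 0) {
    warning(length(constant), " constant feature column(s) ranked last")
  }
  xs <- apply_scale(x, scale_stats(x))
  surv <- setdiff(seq_len(p), constant)
  # correlation graph computed once; induced subgraphs over survivors
  # are what each round's grouping needs
  nb <- if (isTRUE(control$cbr)) {
    corr_neighbors(xs[, surv, drop = FALSE], surv, p,
                   control$corr_threshold)
  } else NULL
  stack <- integer(0)                  # eliminated, worst first
  rnd <- 0L
  while (length(surv) > stop_at) {
    rnd <- rnd + 1L
    w2 <- linear_svm_weights(xs[, surv, drop = FALSE], y, control$inner_C)
    score[surv] <- w2
    n_elim <- max(1L, floor(control$step_fraction * length(surv)))
    n_elim <- min(n_elim, length(surv) - stop_at)
    if (n_elim < 1L) break
    cand <- if (is.null(nb)) {
      surv[order(w2, surv)][seq_len(n_elim)]   # plain RFE: lowest scores
    } else {
      cbr_candidates(surv, w2, nb, n_elim)
    }
    round_tag[cand] <- rnd
    stack <- c(stack, cand[order(score[cand], cand)])
    surv <- setdiff(surv, cand)
  }
  if (length(surv) > 0) {
    w2 <- if (length(surv) > 1) {
      linear_svm_weights(xs[, surv, drop = FALSE], y, control$inner_C)
    } else 1
    score[surv] <- w2
    surv_rank <- surv[order(-w2, surv)]
  } else surv_rank <- integer(0)
  order_out <- c(surv_rank, rev(stack), constant)
  rf <- structure(list(order = order_out, round = round_tag, score = score,
                       p = p, blocks = feature_blocks(x)),
                  class = "ranked_features")
  stopifnot(length(order_out) == p, !anyDuplicated(order_out))
  rf
}

# Adjacency lists of the |r| >= thr feature graph, indexed by original
# column; computed once per ranking run.
corr_neighbors <- function(xsub, cols, p, thr) {
  # columns are z-scored already (population SD), so Pearson r is a
  # cross product
  cc <- abs(crossprod(xsub) / nrow(xsub))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  nb <- vector("list", p)
  hit <- which(cc >= thr, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    sp <- split(cols[hit[, 2]], hit[, 1])
    nb[cols[as.integer(names(sp))]] <- sp
  }
  nb
}

# CBR elimination set: connected components of the correlation graph
# induced on the survivors form the grouping; every group is scored by
# its strongest member (the group's evidence, undiluted by weight
# sharing) and whole groups are eliminated in ascending unit score
# until the round's quota is met. A partially bottom-ranked group is
# therefore never split — its low-scoring members are protected by the
# surviving evidence. If the single lowest unit alone exceeds the
# quota, its weakest members fill the quota so a round always makes
# progress.
cbr_candidates <- function(surv, w2, nb, n_elim) {
  lab <- graph_components(surv, nb)
  unit_best <- tapply(w2, lab, max)
  units <- as.integer(names(sort(unit_best)))   # ascending evidence
  cand <- integer(0)
  for (u in units) {
    members <- surv[lab == u]
    if (length(cand) + length(members) > n_elim) break
    cand <- c(cand, members)
  }
  if (length(cand) == 0) {                      # first unit overflows quota
    members <- surv[lab == units[1]]
    mw <- w2[match(members, surv)]
    cand <- members[order(mw, members)][seq_len(n_elim)]
  }
  cand
}

# connected components of the induced subgraph on `surv`; returns an
# integer label per survivor
graph_components <- function(surv, nb) {
  pos <- integer(max(surv))
  pos[surv] <- seq_along(surv)
  lab <- integer(length(surv))
  comp <- 0L
  for (s in seq_along(surv)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[surv[v]]]) {
        wp <- if (w <= length(pos)) pos[w] else 0L
        if (wp > 0L && lab[wp] == 0L) {
          lab[wp] <- comp
          queue <- c(queue, wp)
        }
      }
    }
  }
  lab
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features, %d elimination rounds\n",
              x$p, max(x$round)))
  cat("top 10:", utils::head(x$order, 10), "\n")
  invisible(x)
}

#' Per-block counts of a ranking prefix
#'
#' @param ranked a `ranked_features` object from [rank_features()].
#' @param k prefix size.
#' @return named integer vector: how many of the k best-ranked
#'   features fall in each feature block.
#' @export
block_counts <- function(ranked, k = ranked$p) {
  stopifnot(inherits(ranked, "ranked_features"), k >= 1, k <= ranked$p)
  idx <- ranked$order[seq_len(k)]
  table(factor(ranked$blocks[idx], levels = unique(ranked$blocks)))
}

#' Select the k best-ranked feature columns
#'
#' @param ranked a `ranked_features` object.
#' @param k prefix size, `1 <= k <= p`.
#' @param x the feature matrix the ranking was computed on (or any
#'   matrix with the same columns).
#' @return list with `matrix` (n x k, columns in rank order) and `map`
#'   (data.frame `rank`, `index` into the original columns, `block`).
#'   Selecting k then k' < k from the result's map equals selecting k'
#'   directly (prefix consistency).
#' @export
select_top_k <- function(ranked, k, x) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k < 1 || k > ranked$p) stop("k = ", k, " out of range [1, ",
                                  ranked$p, "]")
  idx <- ranked$order[seq_len(k)]
  list(matrix = as.matrix(x)[, idx, drop = FALSE],
       map = data.frame(rank = seq_len(k), index = idx,
                        block = ranked$blocks[idx],
                        stringsAsFactors = FALSE))
}

#' Accuracy against number of selected features
#'
#' Evaluates the classifier on growing prefixes of a ranked feature
#' list (the ranking itself is taken as given, so the curve describes
#' that one ranking; for unbiased accuracy estimates re-rank within
#' folds via [jackknife_eval()]).
#'
#' @param x feature matrix; `y` labels.
#' @param ranked a `ranked_features` object for `x`.
#' @param k_grid prefix sizes to evaluate (non-empty).
#' @param protocol `"cv"` (stratified `folds`-fold) or `"jackknife"`.
#' @param folds folds for the cv protocol.
#' @param svm an [svm_control()].
#' @param seed fold-assignment seed.
#' @return data.frame with one row per k: `k`, `ACC`, `MCC`, `SN`,
#'   `SP`; attribute `best_k` = smallest k attaining the maximum ACC.
#' @export
sweep_k <- function(x, y, ranked, k_grid, protocol = c("cv", "jackknife"),
                    folds = 5, svm = svm_control(), seed = 1) {
  protocol <- match.arg(protocol)
  if (length(k_grid) == 0) stop("empty k grid")
  rows <- lapply(k_grid, function(k) {
    sel <- select_top_k(ranked, k, x)
    ev <- if (protocol == "jackknife") {
      jackknife_eval(sel$matrix, y, svm = svm)
    } else {
      cv_eval(sel$matrix, y, folds = folds, svm = svm, seed = seed)
    }
    data.frame(k = k, ACC = ev$metrics$ACC, MCC = ev$metrics$MCC,
               SN = ev$metrics$SN, SP = ev$metrics$SP)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k") <- out$k[order(-out$ACC, out$k)][1]  # ties -> smaller k
  out
}
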