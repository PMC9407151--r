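# Performance indicators: precision / recall learning curves over
# training-instance counts, and ROC curves against annotated truth.

#' Micro- and per-class precision/recall
#'
#' Micro-averaging pools every (prediction, truth) pair, so for
#' single-label multiclass data micro-precision and micro-recall both
#' equal accuracy.  Per-class values are undefined when a class never
#' appears among predictions (precision) or truth (recall); these are
#' reported as 0 and flagged.
#'
#' @param pred,truth integer class indices.
#' @param K number of classes.
#' @return list with `precision`, `recall` (micro), `per_class`
#'   (data.frame class / precision / recall / degenerate).
#' @export
precision_recall <- function(pred, truth, K) {
  tp <- fp <- fn <- numeric(K)
  for (k in seq_len(K)) {
    tp[k] <- sum(pred == k & truth == k)
    fp[k] <- sum(pred == k & truth != k)
    fn[k] <- sum(pred != k & truth == k)
  }
  prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_k <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  degenerate <- (tp + fp == 0) | (tp + fn == 0)
  list(
    precision = sum(tp) / max(sum(tp) + sum(fp), 1),
    recall = sum(tp) / max(sum(tp) + sum(fn), 1),
    per_class = data.frame(class = seq_len(K), precision = prec_k,
                           recall = rec_k, degenerate = degenerate)
  )
}

#' Training-set learning curve over instance counts
#'
#' Draws one bootstrap ordering of the labeled pixels, then for each
#' instance count `n` in `schedule` trains a forest on the first `n`
#' bootstrap-ordered samples and records training-set precision and
#' recall (micro-averaged) on those `n` instances.  Classes not yet seen
#' at small `n` are flagged `degenerate` and contribute 0 to their
#' per-class values.
#'
#' @param stack a [build_stack()] stack.
#' @param labels a [label_set()].
#' @param schedule increasing positive instance counts; maximum may not
#'   exceed the total number of labeled pixels.
#' @param seed RNG seed (bootstrap ordering and per-count forests).
#' @param n_trees,mtry forest hyperparameters (defaults as [frf_train()]).
#' @return object of class `performance_curve` with `instances`,
#'   `precision`, `recall`, `per_class` (list of data.frames), and
#'   `degenerate` (logical: any class unseen at that count).
#' @export
learning_curve <- function(stack, labels, schedule, seed = 1L,
                           n_trees = 50L, mtry = NULL) {
  assert_that(length(schedule) >= 1, "parameter", "schedule must be non-empty")
  assert_that(all(diff(schedule) > 0) || length(schedule) == 1, "parameter",
              "schedule must be strictly increasing")
  counts <- label_counts(labels)
  n_total <- sum(counts)
  assert_that(max(schedule) <= n_total, "parameter",
              "schedule exceeds the number of labeled pixels")
  coords <- do.call(rbind, labels$coords)
  y <- rep(seq_along(labels$classes), counts)
  X <- stack_features_at(stack, coords)
  K <- length(labels$classes)
  nf <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(nf)))
  set.seed(seed)
  ord <- sample.int(n_total, n_total, replace = TRUE)  # bootstrap ordering
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(schedule))
  prec <- rec <- numeric(length(schedule))
  degenerate <- logical(length(schedule))
  per_class <- vector("list", length(schedule))
  for (si in seq_along(schedule)) {
    n <- schedule[si]
    take <- ord[seq_len(n)]
    Xi <- X[take, , drop = FALSE]
    yi <- y[take]
    classes_seen <- sort(unique(yi))
    # remap to the seen classes for tree growth, keep K-wide reporting
    ymap <- match(yi, classes_seen)
    set.seed(sub_seeds[si])
    tseeds <- sample.int(.Machine$integer.max - 1L, n_trees)
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      set.seed(tseeds[b])
      idx <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- grow_tree(Xi[idx, , drop = FALSE], ymap[idx],
                              length(classes_seen), mtry)
    }
    acc <- matrix(0, n, length(classes_seen))
    for (tr in trees) acc <- acc + tree_predict(tr, Xi)
    pred <- classes_seen[max.col(acc / n_trees, ties.method = "first")]
    pr <- precision_recall(pred, yi, K)
    prec[si] <- pr$precision
    rec[si] <- pr$recall
    degenerate[si] <- length(classes_seen) < K
    pr$per_class$degenerate <- pr$per_class$degenerate |
      !(seq_len(K) %in% classes_seen)
    per_class[[si]] <- pr$per_class
  }
  structure(list(instances = schedule, precision = prec, recall = rec,
                 per_class = per_class, degenerate = degenerate,
                 class_names = labels$classes, seed = seed),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  if (!is.null(x$instances)) {
    cat("<performance_curve> learning curve\n")
    print(data.frame(instances = x$instances, precision = x$precision,
                     recall = x$recall, degenerate = x$degenerate))
  } else {
    cat(sprintf("<performance_curve> ROC, AUC = %.4f (%d points)\n",
                x$auc, nrow(x$roc_points)))
  }
  invisible(x)
}

#' Plot a performance curve
#'
#' Learning curves plot precision and recall against the instance count;
#' ROC curves plot TPR against FPR with the chance diagonal.
#'
#' @param x a `performance_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.performance_curve <- function(x, ...) {
  if (!is.null(x$instances)) {
    graphics::plot(x$instances, x$precision, type = "b", ylim = c(0, 1),
                   xlab = "training instances", ylab = "score",
                   main = "FRF learning curve", ...)
    graphics::lines(x$instances, x$recall, type = "b", lty = 2, pch = 2)
    graphics::legend("bottomright", c("precision", "recall"),
                     lty = 1:2, pch = 1:2, bty = "n")
  } else {
    graphics::plot(x$roc_points[, "fpr"], x$roc_points[, "tpr"], type = "l",
                   xlab = "false-positive rate", ylab = "true-positive rate",
                   main = sprintf("ROC (AUC = %.3f)", x$auc),
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' ROC curve of a probability map against annotated truth
#'
#' Sweeps a threshold over the unique probability values of the positive
#' class at the annotated pixels (positives: the `positive_class` pixels;
#' negatives: every other annotated pixel), recording (FPR, TPR) points
#' anchored at (0,0) and (1,1), and integrates the AUC by the trapezoid
#' rule.
#'
#' @param prob a [prob_map()].
#' @param truth a [label_set()] covering at least one positive and one
#'   negative pixel.
#' @param positive_class class name in `truth` and `prob`.
#' @return a `performance_curve` with `roc_points` (matrix fpr/tpr) and
#'   `auc`.
#' @export
frf_roc <- function(prob, truth, positive_class) {
  stopifnot(inherits(prob, "prob_map"))
  assert_that(positive_class %in% prob$class_names, "parameter",
              sprintf("unknown class '%s'", positive_class))
  assert_that(positive_class %in% truth$classes, "evaluation",
              "truth has no annotations for the positive class")
  plane <- prob_plane(prob, positive_class)
  pos <- truth$coords[[positive_class]]
  neg <- do.call(rbind, truth$coords[setdiff(truth$classes, positive_class)])
  assert_that(!is.null(pos) && nrow(pos) >= 1, "evaluation",
              "no positive truth pixels")
  assert_that(!is.null(neg) && nrow(neg) >= 1, "evaluation",
              "no negative truth pixels")
  sc_pos <- plane[cbind(pos[, 1] + 1L, pos[, 2] + 1L)]
  sc_neg <- plane[cbind(neg[, 1] + 1L, neg[, 2] + 1L)]
  scores <- c(sc_pos, sc_neg)
  is_pos <- c(rep(TRUE, length(sc_pos)), rep(FALSE, length(sc_neg)))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(sc_pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(sc_neg >= t), 0)
  pts <- cbind(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts)
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                               utils::tail(pts[, 2], -1)) / 2)
  structure(list(roc_points = pts, auc = auc,
                 positive_class = positive_class,
                 n_pos = length(sc_pos), n_neg = length(sc_neg)),
            class = "performance_curve")
}

#' Export a performance curve as CSV
#'
#' @param curve a `performance_curve`.
#' @param path output CSV path.
#' @export
write_curve <- function(curve, path) {
  df <- if (!is.null(curve$instances)) {
    data.frame(instances = curve$instances, precision = curve$precision,
               recall = curve$recall, degenerate = curve$degenerate)
  } else {
    as.data.frame(curve$roc_points)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
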