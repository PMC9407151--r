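# The fast-random-forest pixel classifier.
#
# Hand-built CART-style trees so that the ensemble is fully transparent:
# explicit split nodes (feature index + threshold), leaves holding class
# frequency vectors, per-tree sub-seeds so the K-tree probability map is
# exactly the mean of the K single-tree maps, and deterministic lowest-
# index tie-breaks throughout.  Trees are grown to purity (minimum leaf
# size 1) on a bootstrap resample of the labeled pixels, choosing at each
# node the best Gini split among `mtry` features drawn without
# replacement.

# ---- tree internals -------------------------------------------------------

# A tree is a list of parallel vectors indexed by node id:
#   feature  : 1-based feature column, NA at leaves
#   threshold: split value (left: x < thr), NA at leaves
#   left,right: child node ids, NA at leaves
#   freq     : n_nodes x K matrix of class frequencies (rows sum to 1 at
#              leaves; NA rows at internal nodes)

# Best Gini split for one feature column. Returns list(gini, thr) or NULL.
best_split_feature <- function(v, y, K) {
  o <- order(v)
  v <- v[o]; y <- y[o]
  n <- length(v)
  cut_ok <- which(diff(v) > 0)            # split between i and i+1
  if (length(cut_ok) == 0) return(NULL)
  # cumulative class counts
  C <- matrix(0L, n, K)
  C[cbind(seq_len(n), y)] <- 1L
  C <- apply(C, 2, cumsum)
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  tot <- C[n, ]
  i <- cut_ok
  nl <- i; nr <- n - i
  Cl <- C[i, , drop = FALSE]
  Cr <- matrix(tot, length(i), K, byrow = TRUE) - Cl
  gl <- 1 - rowSums(Cl^2) / nl^2
  gr <- 1 - rowSums(Cr^2) / nr^2
  w <- (nl * gl + nr * gr) / n
  best <- which.min(w)                    # ties: smallest i => lowest thr
  list(gini = w[best], thr = (v[i[best]] + v[i[best] + 1]) / 2)
}

node_gini <- function(y, K) {
  p <- tabulate(y, K) / length(y)
  1 - sum(p^2)
}

# Grow one tree on (X, y). RNG state must be set by the caller.
grow_tree <- function(X, y, K, mtry, max_depth = Inf, min_leaf = 1L) {
  nf <- ncol(X)
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0); nodes$threshold <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$freq_row <- list()
  nodes$n <- 0L
  nodes$importance <- numeric(nf)
  n_total <- length(y)

  new_node <- function() {
    nodes$n <- nodes$n + 1L
    nodes$feature[nodes$n] <- NA_integer_
    nodes$threshold[nodes$n] <- NA_real_
    nodes$left[nodes$n] <- NA_integer_
    nodes$right[nodes$n] <- NA_integer_
    nodes$n
  }

  build <- function(idx, depth) {
    id <- new_node()
    yi <- y[idx]
    g <- node_gini(yi, K)
    if (g == 0 || length(idx) <= min_leaf || depth >= max_depth) {
      nodes$freq_row[id] <- list(tabulate(yi, K) / length(yi))
      return(id)
    }
    cand <- sort(sample.int(nf, min(mtry, nf)))
    split <- NULL
    for (f in cand) {                     # ascending: lowest-index tie-break
      s <- best_split_feature(X[idx, f], yi, K)
      if (!is.null(s) && (is.null(split) || s$gini < split$gini - 1e-12)) {
        split <- c(s, feature = f)
      }
    }
    if (is.null(split) && mtry < nf) {
      # sampled features were all constant on this node; fall back to the
      # full feature set so separable data still reaches purity
      for (f in seq_len(nf)) {
        s <- best_split_feature(X[idx, f], yi, K)
        if (!is.null(s) && (is.null(split) || s$gini < split$gini - 1e-12)) {
          split <- c(s, feature = f)
        }
      }
    }
    if (is.null(split)) {                 # duplicate rows, mixed labels
      nodes$freq_row[id] <- list(tabulate(yi, K) / length(yi))
      return(id)
    }
    nodes$feature[id] <- split$feature
    nodes$threshold[id] <- split$thr
    nodes$importance[split$feature] <- nodes$importance[split$feature] +
      length(idx) / n_total * (g - split$gini)
    go_left <- X[idx, split$feature] < split$thr
    nodes$left[id] <- build(idx[go_left], depth + 1L)
    nodes$right[id] <- build(idx[!go_left], depth + 1L)
    id
  }

  build(seq_along(y), 0L)
  freq <- matrix(NA_real_, nodes$n, K)
  for (i in seq_len(length(nodes$freq_row))) {
    if (!is.null(nodes$freq_row[[i]])) freq[i, ] <- nodes$freq_row[[i]]
  }
  list(feature = nodes$feature, threshold = nodes$threshold,
       left = nodes$left, right = nodes$right, freq = freq,
       importance = nodes$importance)
}

# Vectorized traversal: class-frequency matrix (nrow(X) x K) for one tree.
tree_predict <- function(tree, X) {
  K <- ncol(tree$freq)
  out <- matrix(0, nrow(X), K)
  recurse <- function(id, rows) {
    if (length(rows) == 0) return(invisible(NULL))
    f <- tree$feature[id]
    if (is.na(f)) {
      out[rows, ] <<- matrix(tree$freq[id, ], length(rows), K, byrow = TRUE)
      return(invisible(NULL))
    }
    go_left <- X[rows, f] < tree$threshold[id]
    recurse(tree$left[id], rows[go_left])
    recurse(tree$right[id], rows[!go_left])
  }
  recurse(1L, seq_len(nrow(X)))
  out
}

# ---- the fitting function -------------------------------------------------

#' Train the fast-random-forest pixel classifier
#'
#' Fits an ensemble of Gini decision trees to the feature vectors of the
#' annotated pixels.  Each tree is grown on a bootstrap resample of the
#' labeled pixels (trees to purity, minimum leaf size 1); at every node
#' `mtry` features are drawn uniformly without replacement and the best
#' Gini-impurity split among them is taken, ties broken toward the lowest
#' feature index and the lowest threshold.  The fit is deterministic for a
#' fixed `seed`: per-tree sub-seeds are drawn up front, so the same seed
#' always yields the same forest and the K-tree probability map equals the
#' mean of the K single-tree maps trained with those sub-seeds.
#'
#' @param stack a [build_stack()] feature stack.
#' @param labels a [label_set()] with at least two non-empty classes.
#' @param n_trees number of trees (default 200).
#' @param mtry features drawn per node; default `floor(sqrt(n_features))`.
#' @param seed integer RNG seed.
#' @param max_depth maximum tree depth (`Inf` = grow to purity).
#' @param bootstrap resample the training pixels per tree (default `TRUE`);
#'   `FALSE` grows every tree on the exact label set (useful with
#'   `n_trees = 1` for auditing splits).
#' @param tree_seeds optional integer vector of per-tree sub-seeds
#'   (length `n_trees`), overriding the seed-derived ones.
#' @return an object of class `frf`: list with `trees`, `n_trees`, `mtry`,
#'   `seed`, `tree_seeds`, `class_names`, `feature_names`, `importance`,
#'   and the training accuracy on the labeled pixels.
#' @seealso [predict.frf()], [learning_curve()], [frf_roc()]
#' @export
frf_train <- function(stack, labels, n_trees = 200L, mtry = NULL,
                      seed = 1L, max_depth = Inf, bootstrap = TRUE,
                      tree_seeds = NULL) {
  stopifnot(inherits(stack, "feature_stack"))
  counts <- label_counts(labels)
  assert_that(length(counts) >= 2, "training",
              "training needs at least two annotated classes")
  assert_that(all(counts >= 1), "training",
              sprintf("class '%s' has no labeled pixels",
                      labels$classes[which(counts < 1)[1]]))
  coords <- do.call(rbind, labels$coords)
  y <- rep(seq_along(labels$classes), counts)
  X <- stack_features_at(stack, coords)
  K <- length(labels$classes)
  nf <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(nf)))
  assert_that(mtry >= 1 && mtry <= nf, "parameter",
              "mtry must be between 1 and n_features")
  if (is.null(tree_seeds)) {
    set.seed(seed)
    tree_seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  }
  assert_that(length(tree_seeds) == n_trees, "parameter",
              "tree_seeds must have length n_trees")
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    set.seed(tree_seeds[b])
    idx <- if (bootstrap) sample.int(length(y), length(y), replace = TRUE)
           else seq_along(y)
    trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y[idx], K, mtry,
                            max_depth = max_depth)
  }
  importance <- Reduce(`+`, lapply(trees, `[[`, "importance")) / n_trees
  names(importance) <- stack$feature_names
  model <- structure(list(
    trees = trees, n_trees = n_trees, mtry = mtry, seed = seed,
    tree_seeds = tree_seeds, class_names = labels$classes,
    feature_names = stack$feature_names, importance = importance,
    call = match.call()
  ), class = "frf")
  pr <- predict_matrix(model, X)
  model$training_accuracy <- mean(max.col(pr, ties.method = "first") == y)
  model
}

# Ensemble-averaged class probabilities for a plain feature matrix.
predict_matrix <- function(model, X) {
  assert_that(ncol(X) == length(model$feature_names), "incompatible",
              sprintf("stack has %d features but model expects %d",
                      ncol(X), length(model$feature_names)))
  K <- length(model$class_names)
  acc <- matrix(0, nrow(X), K)
  for (tree in model$trees) acc <- acc + tree_predict(tree, X)
  acc / model$n_trees
}

#' Per-class probability map container
#'
#' @param planes array `height x width x n_classes` with values in
#'   `[0, 1]`; per-pixel class probabilities must sum to 1 (tolerance
#'   `1e-6`) unless `normalize = FALSE`.
#' @param class_names character vector naming the planes.
#' @param normalize check the sum-to-one invariant (default `TRUE`).
#' @return object of class `prob_map`.
#' @export
prob_map <- function(planes, class_names, normalize = TRUE) {
  assert_that(length(dim(planes)) == 3 &&
                dim(planes)[3] == length(class_names), "format",
              "planes must be height x width x n_classes")
  assert_that(all(planes >= -1e-9 & planes <= 1 + 1e-9), "format",
              "probabilities must lie in [0, 1]")
  if (normalize) {
    s <- apply(planes, c(1, 2), sum)
    assert_that(max(abs(s - 1)) < 1e-6, "format",
                "per-pixel class probabilities must sum to 1")
  }
  structure(list(planes = planes, class_names = class_names),
            class = "prob_map")
}

#' Extract one class plane of a probability map as a matrix
#' @param prob a [prob_map()].
#' @param k class index or name.
#' @export
prob_plane <- function(prob, k) {
  if (is.character(k)) {
    assert_that(k %in% prob$class_names, "parameter",
                sprintf("unknown class '%s'", k))
    k <- match(k, prob$class_names)
  }
  d <- dim(prob$planes)
  matrix(prob$planes[, , k], d[1], d[2])
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %d x %d px, classes: %s\n",
              dim(x$planes)[1], dim(x$planes)[2],
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Predict class and probability maps for a feature stack
#'
#' Per-pixel class probabilities are the mean of the leaf class-frequency
#' vectors across all trees; the class map is the per-pixel argmax with
#' ties broken toward the lowest class index.
#'
#' @param object an [frf_train()] model.
#' @param stack a [build_stack()] stack with the model's features.
#' @param type `"both"` (default), `"prob"`, or `"class"`.
#' @param coords optional 0-based (row, col) matrix; when given, returns
#'   the probability matrix (and class vector) for just those pixels.
#' @param ... unused.
#' @return for full-image calls, a list with `prob` (a [prob_map()]) and/or
#'   `class_map` (integer matrix of class indices, named by
#'   `class_names`); for `coords` calls, a list with `prob` (matrix) and
#'   `class` (integer vector).
#' @export
predict.frf <- function(object, stack, type = c("both", "prob", "class"),
                        coords = NULL, ...) {
  type <- match.arg(type)
  stopifnot(inherits(stack, "feature_stack"))
  if (!is.null(coords)) {
    pr <- predict_matrix(object, stack_features_at(stack, coords))
    colnames(pr) <- object$class_names
    return(list(prob = pr, class = max.col(pr, ties.method = "first")))
  }
  npx <- prod(stack$dims)
  flat <- matrix(stack$planes, npx, n_features(stack))
  pr <- predict_matrix(object, flat)
  K <- length(object$class_names)
  planes <- array(pr, c(stack$dims, K))
  out <- list()
  if (type != "class") {
    out$prob <- prob_map(planes, object$class_names)
  }
  if (type != "prob") {
    cm <- matrix(max.col(pr, ties.method = "first"),
                 stack$dims[1], stack$dims[2])
    attr(cm, "class_names") <- object$class_names
    out$class_map <- cm
  }
  out
}

# ---- standard model methods ----------------------------------------------

#' @export
print.frf <- function(x, ...) {
  cat(sprintf("Fast-random-forest pixel classifier (%d trees, mtry = %d, seed = %d)\n",
              x$n_trees, x$mtry, x$seed))
  cat(sprintf("  classes:  %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  features: %d\n", length(x$feature_names)))
  cat(sprintf("  training accuracy: %.4f\n", x$training_accuracy))
  invisible(x)
}

#' @export
summary.frf <- function(object, ...) {
  depths <- vapply(object$trees, function(tr) {
    d <- integer(length(tr$feature)); d[1] <- 1L
    for (i in seq_along(tr$feature)) {
      if (!is.na(tr$left[i])) {
        d[tr$left[i]] <- d[i] + 1L
        d[tr$right[i]] <- d[i] + 1L
      }
    }
    max(d)
  }, 0L)
  n_leaves <- vapply(object$trees,
                     function(tr) sum(is.na(tr$feature)), 0L)
  structure(list(model = object, depths = depths, n_leaves = n_leaves,
                 top_features = sort(object$importance, decreasing = TRUE)),
            class = "summary.frf")
}

#' @export
print.summary.frf <- function(x, ...) {
  print(x$model)
  cat(sprintf("  tree depth: median %g (range %d-%d); leaves: median %g\n",
              stats::median(x$depths), min(x$depths), max(x$depths),
              stats::median(x$n_leaves)))
  cat("  top features by Gini importance:\n")
  tf <- utils::head(x$top_features, 5)
  for (i in seq_along(tf)) {
    cat(sprintf("    %-28s %.5f\n", names(tf)[i], tf[i]))
  }
  invisible(x)
}

#' Plot Gini feature importance of a trained forest
#'
#' @param x an `frf` model.
#' @param n_top number of features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.frf <- function(x, n_top = 20, ...) {
  imp <- sort(x$importance, decreasing = TRUE)
  imp <- utils::head(imp, n_top)
  op <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp), horiz = TRUE, las = 1,
                    xlab = "mean Gini importance",
                    main = "FRF feature importance",
                    cex.names = 0.7, ...)
  invisible(imp)
}

# ---- JSON model serialization --------------------------------------------

#' Serialize a trained forest to JSON
#'
#' Writes trees (features, thresholds, children, leaf frequencies),
#' hyperparameters, seeds and the class table; [read_frf()] restores a
#' model whose predictions are identical.
#'
#' @param model an `frf` model.
#' @param path output JSON path.
#' @export
write_frf <- function(model, path) {
  payload <- list(
    n_trees = model$n_trees, mtry = model$mtry, seed = model$seed,
    tree_seeds = model$tree_seeds, class_names = model$class_names,
    feature_names = model$feature_names,
    importance = unname(model$importance),
    training_accuracy = model$training_accuracy,
    trees = lapply(model$trees, function(tr) {
      fr <- as.vector(t(tr$freq))
      fr[is.na(fr)] <- -1          # internal nodes; restored as NA on read
      list(feature = tr$feature, threshold = tr$threshold,
           left = tr$left, right = tr$right,
           n_nodes = length(tr$feature), freq_flat = fr)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Restore a forest written by [write_frf()]
#' @param path JSON path.
#' @return an `frf` model.
#' @export
read_frf <- function(path) {
  assert_that(file.exists(path), "io", sprintf("file not found: %s", path))
  p <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  K <- length(unlist(p$class_names))
  as_int_na <- function(v) {
    v <- vapply(v, function(e) if (is.null(e)) NA_integer_ else as.integer(e),
                0L)
    v
  }
  as_num_na <- function(v) {
    vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e), 0)
  }
  trees <- lapply(p$trees, function(tr) {
    fr <- as_num_na(tr$freq_flat)
    fr[fr < 0] <- NA_real_
    list(feature = as_int_na(tr$feature),
         threshold = as_num_na(tr$threshold),
         left = as_int_na(tr$left),
         right = as_int_na(tr$right),
         freq = matrix(fr, nrow = as.integer(tr$n_nodes), ncol = K,
                       byrow = TRUE),
         importance = numeric(length(p$feature_names)))
  })
  structure(list(
    trees = trees, n_trees = p$n_trees, mtry = p$mtry, seed = p$seed,
    tree_seeds = as.integer(unlist(p$tree_seeds)),
    class_names = unlist(p$class_names),
    feature_names = unlist(p$feature_names),
    importance = stats::setNames(as.numeric(unlist(p$importance)),
                                 unlist(p$feature_names)),
    training_accuracy = p$training_accuracy,
    call = NULL
  ), class = "frf")
}
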