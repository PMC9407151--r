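# The forest: split choice against the enumeration oracle, ensemble
# averaging, determinism, memorization, separable-fixture performance,
# and serialization.

test_that("single-tree split equals exhaustive enumeration on tiny instances", {
  # several randomized tiny instances: <= 10 samples, <= 3 features
  for (seed in 1:8) {
    set.seed(seed + 100)
    n <- sample(4:10, 1)
    nf <- sample(2:3, 1)
    X <- matrix(round(runif(n * nf), 2), n, nf)
    y <- sample(1:2, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 3 - y[1]
    planes <- lapply(seq_len(nf), function(f) {
      m <- matrix(0, 1, n); m[1, ] <- X[, f]; m
    })
    names(planes) <- paste0("f", seq_len(nf))
    st <- make_stack(planes)
    labels <- label_set(list(C1 = cbind(0L, which(y == 1) - 1L),
                             C2 = cbind(0L, which(y == 2) - 1L)),
                        dims = c(1, n))
    # frf_train concatenates class-1 then class-2 coords; rebuild X, y in
    # that order for the oracle
    ord <- c(which(y == 1), which(y == 2))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
    model <- frf_train(st, labels, n_trees = 1, mtry = nf, seed = 1,
                       max_depth = 1, bootstrap = FALSE)
    tree <- model$trees[[1]]
    oracle <- exhaustive_best_split(X, y, 2)
    if (is.null(oracle)) {
      expect_true(is.na(tree$feature[1]))
    } else {
      expect_identical(tree$feature[1], oracle$feature)
      expect_equal(tree$threshold[1], oracle$thr)
    }
  }
})

test_that("6-sample 2-feature split is reproduced exactly", {
  X <- cbind(f1 = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
             f2 = c(0.5, 0.1, 0.9, 0.4, 0.2, 0.6))
  y <- c(1L, 1L, 1L, 2L, 2L, 2L)
  st <- make_stack(list(f1 = matrix(X[, 1], 1), f2 = matrix(X[, 2], 1)))
  labels <- label_set(list(A = cbind(0L, 0:2), B = cbind(0L, 3:5)),
                      dims = c(1, 6))
  model <- frf_train(st, labels, n_trees = 1, mtry = 2, seed = 1,
                     max_depth = 1, bootstrap = FALSE)
  oracle <- exhaustive_best_split(X, y, 2)
  expect_identical(model$trees[[1]]$feature[1], oracle$feature)
  expect_equal(model$trees[[1]]$threshold[1], oracle$thr)
  expect_identical(oracle$feature, 1L)           # f1 separates perfectly
  expect_equal(oracle$thr, 0.5)
})

test_that("training on a separable two-region fixture reaches precision 1", {
  img <- separable_image()
  labels <- separable_labels()
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 4))
  model <- frf_train(st, labels, n_trees = 20, seed = 5)
  pred <- predict(model, st, coords = do.call(rbind, labels$coords))
  truth <- rep(1:2, each = 50)
  pr <- precision_recall(pred$class, truth, 2)
  expect_identical(pr$precision, 1)
  expect_identical(pr$recall, 1)
  expect_true(all(pr$per_class$precision == 1))
})

test_that("a model memorizes single labeled pixels per class", {
  set.seed(61)
  img <- gray_image(matrix(runif(100), 10, 10))
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  labels <- label_set(list(A = cbind(2L, 3L), B = cbind(7L, 8L)),
                      dims = c(10, 10))
  model <- frf_train(st, labels, n_trees = 5, seed = 2)
  pred <- predict(model, st, coords = rbind(c(2, 3), c(7, 8)))
  expect_identical(pred$class, c(1L, 2L))
})

test_that("K-tree probabilities equal the mean of per-tree sub-seed maps", {
  img <- separable_image(20, 20)
  labels <- separable_labels(20, 20, n = 15)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  m3 <- frf_train(st, labels, n_trees = 3, seed = 9)
  p3 <- predict(m3, st)$prob$planes
  singles <- lapply(m3$tree_seeds, function(ts) {
    m1 <- frf_train(st, labels, n_trees = 1, seed = 9, tree_seeds = ts)
    predict(m1, st)$prob$planes
  })
  avg <- (singles[[1]] + singles[[2]] + singles[[3]]) / 3
  expect_equal(p3, avg, tolerance = 1e-12)
  # 1-tree maps contain only leaf frequencies; pure leaves give 0/1
  expect_true(all(singles[[1]] %in% c(0, 1) |
                    (singles[[1]] > 0 & singles[[1]] < 1)))
})

test_that("probabilities conserve mass and ties break to the lowest class", {
  img <- separable_image(20, 20)
  labels <- separable_labels(20, 20, n = 15)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  model <- frf_train(st, labels, n_trees = 10, seed = 3)
  pred <- predict(model, st)
  sums <- apply(pred$prob$planes, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  # argmax ties -> lowest index (max.col ties.method = "first")
  pm <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  expect_identical(max.col(pm, ties.method = "first"), c(1L, 2L))
  expect_identical(sort(unique(as.vector(pred$class_map))),
                   seq_along(model$class_names)[
                     seq_along(unique(as.vector(pred$class_map)))])
})

test_that("the fit is deterministic for a fixed seed", {
  img <- separable_image(20, 20)
  labels <- separable_labels(20, 20, n = 12)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  m1 <- frf_train(st, labels, n_trees = 8, seed = 17)
  m2 <- frf_train(st, labels, n_trees = 8, seed = 17)
  expect_identical(m1$trees, m2$trees)
  expect_identical(predict(m1, st)$prob$planes,
                   predict(m2, st)$prob$planes)
  m3 <- frf_train(st, labels, n_trees = 8, seed = 18)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("training contracts: class counts and stack compatibility", {
  img <- separable_image(20, 20)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  one <- label_set(list(A = cbind(1L, 1L)), dims = c(20, 20))
  expect_error(frf_train(st, one), class = "frfseg_training_error")
  labels <- separable_labels(20, 20, n = 10)
  model <- frf_train(st, labels, n_trees = 3, seed = 1)
  other <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                          sigma_min = 1, sigma_max = 4))
  expect_error(predict(model, other), class = "frfseg_incompatible_error")
})

test_that("JSON serialization round-trips predictions exactly", {
  img <- separable_image(16, 16)
  labels <- separable_labels(16, 16, n = 10)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  model <- frf_train(st, labels, n_trees = 4, seed = 23)
  tf <- tempfile(fileext = ".json")
  write_frf(model, tf)
  back <- read_frf(tf)
  expect_identical(back$class_names, model$class_names)
  expect_equal(predict(back, st)$prob$planes,
               predict(model, st)$prob$planes, tolerance = 1e-12)
  # leaf frequency vectors sum to 1
  for (tr in back$trees) {
    leaf <- is.na(tr$feature)
    expect_equal(rowSums(tr$freq[leaf, , drop = FALSE]),
                 rep(1, sum(leaf)))
  }
})

test_that("an independent forest implementation agrees on separable data", {
  skip_if_not_installed("ranger")
  img <- separable_image()
  labels <- separable_labels()
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 4))
  X <- stack_features_at(st, do.call(rbind, labels$coords))
  y <- factor(rep(c("dark", "bright"), each = 50))
  model <- frf_train(st, labels, n_trees = 20, seed = 5)
  rf <- ranger::ranger(y = y, x = as.data.frame(X), num.trees = 20,
                       seed = 5)
  ours <- model$class_names[
    predict(model, st, coords = do.call(rbind, labels$coords))$class]
  theirs <- as.character(predict(rf, as.data.frame(X))$predictions)
  expect_identical(ours, theirs)
  expect_identical(mean(ours == as.character(y)), 1)
})
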