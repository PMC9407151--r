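# Performance indicators: ROC against hand-enumerated and independent
# oracles, and the learning curve over bootstrap-ordered instances.

make_prob <- function(plane_pos) {
  planes <- array(c(plane_pos, 1 - plane_pos),
                  c(nrow(plane_pos), ncol(plane_pos), 2))
  prob_map(planes, c("pos", "neg"))
}

test_that("a perfectly separated 4-pixel case gives the ideal ROC", {
  plane <- matrix(c(0.9, 0.8, 0.4, 0.1), 1, 4)
  prob <- make_prob(plane)
  truth <- label_set(list(pos = cbind(0L, 0:1), neg = cbind(0L, 2:3)),
                     dims = c(1, 4))
  roc <- frf_roc(prob, truth, "pos")
  expect_equal(roc$auc, 1)
  expect_true(any(roc$roc_points[, "fpr"] == 0 &
                    roc$roc_points[, "tpr"] == 1))   # passes through (0,1)
  expect_equal(roc$auc, brute_auc(c(0.9, 0.8), c(0.4, 0.1)))
  # contract: starts at (0,0), ends at (1,1), both coords non-decreasing
  expect_equal(unname(roc$roc_points[1, ]), c(0, 0))
  expect_equal(unname(roc$roc_points[nrow(roc$roc_points), ]), c(1, 1))
  expect_true(all(diff(roc$roc_points[, "fpr"]) >= 0))
  expect_true(all(diff(roc$roc_points[, "tpr"]) >= 0))
})

test_that("uninformative probabilities give AUC 1/2", {
  plane <- matrix(0.5, 2, 4)
  prob <- make_prob(plane)
  truth <- label_set(list(pos = cbind(0L, 0:3), neg = cbind(1L, 0:3)),
                     dims = c(2, 4))
  roc <- frf_roc(prob, truth, "pos")
  expect_equal(roc$auc, 0.5)
})

test_that("AUC matches the rank-statistic oracle and pROC on random scores", {
  set.seed(71)
  n <- 30
  plane <- matrix(runif(2 * n), 2, n)
  prob <- make_prob(plane)
  truth <- label_set(list(pos = cbind(0L, seq_len(n) - 1L),
                          neg = cbind(1L, seq_len(n) - 1L)),
                     dims = c(2, n))
  roc <- frf_roc(prob, truth, "pos")
  expect_equal(roc$auc, brute_auc(plane[1, ], plane[2, ]), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(
    response = rep(c(1, 0), each = n),
    predictor = c(plane[1, ], plane[2, ]),
    direction = "<", quiet = TRUE))           # fixed orientation, no auto-flip
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("one-sided truth is rejected", {
  prob <- make_prob(matrix(0.7, 1, 4))
  only_pos <- label_set(list(pos = cbind(0L, 0:3)), dims = c(1, 4))
  expect_error(frf_roc(prob, only_pos, "pos"),
               class = "frfseg_evaluation_error")
  expect_error(frf_roc(prob, only_pos, "nope"),
               class = "frfseg_parameter_error")
})

test_that("the learning curve reaches and holds precision 1 on separable data", {
  img <- separable_image()
  labels <- separable_labels()
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 4))
  sched <- c(5, 10, 20, 40, 80, 100)
  curve <- learning_curve(st, labels, sched, seed = 3, n_trees = 20)
  expect_s3_class(curve, "performance_curve")
  expect_identical(curve$instances, sched)
  expect_true(all(curve$precision >= 0 & curve$precision <= 1))
  reach <- which(curve$precision == 1)
  expect_gt(length(reach), 0)
  expect_true(all(curve$precision[min(reach):length(sched)] == 1))
  # final point: training precision of a full-size forest is also 1
  model <- frf_train(st, labels, n_trees = 20, seed = 3)
  pred <- predict(model, st, coords = do.call(rbind, labels$coords))
  pr <- precision_recall(pred$class, rep(1:2, each = 50), 2)
  expect_identical(pr$precision, curve$precision[length(sched)])
})

test_that("degenerate single-instance schedules are flagged", {
  img <- separable_image(20, 20)
  labels <- separable_labels(20, 20, n = 10)
  st <- build_stack(img, filter_config(enabled_filters = "gaussian",
                                       sigma_min = 1, sigma_max = 2))
  curve <- learning_curve(st, labels, 1L, seed = 2, n_trees = 3)
  expect_true(curve$degenerate[1])
  pc <- curve$per_class[[1]]
  seen <- which(!pc$degenerate)
  expect_length(seen, 1)                       # only one class visible
  expect_identical(pc$precision[seen], 1)      # and it is predicted perfectly
  expect_identical(pc$precision[pc$degenerate],
                   rep(0, sum(pc$degenerate)))
  expect_error(learning_curve(st, labels, integer(0)),
               class = "frfseg_parameter_error")
  expect_error(learning_curve(st, labels, 10^6),
               class = "frfseg_parameter_error")
})

test_that("micro precision/recall pool pairs; per-class flags degeneracy", {
  pr <- precision_recall(c(1, 1, 2, 2), c(1, 2, 2, 2), K = 2)
  expect_equal(pr$precision, 3 / 4)
  expect_equal(pr$recall, 3 / 4)
  expect_equal(pr$per_class$precision, c(1 / 2, 1))
  expect_equal(pr$per_class$recall, c(1, 2 / 3))
  pr2 <- precision_recall(c(1, 1), c(1, 1), K = 2)
  expect_true(pr2$per_class$degenerate[2])
  expect_identical(pr2$per_class$precision[2], 0)
})

test_that("curves export to CSV", {
  prob <- make_prob(matrix(c(0.9, 0.1), 1, 2))
  truth <- label_set(list(pos = cbind(0L, 0L), neg = cbind(0L, 1L)),
                     dims = c(1, 2))
  roc <- frf_roc(prob, truth, "pos")
  tf <- tempfile(fileext = ".csv")
  write_curve(roc, tf)
  back <- read.csv(tf)
  expect_identical(names(back), c("fpr", "tpr"))
})
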