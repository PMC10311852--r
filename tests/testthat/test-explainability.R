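## toy feature data with one decisive column among noise
toy_data <- function(n = 120, p = 6, seed = 8) {
  set.seed(seed)
  X <- matrix(round(runif(n * p, 0, 10), 2), n, p,
              dimnames = list(NULL, c("PATH0", sprintf("nod1_t%d", 1:(p - 1)))))
  y <- as.integer(X[, "PATH0"] > 5)
  list(X = X, y = y)
}

test_that("importances are normalized, zero for constants, top for the signal", {
  td <- toy_data()
  X <- cbind(td$X, rel1_TREATS = 0)  # constant feature
  m <- mk_forest_model(X, td$y)
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_equal(imp$feature[1], "PATH0")
  expect_equal(imp$importance[imp$feature == "rel1_TREATS"], 0)
  expect_error(feature_importance(list()), "fitted blgpa model")
})

test_that("a single-split forest distills to a depth-1 surrogate with fidelity 1", {
  td <- toy_data(n = 200, seed = 12)
  ## forest on the decisive feature only: its prediction IS a single split
  m <- mk_forest_model(td$X[, "PATH0", drop = FALSE], td$y, ntree = 100)
  sur <- fit_surrogate(m, grid = list(maxdepth = c(1, 2), minbucket = c(1, 5)),
                       cv_folds = 3, seed = 1)
  expect_equal(sur$fidelity$accuracy, 1.0)
  expect_equal(sur$depth, 1L)
})

test_that("an unrestricted surrogate memorizes the forest on its training set", {
  td <- toy_data(n = 150, seed = 13)
  m <- mk_forest_model(td$X, td$y)
  sur <- fit_surrogate(m, grid = list(maxdepth = 30, minbucket = 1),
                       cv_folds = 0)
  expect_equal(sur$fidelity$accuracy, 1.0)
  expect_equal(sur$fidelity$f1, 1.0)
})

test_that("post-pruning respects the floor and its degenerate limits", {
  td <- toy_data(n = 150, seed = 14)
  m <- mk_forest_model(td$X, td$y)
  sur <- fit_surrogate(m, grid = list(maxdepth = 30, minbucket = 1),
                       cv_folds = 0)

  ## floor 0: collapses to the majority leaf
  p0 <- post_prune(sur, fidelity_floor = 0)
  expect_equal(p0$depth, 0L)
  expect_equal(p0$n_leaves, 1L)

  ## floor 1 on a memorizing tree evaluated on its training set: unchanged
  p1 <- post_prune(sur, fidelity_floor = 1.0)
  expect_identical(p1$tree, sur$tree)
  expect_equal(p1$fidelity$accuracy, 1.0)

  ## unattainable floor on held-out-like data: unpruned tree, flagged
  sur_low <- sur
  sur_low$training$target <- 1L - sur$training$target  # adversarial targets
  p_bad <- post_prune(sur_low, fidelity_floor = 0.99)
  expect_true(p_bad$floor_unmet)
  expect_identical(p_bad$tree, sur$tree)
})

test_that("pruning never increases depth or fidelity across random runs", {
  for (s in 1:20) {
    td <- toy_data(n = 80, p = 4, seed = 300 + s)
    m <- mk_forest_model(td$X, td$y, ntree = 25, seed = s)
    sur <- fit_surrogate(m, grid = list(maxdepth = 30, minbucket = 1),
                         cv_folds = 0)
    floor <- sample(c(0.7, 0.8, 0.9), 1)
    pruned <- post_prune(sur, fidelity_floor = floor)
    expect_lte(pruned$depth, sur$depth)
    expect_lte(pruned$fidelity$accuracy, sur$fidelity$accuracy)
    expect_gte(pruned$fidelity$accuracy, floor)
  }
})

test_that("a degenerate forest target is rejected", {
  td <- toy_data(n = 100, seed = 15)
  m <- mk_forest_model(td$X, td$y)
  high <- td$X[td$X[, "PATH0"] > 7, , drop = FALSE]  # forest says 1 everywhere
  expect_error(fit_surrogate(m, x = high, grid = list(maxdepth = 3,
                                                      minbucket = 1),
                             cv_folds = 0), "single class")
})

## hand-built two-split tree matching the published example rule
rule_tree <- function() {
  leaf <- function(cls, n0, n1)
    list(leaf = TRUE, class = cls, counts = c(`0` = n0, `1` = n1))
  list(leaf = FALSE, feature = "rel1_TREATS", threshold = 49.5,
       class = 0L, counts = c(`0` = 1200, `1` = 900),
       left = leaf(0L, 1100, 59),
       right = list(leaf = FALSE, feature = "PATH2", threshold = 8.5,
                    class = 1L, counts = c(`0` = 100, `1` = 841),
                    left = leaf(0L, 59, 41),
                    right = leaf(1L, 41, 800)))
}

rule_surrogate <- function() {
  X <- matrix(c(100, 10, 10, 3, 60, 2), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("rel1_TREATS", "PATH2")))
  blgpa:::new_surrogate(rule_tree(), colnames(X), X,
                        blgpa:::predict_tree(rule_tree(), X))
}

test_that("traced rules render in the published two-condition format", {
  sur <- rule_surrogate()
  r <- trace_decision(sur, c(rel1_TREATS = 3143, PATH2 = 5333))
  expect_equal(format(r),
               "IF rel1_TREATS > 49.5 AND PATH2 > 8.5 THEN Interaction (800/841)")
  expect_equal(r$class, 1L)
  expect_equal(r$majority, 800)
  expect_equal(r$total, 841)

  ## left branches render with the <= comparator
  r2 <- trace_decision(sur, c(rel1_TREATS = 10, PATH2 = 0))
  expect_equal(r2$conditions$comparator, "\u2264")
  expect_equal(format(r2),
               "IF rel1_TREATS \u2264 49.5 THEN No interaction (1100/1159)")

  ## two vectors landing in the same leaf yield identical rules
  r3 <- trace_decision(sur, c(rel1_TREATS = 60, PATH2 = 9))
  r4 <- trace_decision(sur, c(rel1_TREATS = 999, PATH2 = 99))
  expect_identical(r3, r4)

  expect_error(trace_decision(sur, c(wrong = 1)), "layout")
})

test_that("traced rules agree with the tree's own prediction", {
  td <- toy_data(n = 100, seed = 16)
  m <- mk_forest_model(td$X, td$y)
  sur <- fit_surrogate(m, grid = list(maxdepth = 6, minbucket = 2),
                       cv_folds = 0)
  set.seed(17)
  Xr <- matrix(runif(200 * ncol(td$X), 0, 10), 200, ncol(td$X),
               dimnames = list(NULL, colnames(td$X)))
  pred <- blgpa:::predict_tree(sur$tree, Xr)
  for (i in seq_len(nrow(Xr)))
    expect_equal(trace_decision(sur, Xr[i, ])$class, pred[i])

  ## a depth-1 tree yields single-condition rules
  m1 <- mk_forest_model(td$X[, "PATH0", drop = FALSE], td$y, ntree = 100)
  sur1 <- fit_surrogate(m1, grid = list(maxdepth = 1, minbucket = 1),
                        cv_folds = 0)
  r <- trace_decision(sur1, c(PATH0 = 9))
  expect_equal(nrow(r$conditions), 1)
})
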