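test_that("mean imputation always uses training-fold statistics", {
  tr <- toy_table(data.frame(X1 = c(1, 2, NA, 3), X2 = c(5, 5, 5, 5)), y = c(0, 1, 0, 1))
  te <- toy_table(data.frame(X1 = c(NA, 100), X2 = c(NA, 1)), y = c(0, 1))
  comp <- mean_impute(tr, te)
  expect_equal(comp$train$x$X1[3], 2)
  expect_equal(comp$test$x$X1[1], 2)   # train mean, not the test mean (100)
  expect_equal(comp$test$x$X2[1], 5)
  expect_false(anyNA(comp$train$x) || anyNA(comp$test$x))

  # identity on complete data
  full <- toy_table(data.frame(X1 = 1:4, X2 = 4:1), y = c(0, 1, 0, 1))
  expect_identical(mean_impute(full, full)$train$x, full$x)

  all_na <- toy_table(data.frame(X1 = c(NA_real_, NA_real_)), y = c(0, 1))
  expect_error(mean_impute(all_na), "X1")
})

test_that("kNN imputation averages the nearest training donors", {
  # distances to row 4 (on X1 alone, shared scale): rows 1 and 2 tie, row 3 far
  tr <- toy_table(
    data.frame(X1 = c(0, 0, 4, 0.5), X2 = c(0, 2, 4, NA)),
    y = c(0, 1, 0, 1)
  )
  expect_equal(knn_impute(tr, k = 1)$train$x$X2[4], 0) # tie -> lower row id
  expect_equal(knn_impute(tr, k = 2)$train$x$X2[4], 1) # mean(0, 2)
  expect_equal(knn_impute(tr, k = 3)$train$x$X2[4], 2) # mean(0, 2, 4)

  # exact duplicate dominates at k = 1
  tr2 <- toy_table(
    data.frame(X1 = c(1, 1, 9, 5), X2 = c(7, NA, 2, 3)),
    y = c(0, 1, 0, 1)
  )
  expect_equal(knn_impute(tr2, k = 1)$train$x$X2[2], 7)

  # test neighbours come from training rows only
  te <- toy_table(data.frame(X1 = c(1), X2 = c(NA)), y = 0)
  expect_equal(knn_impute(tr2, te, k = 1)$test$x$X2[1], 7)

  # identity on complete data, and k reported
  full <- toy_table(data.frame(X1 = 1:4, X2 = 4:1), y = c(0, 1, 0, 1))
  out <- knn_impute(full, k = 2)
  expect_identical(out$train$x, full$x)
  expect_identical(out$k, 2L)
})

test_that("kNN k-selection picks from the grid deterministically", {
  tab <- balanced_table(45, seed = 20)
  masked <- apply_mask(tab, inject_mcar(tab, 0.15, seed = 21))
  out1 <- knn_impute(masked, k_grid = c(1, 3, 5), seed = 7)
  out2 <- knn_impute(masked, k_grid = c(1, 3, 5), seed = 7)
  expect_true(out1$k %in% c(1L, 3L, 5L))
  expect_identical(out1, out2)
  expect_false(anyNA(out1$train$x))
})

test_that("forest-proximity imputation completes training data within range", {
  # identity on complete data
  full <- balanced_table(30, seed = 22)
  expect_identical(rf_proximity_impute(full, seed = 1), full)

  # two well-separated clusters: the imputed cell stays in its own cluster
  set.seed(5)
  x <- data.frame(
    X1 = c(rnorm(15, 0, 0.1), rnorm(15, 10, 0.1)),
    X2 = c(rnorm(15, 0, 0.1), rnorm(15, 10, 0.1))
  )
  y <- factor(rep(c(0, 1), each = 15))
  x$X2[3] <- NA
  tab <- toy_table(x, y)
  comp <- rf_proximity_impute(tab, iterations = 3, ntree = 100, seed = 2)
  expect_lt(comp$x$X2[3], 5) # cluster 1 lives near 0, cluster 2 near 10
  expect_identical(comp$x$X1, tab$x$X1) # observed cells untouched
  expect_identical(
    rf_proximity_impute(tab, iterations = 3, ntree = 100, seed = 2)$x$X2[3],
    comp$x$X2[3]
  )

  const <- toy_table(data.frame(X1 = c(1, NA, 3)), y = factor(rep("a", 3)))
  expect_error(rf_proximity_impute(const), "single response class")
})

test_that("forest proximities are symmetric with unit diagonal", {
  tab <- balanced_table(25, seed = 23)
  fit <- with(tab, randomForest::randomForest(as.data.frame(x), y, ntree = 50, proximity = TRUE))
  prox <- fit$proximity
  expect_equal(prox, t(prox))
  expect_equal(unname(diag(prox)), rep(1, 25))
})

test_that("chained equations yield m completed sets that track the drivers", {
  # no missing cells: m identical copies
  full <- balanced_table(20, seed = 24)
  out <- mice_impute(full, m = 3, seed = 1)
  expect_length(out, 3)
  for (o in out) expect_identical(o$train$x, full$x)

  # strongly correlated driver: imputations must follow it
  set.seed(9)
  n <- 500
  x2 <- rnorm(n)
  x1 <- 0.9 * x2 + sqrt(1 - 0.81) * rnorm(n)
  tab <- toy_table(data.frame(X1 = x1, X2 = x2, X3 = rnorm(n)), y = rbinom(n, 1, 0.5))
  masked <- apply_mask(tab, inject_mar(tab, 0.3, driver = 2, target = 1))
  out <- mice_impute(masked, m = 2, seed = 3, sweeps = 5)
  for (o in out) {
    filled <- is.na(masked$x$X1)
    expect_false(anyNA(o$train$x))
    expect_gt(cor(o$train$x$X1[filled], masked$x$X2[filled]), 0.5)
    # observed cells never altered
    expect_identical(o$train$x$X1[!filled], masked$x$X1[!filled])
  }

  # level-coded columns stay within the observed level range
  fix <- discretized_fixture(40, seed = 25, miss_rate = 0.2)
  out2 <- mice_impute(fix$table, m = 2, seed = 4, sweeps = 3)
  for (o in out2) {
    for (nm in names(o$train$x)) {
      rng <- range(fix$table$x[[nm]], na.rm = TRUE)
      expect_true(all(o$train$x[[nm]] >= rng[1] & o$train$x[[nm]] <= rng[2]))
    }
  }

  # deterministic under a fixed seed, distinct across sub-seeds
  rerun <- mice_impute(masked, m = 2, seed = 3, sweeps = 5)
  expect_identical(out, rerun)
  expect_false(identical(out[[1]]$train$x, out[[2]]$train$x))
})

test_that("chained-equation test rows use the final models without refitting", {
  set.seed(13)
  n <- 200
  x2 <- rnorm(n)
  x1 <- 0.9 * x2 + 0.3 * rnorm(n)
  tab <- toy_table(data.frame(X1 = x1, X2 = x2), y = rbinom(n, 1, 0.5))
  tr <- table_rows(tab, 1:150)
  te <- table_rows(tab, 151:200)
  tr_masked <- apply_mask(tr, inject_mar(tr, 0.3, driver = 2, target = 1))
  te_masked <- apply_mask(te, inject_mar(te, 0.4, driver = 2, target = 1))
  out <- mice_impute(tr_masked, te_masked, m = 2, seed = 5, sweeps = 5)
  for (o in out) {
    expect_false(anyNA(o$test$x))
    filled <- is.na(te_masked$x$X1)
    expect_gt(cor(o$test$x$X1[filled], te_masked$x$X2[filled]), 0.5)
  }
})
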