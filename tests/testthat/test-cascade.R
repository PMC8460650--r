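test_that("forest probability averaging reproduces the three-tree example", {
  fx <- worked_example_fixture()
  avg <- average_tree_distributions(fx$tree_distributions)
  expect_equal(round(unname(avg), 4), c(0.6435, 0.3565))
  expect_equal(sum(avg), 1)

  expect_equal(unname(average_tree_distributions(list(c(0.5, 0.5), c(0.5, 0.5)))),
               c(0.5, 0.5))
  expect_equal(unname(average_tree_distributions(list(c(0.2, 0.8)))), c(0.2, 0.8))
  expect_error(average_tree_distributions(list()), "at least one")
  expect_error(average_tree_distributions(list(c(0.7, 0.7))), "summing to 1")
})

test_that("augmentation appends the class vector to the original features", {
  X <- matrix(0, 5, 800)
  cv <- matrix(0.5, 5, 8)
  expect_equal(ncol(augment_features(X, cv)), 808L)
  expect_equal(ncol(augment_features(matrix(0, 5, 10), cv)), 18L)
  z <- augment_features(matrix(0, 0, 10), matrix(0, 0, 8))
  expect_equal(dim(z), c(0L, 18L))
  expect_error(augment_features(matrix(0, 4, 10), cv), "mismatch")
})

test_that("cascade separates a wide-margin toy problem and respects caps", {
  toy <- toy_separable()
  m <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 1))
  p <- predict(m, toy$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(compute_auc(toy$y, p), 1)
  expect_gte(length(m$layers), 1L)
  expect_true(min(p[toy$y == 1]) > max(p[toy$y == 0]))

  m1 <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 1, max_layers = 1L))
  expect_equal(length(m1$layers), 1L)
  expect_length(m1$stopping_record$val_auc, 1L)
})

test_that("class vectors are paired probabilities in fixed classifier order", {
  toy <- toy_separable(n = 60, d = 6)
  m <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 2, max_layers = 1L))
  cv <- layer_class_vector(m$layers[[1]], toy$X)
  expect_equal(dim(cv), c(60L, 8L))
  for (i in 1:4) {
    expect_equal(unname(cv[, 2 * i - 1] + cv[, 2 * i]), rep(1, 60),
                 tolerance = 1e-9)
  }
  # identical samples get identical class vectors
  X2 <- toy$X[c(1, 1), , drop = FALSE]
  cv2 <- layer_class_vector(m$layers[[1]], X2)
  expect_equal(cv2[1, ], cv2[2, ])
  expect_error(layer_class_vector(m$layers[[1]], toy$X[, 1:3]), "columns")
})

test_that("fitting is deterministic under a fixed seed", {
  toy <- toy_separable(n = 80, d = 8)
  m1 <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 9))
  m2 <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 9))
  expect_identical(m1$stopping_record, m2$stopping_record)
  expect_identical(predict(m1, toy$X), predict(m2, toy$X))
})

test_that("cascade rejects degenerate inputs", {
  toy <- toy_separable(n = 40, d = 5)
  expect_error(fit_cascade(toy$X, rep(1L, 40), tiny_cascade()), "both classes")
  expect_error(fit_cascade(toy$X, toy$y[1:10], tiny_cascade()), "length")
  expect_error(fit_cascade(toy$X[1:1, , drop = FALSE], 1L, tiny_cascade()),
               "both classes|fewer samples")
  m <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 3, max_layers = 1L))
  expect_error(predict(m, toy$X[, 1:3]), "columns")
})

test_that("constant features get zero importance and are pruned", {
  toy <- toy_separable(n = 100, d = 6)
  X <- cbind(toy$X, fconst = rep(2, 100))
  colnames(X) <- paste0("f", 1:7)
  m <- fit_cascade(X, toy$y, tiny_cascade(seed = 4, max_layers = 1L))
  expect_length(m$feature_mask, 7L)
  expect_false(m$feature_mask[7])
  expect_true(any(m$feature_mask))
  # informative features survive
  expect_true(all(m$feature_mask[1:6]))
  expect_equal(m$feature_mask, prune_zero_importance(m))
})

test_that("a single-forest single-layer cascade reduces to the bare forest", {
  toy <- toy_separable(n = 90, d = 7, seed = 13)
  cfg <- cascade_config(max_layers = 1L, oof_folds = 3L, num_trees = 25L,
                        classifiers = "random_forest", seed = 31)
  m <- fit_cascade(toy$X, toy$y, cfg)
  Xnew <- toy_separable(n = 30, d = 7, seed = 14)$X
  p_cascade <- predict(m, Xnew)

  # Structural oracle: replicate the refit layer's fold models directly with
  # ranger and average their probabilities.
  folds <- lpiforest:::.assign_folds(90, 3, lpiforest:::.derive_seed(31L, 1L + 1000L, 0L, 0L))
  Xn <- toy$X; colnames(Xn) <- paste0("f", 1:7)
  preds <- sapply(1:3, function(f) {
    fit <- ranger::ranger(x = Xn[folds != f, ], y = factor(toy$y[folds != f],
                                                           levels = c(0, 1)),
                          num.trees = 25, min.node.size = 5,
                          probability = TRUE, importance = "impurity",
                          seed = lpiforest:::.derive_seed(31L, 1L + 1000L, 1L, f),
                          num.threads = 1)
    Xq <- Xnew; colnames(Xq) <- paste0("f", 1:7)
    predict(fit, data = Xq, num.threads = 1)$predictions[, "1"]
  })
  expect_equal(p_cascade, unname(rowMeans(preds)), tolerance = 1e-12)
})

test_that("models serialize and reload across the schema check", {
  toy <- toy_separable(n = 60, d = 5)
  m <- fit_cascade(toy$X, toy$y, tiny_cascade(seed = 6, max_layers = 1L))
  path <- tempfile(fileext = ".rds")
  save_cascade(m, path)
  m2 <- load_cascade(path)
  expect_identical(predict(m, toy$X), predict(m2, toy$X))
  saveRDS(list(), path)
  expect_error(load_cascade(path), "incompatible")
})
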