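test_that("point metrics follow the confusion-table definitions", {
  m <- compute_point_metrics(TP = 3, FP = 1, TN = 4, FN = 2)
  expect_equal(unname(m), c(0.75, 0.6, 0.7, 2 * 0.75 * 0.6 / 1.35))

  expect_warning(expect_warning(
    m2 <- compute_point_metrics(TP = 0, FP = 0, TN = 10, FN = 0),
    "precision"), "recall")
  expect_equal(unname(m2), c(0, 0, 1, 0))

  m3 <- compute_point_metrics(TP = 5, FP = 0, TN = 5, FN = 0)
  expect_equal(unname(m3), c(1, 1, 1, 1))
})

test_that("AUC handles separation, ties, and the hand-enumerated example", {
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(compute_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(compute_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_error(compute_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUPR handles separation, constant scores, and known values", {
  expect_equal(compute_aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(compute_aupr(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)
  expect_equal(compute_aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)),
               oracle_aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)))
  expect_equal(compute_aupr(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 5 / 6)
  expect_error(compute_aupr(c(0, 0), c(0.2, 0.3)), "positive")
})

test_that("rank metrics agree with brute-force oracles on random vectors", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(compute_auc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
    expect_equal(compute_aupr(labels, scores), oracle_aupr(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("negative sampling avoids positives and reproduces under a seed", {
  set.seed(31)
  Y <- matrix(rbinom(100, 1, 0.3), 10, 10)
  n <- sum(Y)
  neg <- sample_negatives(Y, n, seed = 5)
  expect_equal(nrow(neg), n)
  expect_true(all(Y[cbind(neg$row, neg$col)] == 0L))
  expect_false(any(duplicated(neg)))
  expect_identical(neg, sample_negatives(Y, n, seed = 5))

  expect_error(sample_negatives(matrix(1L, 2, 2), 1), "deficit")
  ex <- which(Y == 0, arr.ind = TRUE)
  expect_error(sample_negatives(Y, sum(Y == 0), exclude = ex[1:2, ]), "deficit")
})

test_that("CV splits partition correctly under all three schemes", {
  set.seed(7)
  Y <- matrix(rbinom(200, 1, 0.3), 10, 20)
  # CV1: each fold masks 2 rows, no test row appears in training
  s1 <- make_cv_splits(Y, "CV1", n_folds = 5, seed = 1)
  test_rows <- sort(unique(unlist(lapply(s1, function(f) unique(f$test$row)))))
  expect_equal(test_rows, 1:10)
  for (f in s1) expect_length(intersect(unique(f$test$row), unique(f$train$row)), 0)

  # CV2 over columns
  s2 <- make_cv_splits(Y, "CV2", n_folds = 5, seed = 1)
  for (f in s2) expect_length(intersect(unique(f$test$col), unique(f$train$col)), 0)

  # CV3: balanced pairs split 80/20
  s3 <- make_cv_splits(Y, "CV3", n_folds = 5, seed = 1)
  total <- nrow(s3[[1]]$train) + nrow(s3[[1]]$test)
  expect_equal(total, 2 * sum(Y))
  for (f in s3) {
    expect_equal(nrow(f$test), total / 5)
    expect_length(intersect(paste(f$test$row, f$test$col, f$test$label),
                            paste(f$train$row, f$train$col, f$train$label)), 0)
  }
  expect_error(make_cv_splits(Y, "CV1", n_folds = 11), "at least as many")
})

test_that("balanced labeled sets are exactly balanced under CV3", {
  set.seed(12)
  Y <- matrix(rbinom(150, 1, 0.25), 15, 10)
  s <- make_cv_splits(Y, "CV3", n_folds = 5, seed = 3)
  all_pairs <- rbind(s[[1]]$train, s[[1]]$test)
  expect_equal(sum(all_pairs$label == 1), sum(all_pairs$label == 0))
})

test_that("repeated CV bookkeeping and determinism hold on a small pipeline", {
  fx <- tiny_pipeline_fixture()
  rep1 <- run_cv_experiment(fx$dataset, "CV3", n_folds = 3, repeats = 2,
                            cascade = tiny_cascade(), features = fx$features,
                            seed = 99)
  expect_s3_class(rep1, "lpi_cv_report")
  expect_equal(nrow(rep1$per_repeat), 2L)
  expect_equal(rep1$summary$metric,
               c("precision", "recall", "accuracy", "f1", "auc", "aupr"))
  expect_true(all(rep1$summary$mean >= 0 & rep1$summary$mean <= 1))

  rep2 <- run_cv_experiment(fx$dataset, "CV3", n_folds = 3, repeats = 2,
                            cascade = tiny_cascade(), features = fx$features,
                            seed = 99)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
})

test_that("unknown-pair ranking is complete, ordered, and tie-stable", {
  fx <- tiny_pipeline_fixture()
  ds <- fx$dataset
  pos <- which(ds$Y == 1L, arr.ind = TRUE)
  neg <- sample_negatives(ds$Y, sum(ds$Y), seed = 2)
  X <- pair_features(fx$features, c(pos[, 1], neg$row), c(pos[, 2], neg$col))
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  m <- fit_cascade(X, y, tiny_cascade(seed = 2))

  ranked <- rank_unknown_pairs(m, ds, fx$features)
  expect_equal(nrow(ranked), count_unknown_pairs(ds$Y))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 0))
  # ties broken lexicographically
  ties <- split(seq_len(nrow(ranked)), ranked$score)
  for (idx in ties) {
    if (length(idx) > 1) {
      block <- ranked[idx, ]
      expect_equal(order(block$lncrna_id, block$protein_id), seq_along(idx))
    }
  }
  # restriction to one entity
  rid <- ds$lncrnas$id[1]
  r1 <- rank_unknown_pairs(m, ds, fx$features, restrict = rid)
  expect_true(all(r1$lncrna_id == rid))
  expect_equal(nrow(r1), sum(ds$Y[rid, ] == 0L))
  expect_error(rank_unknown_pairs(m, ds, fx$features, restrict = "nope"),
               "not found")
  # fully-known matrix yields an empty ranking
  ds2 <- ds; ds2$Y[] <- 1L
  expect_equal(nrow(rank_unknown_pairs(m, ds2, fx$features)), 0L)
})

test_that("top-N true fractions follow the labeled prefix", {
  ranked <- data.frame(label = c(rep(1, 10), rep(0, 5), rep(1, 35), 0, 0, 1))
  expect_equal(top_n_true_fraction(ranked, 10), 100)
  expect_equal(top_n_true_fraction(ranked, 50), 90)
  expect_equal(top_n_true_fraction(c(0, 0, 0, 1), 3), 0)
  expect_error(top_n_true_fraction(ranked, 100), "exceeds")
})

test_that("cold-start scoring reacts to feature identity, not indices", {
  # Anti-leakage check: under CV1, swapping the test rows' lncRNA features for
  # training-row copies must change the scores.
  fx <- tiny_pipeline_fixture(seed = 8)
  sp <- make_cv_splits(fx$dataset$Y, "CV1", n_folds = 4, seed = 3)[[1]]
  X_tr <- pair_features(fx$features, sp$train$row, sp$train$col)
  m <- fit_cascade(X_tr, sp$train$label, tiny_cascade(seed = 3))
  X_te <- pair_features(fx$features, sp$test$row, sp$test$col)
  p_real <- predict(m, X_te)
  swapped <- fx$features
  swapped$lncrna[unique(sp$test$row), ] <-
    swapped$lncrna[rep_len(unique(sp$train$row), length(unique(sp$test$row))), ]
  p_swapped <- predict(m, pair_features(swapped, sp$test$row, sp$test$col))
  expect_false(isTRUE(all.equal(p_real, p_swapped)))
})
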