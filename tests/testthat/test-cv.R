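test_that("stratified folds partition cases and balance classes", {
  y <- rep(c(0, 1), each = 5)
  folds <- make_folds(y, k = 5, reps = 3, seed = 61)
  for (r in 1:3) {
    expect_setequal(folds[, r], 1:5)
    for (f in 1:5)
      expect_equal(sum(folds[, r] == f & y == 1), 1)  # 1 positive per fold
  }
  # partition validity across many seeds and an unbalanced cohort
  y2 <- rep(c(0, 1), c(37, 23))
  for (s in 1:10) {
    fl <- make_folds(y2, k = 5, reps = 2, seed = s)
    for (r in 1:2) {
      expect_equal(sort(unique(fl[, r])), 1:5)
      expect_true(all(table(fl[, r], y2)[, "1"] %in% 4:5))
    }
  }
})

test_that("repeated CV returns a coherent result on separable features", {
  set.seed(62)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == 1, 1] <- X[y == 1, 1] + 4
  cv <- repeated_cv(X, y, k = 5, reps = 5, seed = 1)
  expect_length(cv$per_fold_accuracy, 25)
  expect_gt(cv$accuracy, 0.9)
  expect_true(all(cv$per_fold_accuracy >= 0 & cv$per_fold_accuracy <= 1))
  # headline accuracy equals the fold-size weighted mean
  expect_equal(cv$accuracy, mean(colMeans(cv$oof_label == y)),
               tolerance = 1e-12)
  # determinism
  cv2 <- repeated_cv(X, y, k = 5, reps = 5, seed = 1)
  expect_identical(cv$per_fold_accuracy, cv2$per_fold_accuracy)
  expect_error(repeated_cv(X[1:8, ], y[c(1:4, 21:24)], k = 5),
               "smaller k")
})

test_that("permuted labels score near the majority-class rate", {
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 60
    X <- matrix(rnorm(n * 8), n, 8)
    y <- rep(c(0, 1), each = n / 2)
    y_perm <- sample(y)  # break any accidental association
    repeated_cv(X, y_perm, k = 5, reps = 3, seed = s)$accuracy
  }, 0)
  majority <- 0.5
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - majority), 3 * se)
})

test_that("confusion-matrix metrics match hand-computed values", {
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, f1 = 1, kappa = 1))

  allpos <- classification_metrics(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)
  expect_equal(allpos$kappa, 0)

  # TP=3, FP=1, FN=2, TN=4
  truth <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- classification_metrics(pred, truth)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 6 / 9)
  expect_equal(m$kappa, 0.4)

  # single-class truth: undefined entries are NA, not 0
  m1 <- classification_metrics(c(1, 0, 1), c(1, 1, 1))
  expect_true(is.na(m1$specificity))
  expect_equal(m1$sensitivity, 2 / 3)
})

test_that("paired accuracy t-test matches the closed form and flags degeneracy", {
  a <- c(0.70, 0.72, 0.74)
  b <- a - c(0.08, 0.10, 0.12)
  res <- paired_accuracy_ttest(a, b)
  expect_equal(res$t, 0.1 / (sd(c(0.08, 0.10, 0.12)) / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(res$t, 8.660, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0131, tolerance = 1e-2)
  # agreement with the stock paired t-test
  st <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(st$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, st$p.value, tolerance = 1e-12)

  swapped <- paired_accuracy_ttest(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)

  degen <- paired_accuracy_ttest(a, a)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))

  nb <- paired_accuracy_ttest(a, b, nadeau_bengio = TRUE,
                              test_train_ratio = 1 / 4)
  expect_lt(abs(nb$t), abs(res$t))  # variance correction is conservative
})

test_that("permutation baseline shares folds and stays below the signal arm", {
  set.seed(63)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 3
  folds <- make_folds(y, 5, 3, seed = 7)
  cv <- repeated_cv(X, y, k = 5, reps = 3, seed = 7, folds = folds)
  bl <- permutation_baseline(X, y, k = 5, reps = 3, seed = 7, folds = folds)
  expect_identical(bl$folds, folds)
  expect_gt(cv$accuracy, bl$accuracy)
  expect_match(bl$feature_set, "permuted")
})
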