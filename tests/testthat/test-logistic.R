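test_that("null covariate yields OR near 1 with CI covering 1", {
  set.seed(71)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(y, data.frame(x = x), mode = "univariable")
  expect_equal(fit$table$or, 1, tolerance = 0.1)
  expect_lt(fit$table$ci_lo, 1)
  expect_gt(fit$table$ci_hi, 1)
})

test_that("2x2 table odds ratio matches the cross-product ratio", {
  # exposed/outcome a=20, b=10; unexposed c=10, d=20 -> OR = ad/bc = 4
  exposure <- rep(c(TRUE, FALSE), c(30, 30))
  outcome <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(outcome, data.frame(exposed = exposure),
                      mode = "univariable")
  expect_equal(fit$table$or, 4, tolerance = 1e-6)
})

test_that("generator age link is recovered within the design interval", {
  cfg <- cohort_config(n_findings = 2000, age_or_per_year = 1.07, seed = 3)
  set.seed(72)
  cls <- sample(c("benign", "high_risk", "atypia", "malignant"), 2000, TRUE,
                c(0.44, 0.06, 0.05, 0.45))
  covs <- generate_covariates(cls, cfg)
  fit <- fit_logistic(as.integer(cls == "malignant"),
                      data.frame(age = covs$age), mode = "univariable")
  expect_gt(fit$table$or, 1.04)
  expect_lt(fit$table$or, 1.10)
})

test_that("reference-category swap inverts the odds ratio and its CI", {
  set.seed(73)
  n <- 500
  g <- runif(n) < 0.4
  y <- rbinom(n, 1, plogis(-0.5 + 1 * g))
  f1 <- fit_logistic(y, data.frame(g = g))
  f2 <- fit_logistic(y, data.frame(g = !g))
  expect_equal(f2$table$or, 1 / f1$table$or, tolerance = 1e-6)
  expect_equal(f2$table$ci_lo, 1 / f1$table$ci_hi, tolerance = 1e-6)
  expect_equal(f2$table$ci_hi, 1 / f1$table$ci_lo, tolerance = 1e-6)
})

test_that("perfect separation is flagged rather than silently reported", {
  y <- rep(c(0, 1), each = 10)
  x <- y * 2 - 1
  fit <- fit_logistic(y, data.frame(x = x))
  expect_true(fit$separation)
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "both classes")
})

test_that("AUC matches hand-countable examples and the pairwise oracle", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  # concordant pairs: only (0.8 > 0.2) of the 4 pos-neg pairs
  expect_equal(auc(c(0.9, 0.2, 0.8, 0.1), c(0, 0, 1, 1)), 0.25)
  expect_equal(auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")

  set.seed(74)
  for (rep in 1:5) {
    sc <- sample(seq(0, 1, 0.05), 30, TRUE)  # coarse grid forces ties
    tr <- rbinom(30, 1, 0.5)
    if (length(unique(tr)) < 2) next
    expect_equal(auc(sc, tr), auc_oracle(sc, tr), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone and integrates to the Mann-Whitney AUC", {
  set.seed(75)
  sc <- rnorm(80)
  tr <- rbinom(80, 1, 0.4)
  rc <- roc_curve(sc, tr)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, rc$auc, tolerance = 1e-12)
  # AUC invariant under strictly monotone transforms of the scores
  expect_equal(auc(exp(sc), tr), rc$auc, tolerance = 1e-12)
  expect_equal(auc(qlogis(plogis(sc)), tr), rc$auc, tolerance = 1e-10)
})

test_that("AUC comparison behaves at the extremes and is symmetric", {
  set.seed(76)
  tr <- rbinom(200, 1, 0.5)
  a <- roc_curve(tr + rnorm(200, 0, 0.6), tr)
  b <- roc_curve(rnorm(200), tr)
  same <- compare_auc(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  ab <- compare_auc(a, b)
  ba <- compare_auc(b, a)
  expect_lt(ab$p_value, 0.01)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  mismatch <- roc_curve(rnorm(100), rbinom(100, 1, 0.5))
  expect_error(compare_auc(a, mismatch), "identical case sets")
})

test_that("combined model demands out-of-fold scores and rewards signal", {
  set.seed(77)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  cv <- repeated_cv(X, y, k = 5, reps = 3, seed = 5)
  sc <- oof_scores(cv)
  expect_s3_class(sc, "oof_scores")
  expect_error(combined_model(y, NULL, rnorm(n)), "oof_scores")

  covs <- data.frame(age = 50 + 5 * y + rnorm(n, 0, 8))
  img_only <- combined_model(y, NULL, sc, k = 5, reps = 3, seed = 5)
  cov_only <- combined_model(y, covs, NULL, k = 5, reps = 3, seed = 5)
  both <- combined_model(y, covs, sc, k = 5, reps = 3, seed = 5)
  expect_gt(cov_only$auc_cv, 0.5)
  expect_gt(img_only$auc_cv, 0.8)
  expect_gt(both$auc_cv, max(img_only$auc_cv, cov_only$auc_cv) - 0.02)

  # an imaging score identical to the outcome gives AUC 1
  perfect <- structure(as.numeric(y), class = "oof_scores",
                       provenance = "out_of_fold")
  expect_equal(combined_model(y, NULL, perfect, k = 5, reps = 3,
                              seed = 5)$auc_apparent, 1.0)
})
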