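#' Stratified repeated cross-validation folds
#'
#' Draws `reps` independent stratified `k`-fold partitions: within each
#' class, fold labels are a random permutation of a balanced assignment, so
#' every fold's class proportions match the cohort's as closely as integer
#' counts allow.
#'
#' @param y binary labels
#' @param k folds per repetition
#' @param reps repetitions
#' @param seed integer seed
#' @return integer matrix `length(y) x reps` of fold ids in `1..k`
#' @export
make_folds <- function(y, k = 5, reps = 5, seed = 1L) {
  set.seed(seed)
  draw_folds(to_binary(y), k, reps)
}

# fold drawing from the current RNG stream
draw_folds <- function(y, k, reps) {
  n <- length(y)
  folds <- matrix(NA_integer_, n, reps)
  for (r in seq_len(reps)) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx, r] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  folds
}

#' Repeated stratified cross-validated PLDA
#'
#' The evaluation protocol for each feature set: 5-fold stratified
#' cross-validation repeated 5 times (by default). Within each training
#' split the ridge penalty is selected by an inner 3-fold cross-validation
#' over a logarithmic grid; the winning model predicts the held-out fold.
#' Per-fold accuracies (k x reps values) are retained for paired t-tests
#' between feature sets; summary metrics are computed from the pooled
#' out-of-fold predictions of each repetition and then averaged across
#' repetitions. The headline accuracy is the fold-size-weighted mean of the
#' per-fold accuracies, which equals the mean pooled accuracy.
#'
#' @param X feature matrix, cases in rows
#' @param y binary labels (positive class = 1)
#' @param k outer folds (each class must have at least `k` cases)
#' @param reps repetitions
#' @param seed seed for fold drawing and inner tuning
#' @param penalty_grid candidate ridge penalties
#' @param inner_k inner tuning folds
#' @param folds optional precomputed fold matrix from [make_folds()]; pass
#'   the same matrix to every feature set so paired comparisons share fold
#'   assignments
#' @param feature_set,task tags recorded on the result
#' @return object of class `cv_result`: `per_fold_accuracy` (k*reps),
#'   `fold_accuracy_matrix` (k x reps), `oof_label`/`oof_score` (n x reps
#'   out-of-fold predictions), `metrics` (accuracy, sensitivity,
#'   specificity, f1, kappa averaged over repetitions), `accuracy`
#'   (headline), `chosen_penalty` (k x reps), `folds`, tags
#' @export
repeated_cv <- function(X, y, k = 5, reps = 5, seed = 1L,
                        penalty_grid = 10^seq(-4, 2, by = 1),
                        inner_k = 3, folds = NULL,
                        feature_set = "features", task = "task") {
  X <- as.matrix(X)
  y <- to_binary(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (min(table(y)) < k)
    stop("smallest class has fewer cases than k = ", k,
         "; use a smaller k", call. = FALSE)

  set.seed(seed)
  if (is.null(folds)) folds <- draw_folds(y, k, reps)
  stopifnot(nrow(folds) == n, ncol(folds) == reps)

  fold_acc <- matrix(NA_real_, k, reps)
  fold_n <- matrix(NA_integer_, k, reps)
  chosen <- matrix(NA_real_, k, reps)
  oof_label <- matrix(NA_integer_, n, reps)
  oof_score <- matrix(NA_real_, n, reps)

  for (r in seq_len(reps)) {
    for (f in seq_len(k)) {
      test <- folds[, r] == f
      Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
      pen <- tune_penalty(Xtr, ytr, penalty_grid, inner_k)
      fit <- fit_plda(Xtr, ytr, penalty = pen, feature_set = feature_set)
      pr <- predict(fit, X[test, , drop = FALSE])
      fold_acc[f, r] <- mean(pr$label == y[test])
      fold_n[f, r] <- sum(test)
      chosen[f, r] <- pen
      oof_label[test, r] <- pr$label
      oof_score[test, r] <- pr$score
    }
  }

  per_rep <- lapply(seq_len(reps), function(r)
    classification_metrics(oof_label[, r], y))
  metrics <- colMeans(do.call(rbind, lapply(per_rep, unlist)))
  accuracy <- sum(fold_acc * fold_n) / sum(fold_n)

  structure(list(per_fold_accuracy = as.vector(fold_acc),
                 fold_accuracy_matrix = fold_acc,
                 oof_label = oof_label, oof_score = oof_score,
                 truth = y, metrics = as.list(metrics),
                 accuracy = accuracy, chosen_penalty = chosen,
                 folds = folds, k = k, reps = reps, seed = seed,
                 feature_set = feature_set, task = task),
            class = "cv_result")
}

# inner stratified CV accuracy over the penalty grid; smallest penalty among
# the best (ties broken toward less regularization is arbitrary — toward the
# smaller penalty keeps the estimator closest to classical LDA)
tune_penalty <- function(X, y, penalty_grid, inner_k) {
  kk <- min(inner_k, min(table(y)))
  if (kk < 2L) return(stats::median(penalty_grid))
  inner <- draw_folds(y, kk, 1L)[, 1]
  acc <- matrix(NA_real_, kk, length(penalty_grid))
  for (f in seq_len(kk)) {
    hold <- inner == f
    for (j in seq_along(penalty_grid)) {
      fit <- try(fit_plda(X[!hold, , drop = FALSE], y[!hold],
                          penalty = penalty_grid[j]), silent = TRUE)
      acc[f, j] <- if (inherits(fit, "try-error")) NA_real_ else
        mean(predict(fit, X[hold, , drop = FALSE])$label == y[hold])
    }
  }
  mean_acc <- colMeans(acc)
  if (all(is.na(mean_acc))) return(stats::median(penalty_grid))
  penalty_grid[which.max(replace(mean_acc, is.na(mean_acc), -Inf))]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Repeated CV (%d-fold x %d reps) | task: %s | features: %s\n",
              x$k, x$reps, x$task, x$feature_set))
  cat(sprintf("  accuracy %.4f | sens %.4f | spec %.4f | F1 %.4f | kappa %.4f\n",
              x$accuracy, x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$f1, x$metrics$kappa))
  invisible(x)
}

#' Permuted-label baseline under the identical CV protocol
#'
#' Re-runs [repeated_cv()] after randomly permuting the labels once, keeping
#' the fold assignments of the real run, giving an empirical random-classifier
#' reference under the same protocol (typically near, and often slightly
#' below, the majority-class rate).
#'
#' @inheritParams repeated_cv
#' @param perm_seed seed for the label permutation
#' @return a `cv_result` tagged `feature_set = "<feature_set>:permuted"`
#' @export
permutation_baseline <- function(X, y, k = 5, reps = 5, seed = 1L,
                                 perm_seed = seed + 1L, folds = NULL,
                                 feature_set = "features", task = "task",
                                 ...) {
  y <- to_binary(y)
  set.seed(perm_seed)
  y_perm <- sample(y)
  repeated_cv(X, y_perm, k = k, reps = reps, seed = seed, folds = folds,
              feature_set = paste0(feature_set, ":permuted"), task = task,
              ...)
}

#' Binary classification metrics
#'
#' Standard confusion-matrix summaries with the positive class coded 1:
#' accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), and Cohen's kappa (p_o - p_e)/(1 - p_e). When the
#' truth contains a single class the undefined entries are NA (flagged
#' missing), never silently 0.
#'
#' @param predictions predicted binary labels
#' @param truth true binary labels
#' @return named list: accuracy, sensitivity, specificity, f1, kappa
#' @export
classification_metrics <- function(predictions, truth) {
  p <- to_binary(predictions); t <- to_binary(truth)
  stopifnot(length(p) == length(t), length(t) > 0L)
  tp <- sum(p == 1L & t == 1L); tn <- sum(p == 0L & t == 0L)
  fp <- sum(p == 1L & t == 0L); fn <- sum(p == 0L & t == 1L)
  n <- length(t)
  sens <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(accuracy = po, sensitivity = sens, specificity = spec,
       f1 = f1, kappa = kappa)
}

#' Paired t-test on per-fold cross-validation accuracies
#'
#' Two-sided paired t-test on the fold-wise accuracy differences of two
#' feature sets evaluated under shared fold assignments (df = n - 1). An
#' optional Nadeau-Bengio variance correction accounts for the overlap of
#' training sets across repeated-CV folds, which makes the naive paired test
#' anti-conservative.
#'
#' @param acc_a,acc_b equal-length (>= 2) per-fold accuracy vectors from two
#'   arms run on identical folds
#' @param nadeau_bengio apply the variance inflation `1/n + n_test/n_train`
#'   in place of `1/n`
#' @param test_train_ratio `n_test/n_train` for the correction (1/(k-1) for
#'   k-fold CV)
#' @return list: `t`, `df`, `p_value`, `mean_diff`, `degenerate` (TRUE when
#'   the differences have zero variance, in which case t and p are NA)
#' @export
paired_accuracy_ttest <- function(acc_a, acc_b, nadeau_bengio = FALSE,
                                  test_train_ratio = 1 / 4) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2L)
  d <- acc_a - acc_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    return(list(t = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  se <- if (nadeau_bengio)
    sd_d * sqrt(1 / n + test_train_ratio) else sd_d / sqrt(n)
  tstat <- mean(d) / se
  list(t = tstat, df = n - 1L,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
       mean_diff = mean(d), degenerate = FALSE)
}
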