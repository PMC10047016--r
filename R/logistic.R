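#' Dichotomized analysis codings for clinical covariates
#'
#' Maps the raw categorical covariates to the binary codings used in the
#' regression models: race as White (reference) vs. all other races, breast
#' density as non-dense (fatty/scattered, reference) vs. dense
#' (heterogeneously/extremely dense), background parenchymal enhancement as
#' minimal/moderate (reference) vs. marked, menopausal status as pre-
#' (reference) vs. post-menopausal. Unknown category levels raise an error
#' naming the field and value.
#'
#' @param meta data.frame with columns age, race, history, menopause,
#'   density_category, bpe
#' @return data.frame: age, race_other, history, postmenopausal, dense,
#'   bpe_marked (logicals except age)
#' @export
code_covariates <- function(meta) {
  chk <- function(field, allowed) {
    v <- meta[[field]]
    bad <- setdiff(unique(v), allowed)
    if (length(bad))
      stop(sprintf("unknown level in '%s': '%s'", field, bad[1]),
           call. = FALSE)
    v
  }
  race <- chk("race", c("White", "Black", "Asian or Pacific Islander",
                        "Other Race or Race Not Recorded"))
  menop <- chk("menopause", c("Pre-Menopausal", "Post-Menopausal"))
  dens <- chk("density_category",
              c("Fatty", "Scattered", "Heterogeneously Dense",
                "Extremely Dense"))
  bpe <- chk("bpe", c("Minimal", "Moderate", "Marked"))
  data.frame(
    age = as.numeric(meta$age),
    race_other = race != "White",
    history = as.logical(meta$history),
    postmenopausal = menop == "Post-Menopausal",
    dense = dens %in% c("Heterogeneously Dense", "Extremely Dense"),
    bpe_marked = bpe == "Marked"
  )
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fits with Wald standard errors, odds ratios
#' `exp(beta)` and 95% confidence intervals `exp(beta +- 1.96 SE)`.
#' Univariable mode fits each covariate in a separate model; multivariable
#' mode fits them jointly (adjusted odds ratios). Perfect separation is
#' detected from the fitted probabilities and flagged; with
#' `penalized = TRUE` (and glmnet installed) a ridge-penalized refit
#' provides finite coefficients, reported without Wald intervals.
#'
#' @param outcome binary outcome (1 = positive)
#' @param covariates data.frame of predictors (numeric or logical),
#'   e.g. from [code_covariates()]
#' @param mode `"multivariable"` or `"univariable"`
#' @param penalized offer a ridge refit when separation is flagged
#' @return object of class `logistic_fit`: `table` (term, estimate, se, or,
#'   ci_lo, ci_hi, p_value, mode), `converged`, `separation`, `mode`
#' @export
fit_logistic <- function(outcome, covariates,
                         mode = c("multivariable", "univariable"),
                         penalized = FALSE) {
  mode <- match.arg(mode)
  y <- to_binary(outcome)
  if (length(unique(y)) != 2L)
    stop("outcome must contain both classes", call. = FALSE)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y))

  one_fit <- function(df, tag) {
    dat <- cbind(.y = y, df)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    # separation can also complete "successfully" with divergent
    # coefficients: flag it when the fitted probabilities classify the
    # outcome perfectly
    p_hat <- stats::fitted(fit)
    if (max(p_hat[y == 0]) < min(p_hat[y == 1]) &&
        (max(p_hat[y == 0]) < 1e-6 || min(p_hat[y == 1]) > 1 - 1e-6))
      sep <- TRUE
    if (!fit$converged && !sep)
      stop("logistic fit did not converge after ", fit$iter, " iterations",
           call. = FALSE)
    cf <- summary(fit)$coefficients
    cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               or = exp(cf[, 1]),
               ci_lo = exp(cf[, 1] - 1.96 * cf[, 2]),
               ci_hi = exp(cf[, 1] + 1.96 * cf[, 2]),
               p_value = cf[, 4], mode = tag,
               separation = sep, row.names = NULL)
  }

  tab <- if (mode == "univariable") {
    do.call(rbind, lapply(names(covariates), function(v)
      one_fit(covariates[, v, drop = FALSE], "univariable")))
  } else {
    one_fit(covariates, "multivariable")
  }

  sep <- any(tab$separation)
  ridge <- NULL
  if (sep && penalized && requireNamespace("glmnet", quietly = TRUE)) {
    xm <- data.matrix(covariates)
    g <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                        lambda = 1e-2)
    ridge <- stats::setNames(as.vector(stats::coef(g))[-1], colnames(xm))
  }
  structure(list(table = tab[, setdiff(names(tab), "separation")],
                 converged = TRUE, separation = sep,
                 ridge_coefficients = ridge, mode = mode),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s)%s\n", x$mode,
              if (x$separation) " [separation flagged]" else ""))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-16s OR %.2f [%.2f, %.2f]  p = %.4g\n", tb$term[i],
                tb$or[i], tb$ci_lo[i], tb$ci_hi[i], tb$p_value[i]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' random positive case outscores a random negative case, ties counted 1/2.
#' Identical to the trapezoidal integral of the empirical ROC curve.
#'
#' @param scores continuous scores (higher = more positive)
#' @param truth binary truth (1 = positive)
#' @return scalar in `[0, 1]`
#' @export
auc <- function(scores, truth) {
  t <- to_binary(truth)
  if (length(unique(t)) != 2L)
    stop("truth must contain both classes", call. = FALSE)
  stopifnot(length(scores) == length(t), all(is.finite(scores)))
  r <- rank(scores)
  n1 <- sum(t == 1L); n0 <- sum(t == 0L)
  (sum(r[t == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the observed scores and records the
#' true- and false-positive rates; the AUC field is the Mann-Whitney value
#' from [auc()], which equals the trapezoidal integral of the curve.
#'
#' @inheritParams auc
#' @param provenance free-text note on where the scores came from (e.g.
#'   which model and whether they are cross-validated)
#' @return object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `scores`, `truth`, `provenance`
#' @export
roc_curve <- function(scores, truth, provenance = "unspecified") {
  t <- to_binary(truth)
  a <- auc(scores, t)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(t == 1L); n0 <- sum(t == 0L)
  tpr <- vapply(thr, function(h) sum(scores >= h & t == 1L) / n1, 0)
  fpr <- vapply(thr, function(h) sum(scores >= h & t == 0L) / n0, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = a,
                 scores = scores, truth = t, provenance = provenance),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (n+ = %d, n- = %d) [%s]\n", x$auc,
              sum(x$truth == 1L), sum(x$truth == 0L), x$provenance))
  invisible(x)
}

#' Compare two AUCs
#'
#' DeLong's test for correlated ROC curves (the default for paired designs,
#' where both models score the same cases); a seeded bootstrap is used as a
#' fallback when the DeLong variance estimate degenerates. Identical score
#' vectors return p = 1 with statistic 0.
#'
#' @param roc_a,roc_b `roc_curve` objects
#' @param paired both curves score the same cases (requires identical truth
#'   vectors)
#' @param boot_n bootstrap resamples for the fallback
#' @param seed seed for the bootstrap fallback
#' @return list: `p_value`, `statistic`, `auc_a`, `auc_b`, `method`
#' @export
compare_auc <- function(roc_a, roc_b, paired = TRUE, boot_n = 2000,
                        seed = 1L) {
  stopifnot(inherits(roc_a, "roc_curve"), inherits(roc_b, "roc_curve"))
  if (paired && !identical(roc_a$truth, roc_b$truth))
    stop("paired comparison requires identical case sets and truth vectors",
         call. = FALSE)
  if (identical(roc_a$scores, roc_b$scores))
    return(list(p_value = 1, statistic = 0, auc_a = roc_a$auc,
                auc_b = roc_b$auc, method = "identical scores"))
  pa <- pROC::roc(roc_a$truth, roc_a$scores, levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  pb <- pROC::roc(roc_b$truth, roc_b$scores, levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  res <- suppressWarnings(
    pROC::roc.test(pa, pb, method = "delong", paired = paired))
  p <- as.numeric(res$p.value)
  stat <- as.numeric(res$statistic)
  method <- "delong"
  if (!is.finite(p)) {
    set.seed(seed)
    res <- suppressWarnings(
      pROC::roc.test(pa, pb, method = "bootstrap", paired = paired,
                     boot.n = boot_n, progress = "none"))
    p <- as.numeric(res$p.value)
    stat <- as.numeric(res$statistic)
    method <- "bootstrap"
  }
  list(p_value = p, statistic = stat, auc_a = roc_a$auc, auc_b = roc_b$auc,
       method = method)
}

#' Cross-validated out-of-fold imaging scores
#'
#' Extracts the per-case PLDA discriminant score averaged over the
#' out-of-fold predictions of each repetition, tagged with its provenance so
#' downstream models can verify the scores were never fit on the case they
#' score.
#'
#' @param cv a `cv_result`
#' @return numeric vector of class `oof_scores`
#' @export
oof_scores <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  structure(rowMeans(cv$oof_score), class = "oof_scores",
            provenance = "out_of_fold")
}

#' Combined imaging + clinical logistic model
#'
#' Fits a logistic model of the outcome on the cross-validated PLDA imaging
#' score together with the clinical covariates (age, race, history of breast
#' cancer, menopausal status, breast density), and reports both an apparent
#' ROC (in-sample fitted probabilities) and a cross-validated ROC
#' (out-of-fold predicted probabilities under repeated stratified CV); the
#' cross-validated AUC is the honest headline. Imaging scores must carry
#' out-of-fold provenance (see [oof_scores()]); raw in-fold scores are
#' rejected to prevent optimistic AUCs. Pass `imaging_scores = NULL` for a
#' covariates-only model.
#'
#' @param outcome binary outcome
#' @param covariates coded covariate data.frame (see [code_covariates()]);
#'   may be NULL for an imaging-only model
#' @param imaging_scores `oof_scores` vector or NULL
#' @param k,reps,seed repeated-CV settings for the cross-validated
#'   probabilities
#' @param folds optional precomputed fold matrix
#' @return list of class `combined_model`: `fit` (`logistic_fit`), `roc_cv`,
#'   `roc_apparent`, `auc_cv`, `auc_apparent`
#' @export
combined_model <- function(outcome, covariates = NULL, imaging_scores = NULL,
                           k = 5, reps = 5, seed = 1L, folds = NULL) {
  y <- to_binary(outcome)
  if (!is.null(imaging_scores) && !inherits(imaging_scores, "oof_scores"))
    stop("imaging_scores must be cross-validated `oof_scores` (in-fold ",
         "scores would inflate the AUC)", call. = FALSE)
  df <- if (is.null(covariates)) data.frame(row.names = seq_along(y)) else
    as.data.frame(covariates)
  if (!is.null(imaging_scores))
    df$imaging_score <- as.numeric(imaging_scores)
  if (ncol(df) == 0L)
    stop("need at least one of covariates or imaging_scores", call. = FALSE)
  stopifnot(nrow(df) == length(y))

  fit <- fit_logistic(y, df, mode = "multivariable")
  full <- suppressWarnings(stats::glm(.y ~ ., data = cbind(.y = y, df),
                                      family = stats::binomial()))
  roc_app <- roc_curve(stats::fitted(full), y,
                       provenance = "apparent (in-sample)")

  set.seed(seed)
  if (is.null(folds)) folds <- draw_folds(y, k, reps)
  oof_p <- matrix(NA_real_, length(y), reps)
  for (r in seq_len(reps)) {
    for (f in seq_len(k)) {
      test <- folds[, r] == f
      g <- suppressWarnings(
        stats::glm(.y ~ ., data = cbind(.y = y, df)[!test, , drop = FALSE],
                   family = stats::binomial()))
      oof_p[test, r] <- suppressWarnings(
        stats::predict(g, newdata = df[test, , drop = FALSE],
                       type = "response"))
    }
  }
  roc_cv <- roc_curve(rowMeans(oof_p), y,
                      provenance = sprintf(
                        "cross-validated (%d-fold x %d reps)", k, reps))
  structure(list(fit = fit, roc_cv = roc_cv, roc_apparent = roc_app,
                 auc_cv = roc_cv$auc, auc_apparent = roc_app$auc),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("Combined logistic model: AUC %.4f (cross-validated), %.4f (apparent)\n",
              x$auc_cv, x$auc_apparent))
  invisible(x)
}
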