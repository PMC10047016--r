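#' Full-run configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic cohort
#' configuration (or a manifest of existing data in the same layout), the
#' number of radial bands, the cross-validation settings, the task list and
#' the master seed. Identical configurations produce identical outputs.
#'
#' @param cohort a [cohort_config()], or a path to a manifest CSV of an
#'   existing cohort in the package's layout
#' @param n_bands radial bands per channel
#' @param k,reps cross-validation folds and repetitions
#' @param tasks classification tasks to run
#' @param include_atypia_as_benign see [exclusion_filter()]
#' @param seed master seed for folds, permutations and model CV
#' @param out_dir optional directory for the report artifacts; NULL keeps
#'   everything in memory
#' @return list of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(), n_bands = 32,
                       k = 5, reps = 5,
                       tasks = c("malignant_vs_benign",
                                 "invasive_vs_noninvasive"),
                       include_atypia_as_benign = FALSE,
                       seed = 1L, out_dir = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(list(cohort = cohort, n_bands = n_bands, k = k, reps = reps,
                 tasks = tasks,
                 include_atypia_as_benign = include_atypia_as_benign,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> feature extraction -> penalized-LDA
#' repeated cross-validation per feature set (density, contrast,
#' concatenated) with a permuted-label baseline and pairwise paired t-tests
#' -> logistic odds-ratio models -> combined imaging + clinical AUC models
#' with DeLong comparisons. Writes per-task metric tables, odds-ratio and
#' AUC-comparison tables, mean radial profiles, per-fold accuracies and a
#' structured JSON log when `config$out_dir` is set.
#'
#' @param config a [run_config()]
#' @return list of class `run_bundle` with elements `cohort_summary`,
#'   `features`, `tasks` (per task: cv results, baseline, t-tests, metric
#'   table, mean profiles), `models` (odds-ratio tables, AUC table, ROC
#'   curves), `exclusions`, `config`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cases <- stage("simulate", {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else simulate_cohort(config$cohort)$cases
  })
  meta <- stage("simulate", {
    do.call(rbind, lapply(cases, function(cs)
      cbind(data.frame(case_id = cs$case_id, class = cs$class_label,
                       invasive_flag = if (is.null(cs$invasive_flag)) NA
                       else cs$invasive_flag,
                       stringsAsFactors = FALSE),
            cs$covariates[, c("age", "race", "history", "menopause",
                              "density_category", "bpe")])))
  })

  # task filtering first: an unusable class mix should abort before the
  # expensive feature stage
  filters <- list()
  for (task in config$tasks)
    filters[[task]] <- stage(task, exclusion_filter(
      cases, task,
      include_atypia_as_benign = config$include_atypia_as_benign))

  feats <- stage("features", cohort_features(cases, config$n_bands))
  cohort_summary <- summarize_cohort(meta)

  tasks_out <- list()
  models_out <- NULL
  exclusions <- list()
  log <- list(seed = config$seed, n_bands = config$n_bands,
              n_cases = length(cases))

  for (task in config$tasks) {
    flt <- filters[[task]]
    keep <- match(vapply(flt$cases, `[[`, "", "case_id"), meta$case_id)
    y <- flt$labels
    exclusions[[task]] <- flt$exclusion_log

    folds <- make_folds(y, config$k, config$reps, seed = config$seed)
    arms <- list(density = feats$density[keep, , drop = FALSE],
                 contrast = feats$contrast[keep, , drop = FALSE],
                 concatenated = feats$concatenated[keep, , drop = FALSE])
    cv <- stage(task, lapply(names(arms), function(a)
      repeated_cv(arms[[a]], y, k = config$k, reps = config$reps,
                  seed = config$seed, folds = folds,
                  feature_set = a, task = task)))
    names(cv) <- names(arms)
    baseline <- stage(task, permutation_baseline(
      arms$concatenated, y, k = config$k, reps = config$reps,
      seed = config$seed, folds = folds,
      feature_set = "concatenated", task = task))

    pairs <- utils::combn(names(cv), 2, simplify = FALSE)
    ttests <- lapply(pairs, function(pr)
      c(list(a = pr[1], b = pr[2]),
        paired_accuracy_ttest(cv[[pr[1]]]$per_fold_accuracy,
                              cv[[pr[2]]]$per_fold_accuracy)))
    vs_baseline <- lapply(names(cv), function(a)
      c(list(a = a, b = "permuted"),
        paired_accuracy_ttest(cv[[a]]$per_fold_accuracy,
                              baseline$per_fold_accuracy)))

    metric_table <- do.call(rbind, lapply(names(cv), function(a)
      data.frame(task = task, feature_set = a,
                 accuracy = cv[[a]]$accuracy,
                 sensitivity = cv[[a]]$metrics$sensitivity,
                 specificity = cv[[a]]$metrics$specificity,
                 f1 = cv[[a]]$metrics$f1, kappa = cv[[a]]$metrics$kappa)))
    metric_table <- rbind(metric_table, data.frame(
      task = task, feature_set = "permuted_baseline",
      accuracy = baseline$accuracy,
      sensitivity = baseline$metrics$sensitivity,
      specificity = baseline$metrics$specificity,
      f1 = baseline$metrics$f1, kappa = baseline$metrics$kappa))

    profiles <- lapply(c(density = "density", contrast = "contrast"),
                       function(ch) class_average_profile(
                         lapply(feats$histograms[keep],
                                function(h) h[[ch]]),
                         factor(y, c(0, 1),
                                if (task == "malignant_vs_benign")
                                  c("benign", "malignant")
                                else c("non_invasive", "invasive"))))

    tasks_out[[task]] <- list(cv = cv, baseline = baseline,
                              ttests = c(ttests, vs_baseline),
                              metric_table = metric_table,
                              profiles = profiles, folds = folds,
                              labels = y, keep = keep)
    log[[paste0("excluded_", task)]] <- nrow(flt$exclusion_log)
    log[[paste0("penalties_", task)]] <-
      lapply(cv, function(z) as.vector(z$chosen_penalty))
  }

  if ("malignant_vs_benign" %in% names(tasks_out)) {
    tk <- tasks_out$malignant_vs_benign
    mmeta <- meta[tk$keep, , drop = FALSE]
    coded <- code_covariates(mmeta)
    y <- tk$labels
    models_out <- stage("models", {
      uni <- fit_logistic(y, coded, mode = "univariable")
      multi <- fit_logistic(y, coded, mode = "multivariable")
      # the combined predictive models use the clinical covariate set
      # without BPE; BPE appears in the odds-ratio regressions only
      clin <- coded[, c("age", "race_other", "history", "postmenopausal",
                        "dense")]
      combos <- list(
        covariates_only = combined_model(y, clin, NULL, k = config$k,
                                         reps = config$reps,
                                         seed = config$seed,
                                         folds = tk$folds))
      for (a in names(tk$cv)) {
        sc <- oof_scores(tk$cv[[a]])
        combos[[paste0(a, "_only")]] <-
          combined_model(y, NULL, sc, k = config$k, reps = config$reps,
                         seed = config$seed, folds = tk$folds)
        combos[[paste0(a, "_plus_clinical")]] <-
          combined_model(y, clin, sc, k = config$k, reps = config$reps,
                         seed = config$seed, folds = tk$folds)
      }
      auc_table <- do.call(rbind, lapply(names(combos), function(nm) {
        base <- sub("_plus_clinical|_only", "", nm)
        with_clin <- grepl("plus_clinical|covariates_only", nm)
        data.frame(model = nm, auc_cv = combos[[nm]]$auc_cv,
                   auc_apparent = combos[[nm]]$auc_apparent,
                   with_clinical = with_clin)
      }))
      delong <- lapply(intersect(c("density", "contrast", "concatenated"),
                                 names(tk$cv)), function(a)
        c(list(comparison = paste0(a, "_plus_clinical vs ", a, "_only")),
          compare_auc(combos[[paste0(a, "_plus_clinical")]]$roc_cv,
                      combos[[paste0(a, "_only")]]$roc_cv,
                      paired = TRUE, seed = config$seed)))
      list(univariable = uni, multivariable = multi, combined = combos,
           auc_table = auc_table, delong = delong)
    })
  }

  bundle <- structure(list(cohort_summary = cohort_summary,
                           features = feats, tasks = tasks_out,
                           models = models_out, exclusions = exclusions,
                           log = log, config = config),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# serialize the report tables; numbers are written at full precision so
# byte-identical files certify numerically identical runs
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE),
                     file.path(out_dir, name), row.names = FALSE)
  wcsv(bundle$cohort_summary, "cohort_summary.csv")
  for (task in names(bundle$tasks)) {
    tk <- bundle$tasks[[task]]
    wcsv(tk$metric_table, sprintf("metrics_%s.csv", task))
    acc <- do.call(rbind, lapply(names(tk$cv), function(a)
      data.frame(task = task, feature_set = a,
                 fold = seq_along(tk$cv[[a]]$per_fold_accuracy),
                 accuracy = tk$cv[[a]]$per_fold_accuracy)))
    wcsv(acc, sprintf("fold_accuracy_%s.csv", task))
    wcsv(do.call(rbind, lapply(tk$ttests, as.data.frame)),
         sprintf("ttests_%s.csv", task))
    prof <- do.call(rbind, lapply(names(tk$profiles), function(ch) {
      m <- tk$profiles[[ch]]
      data.frame(task = task, channel = ch,
                 group = rep(rownames(m), each = ncol(m)),
                 band = rep(seq_len(ncol(m)), times = nrow(m)),
                 mean_value = as.vector(t(m)))
    }))
    wcsv(prof, sprintf("radial_profiles_%s.csv", task))
  }
  if (!is.null(bundle$models)) {
    wcsv(rbind(bundle$models$univariable$table,
               bundle$models$multivariable$table), "odds_ratios.csv")
    wcsv(bundle$models$auc_table, "auc_comparison.csv")
    wcsv(do.call(rbind, lapply(bundle$models$delong, as.data.frame)),
         "auc_delong_tests.csv")
  }
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Demographic / imaging / pathology summary of a cohort
#'
#' Counts and one-decimal percentages (ties rounded half-up) for every
#' categorical metadata field, plus the median and inter-quartile range of
#' age, in the style of a cohort characteristics table.
#'
#' @param metadata cohort metadata data.frame (e.g.
#'   `synthetic_cohort$metadata`, a manifest, or [design_cohort_metadata()])
#' @return data.frame: field, level, count, pct (NA for the age rows, which
#'   carry `value` instead)
#' @export
summarize_cohort <- function(metadata) {
  n <- nrow(metadata)
  fields <- intersect(c("class", "race", "history", "menopause",
                        "density_category", "bpe", "finding_category",
                        "invasive_flag"),
                      names(metadata))
  rows <- list(data.frame(field = "age", level = "median",
                          count = NA_integer_,
                          value = stats::median(metadata$age), pct = NA),
               data.frame(field = "age", level = "IQR_lo",
                          count = NA_integer_,
                          value = unname(stats::quantile(metadata$age, .25)),
                          pct = NA),
               data.frame(field = "age", level = "IQR_hi",
                          count = NA_integer_,
                          value = unname(stats::quantile(metadata$age, .75)),
                          pct = NA))
  for (f in fields) {
    v <- metadata[[f]]
    if (f == "invasive_flag") v <- v[!is.na(v)]
    tab <- table(v, useNA = "no")
    denom <- if (f == "invasive_flag") length(v) else n
    rows[[length(rows) + 1]] <- data.frame(
      field = f, level = names(tab), count = as.integer(tab),
      value = NA_real_,
      pct = round_half_up(100 * as.integer(tab) / denom, 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
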