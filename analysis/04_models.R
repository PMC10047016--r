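#!/usr/bin/env Rscript
# Step 4 — clinical covariate models and combined imaging + clinical AUCs.
#
# Univariable and multivariable logistic odds ratios for malignancy
# (age, race, personal history, menopausal status, breast density, BPE),
# then combined predictive models coupling the cross-validated PLDA
# discriminant score with the clinical covariates (without BPE). AUCs come
# from cross-validated predicted probabilities; DeLong tests compare each
# imaging model with and without the clinical data.

library(cemradial)

SEED <- 20260929L
cases <- read_cohort("results/cohort/manifest.csv")
feats <- cohort_features(cases, n_bands = 32)
ids <- vapply(cases, `[[`, "", "case_id")

flt <- exclusion_filter(cases, "malignant_vs_benign")
keep <- match(vapply(flt$cases, `[[`, "", "case_id"), ids)
y <- flt$labels
meta <- do.call(rbind, lapply(flt$cases, `[[`, "covariates"))
coded <- code_covariates(meta)

uni <- fit_logistic(y, coded, mode = "univariable")
multi <- fit_logistic(y, coded, mode = "multivariable")
print(uni); print(multi)
write.csv(rbind(uni$table, multi$table), "results/odds_ratios.csv",
          row.names = FALSE)

folds <- make_folds(y, 5, 5, seed = SEED)
clin <- coded[, c("age", "race_other", "history", "postmenopausal", "dense")]
arms <- list(density = feats$density[keep, ],
             contrast = feats$contrast[keep, ],
             concatenated = feats$concatenated[keep, ])

rows <- list(); rocs <- list(); delong <- list()
cov_only <- combined_model(y, clin, NULL, seed = SEED, folds = folds)
rows[["clinical_only"]] <- data.frame(model = "clinical_only",
                                      auc_cv = cov_only$auc_cv,
                                      auc_apparent = cov_only$auc_apparent)
rocs[["clinical_only"]] <- cov_only$roc_cv
for (a in names(arms)) {
  sc <- oof_scores(repeated_cv(arms[[a]], y, seed = SEED, folds = folds,
                               feature_set = a))
  m_img <- combined_model(y, NULL, sc, seed = SEED, folds = folds)
  m_both <- combined_model(y, clin, sc, seed = SEED, folds = folds)
  rows[[a]] <- data.frame(
    model = c(paste0(a, "_only"), paste0(a, "_plus_clinical")),
    auc_cv = c(m_img$auc_cv, m_both$auc_cv),
    auc_apparent = c(m_img$auc_apparent, m_both$auc_apparent))
  rocs[[paste0(a, "_only")]] <- m_img$roc_cv
  rocs[[paste0(a, "_plus_clinical")]] <- m_both$roc_cv
  cmp <- compare_auc(m_both$roc_cv, m_img$roc_cv, seed = SEED)
  delong[[a]] <- data.frame(comparison = paste0(a, ": with vs without clinical"),
                            auc_with = cmp$auc_a, auc_without = cmp$auc_b,
                            p_value = cmp$p_value, method = cmp$method)
  message(sprintf("%s: AUC %.3f -> %.3f with clinical data (p = %.3g)",
                  a, cmp$auc_b, cmp$auc_a, cmp$p_value))
}
write.csv(do.call(rbind, rows), "results/auc_models.csv", row.names = FALSE)
write.csv(do.call(rbind, delong), "results/auc_delong.csv", row.names = FALSE)

svg("results/roc_curves.svg", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
pal <- c(clinical_only = "gray40", density_only = "steelblue",
         contrast_only = "seagreen", concatenated_only = "firebrick")
plot(NA, xlim = 0:1, ylim = 0:1, xlab = "false positive rate",
     ylab = "true positive rate", main = "imaging / clinical models")
abline(0, 1, lty = 3)
for (nm in names(pal))
  lines(rocs[[nm]]$fpr, rocs[[nm]]$tpr, col = pal[nm], lwd = 2)
legend("bottomright", sprintf("%s (AUC %.2f)", names(pal),
                              vapply(rocs[names(pal)], `[[`, 0, "auc")),
       col = pal, lwd = 2, bty = "n", cex = 0.8)
plot(NA, xlim = 0:1, ylim = 0:1, xlab = "false positive rate",
     ylab = "true positive rate", main = "with clinical covariates")
abline(0, 1, lty = 3)
pal2 <- c(density_plus_clinical = "steelblue",
          contrast_plus_clinical = "seagreen",
          concatenated_plus_clinical = "firebrick")
for (nm in names(pal2))
  lines(rocs[[nm]]$fpr, rocs[[nm]]$tpr, col = pal2[nm], lwd = 2)
legend("bottomright", sprintf("%s (AUC %.2f)", names(pal2),
                              vapply(rocs[names(pal2)], `[[`, 0, "auc")),
       col = pal2, lwd = 2, bty = "n", cex = 0.8)
dev.off()
message("wrote results/auc_models.csv, results/auc_delong.csv, results/roc_curves.svg")
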