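# cemradial

Quantitative analysis of contrast-enhanced mammography (CEM) lesions for
researchers studying computer-aided discrimination of breast findings. A CEM
exam yields two co-registered images of a finding: a low-energy "density"
image (essentially a standard mammogram) and a recombined "contrast" image
reflecting iodine uptake. Malignant lesions concentrate both density and
enhancement nearer their core than benign ones; `cemradial` measures that
concentration and uses it to classify findings.

## Method

For each finding (a 300×300-px ROI pair plus a hand-drawn contour), the
pipeline:

1. computes the intensity-weighted **center of mass** of the contour-masked
   density image;
2. builds the **radial distribution histogram**: concentric equal-width
   bands around the center out to the farthest ROI corner; per band, summed
   intensity is divided by the band's pixel area and the values rescaled to
   unit sum — for the density image, the contrast image, and their
   concatenation;
3. classifies findings with a **penalized linear discriminant analysis**,
   `w = (S_w + λI)⁻¹(μ₊ − μ₋)`, under stratified 5-fold × 5-repetition
   cross-validation (λ tuned by inner 3-fold CV), with paired t-tests on the
   25 per-fold accuracies between feature sets and a permuted-label baseline
   under the identical protocol;
4. fits **logistic models**: odds ratios for clinical covariates (age, race,
   personal history of breast cancer, menopausal status, breast density,
   background parenchymal enhancement) and combined models coupling the
   cross-validated PLDA score with the clinical covariates, compared by
   AUC-ROC with DeLong's test.

Tasks: malignant vs. benign (high-risk and atypia findings excluded) and
invasive vs. non-invasive malignancy.

Because real CEM cohorts are not distributable, the package includes a fully
synthetic cohort generator (images with class-dependent radial decay,
contour annotations, and covariates with a designed age–malignancy odds
ratio of 1.07/year) so the entire pipeline is testable end to end. See
`vignettes/cem-radial-methods.Rmd` for the model, its parameters, and what
the synthetic cohort does and does not emulate.

## Worked example

```r
library(cemradial)
bundle <- run_pipeline(run_config(cohort = cohort_config(seed = 1), seed = 1))
bundle$tasks$malignant_vs_benign$metric_table
```

On the default synthetic cohort (159 findings, seed 1) this prints, for the
malignant-vs-benign task:

```
                task       feature_set accuracy sensitivity specificity     f1   kappa
 malignant_vs_benign           density   0.9269      0.8697      0.9747 0.9154  0.8514
 malignant_vs_benign          contrast   0.8014      0.6848      0.8987 0.7584  0.5931
 malignant_vs_benign      concatenated   0.9407      0.9121      0.9646 0.9330  0.8799
 malignant_vs_benign permuted_baseline   0.5366      0.0273      0.9620 0.0492 -0.0115
```

(values rounded to 4 decimals)

i.e. density histograms alone classify at 92.7%, concatenating the contrast
histogram raises that to 94.1%, and the permuted-label baseline sits near
chance (53.7%). `bundle$models$auc_table` shows the corresponding
cross-validated AUCs (concatenated imaging 0.966, clinical covariates alone
0.631, combined 0.972), and `bundle$models$univariable` the covariate odds
ratios. These synthetic-cohort numbers track the generator's designed class
separation, not real-data performance.

The numbered scripts under `analysis/` run the same pipeline step by step —
`01_simulate.R` (cohort to disk), `02_features.R` (feature matrices and mean
radial profiles), `03_classify.R` (CV and t-tests), `04_models.R` (odds
ratios, AUCs, ROC figures), `05_report.R` (single-command bundle) — writing
their tables and figures under `results/`.

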