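---
title: "Radial distribution analysis of contrast-enhanced mammography lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial distribution analysis of CEM lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemradial)
```

## The problem and the model

Contrast-enhanced mammography (CEM) produces two co-registered views of a
breast finding: a low-energy image that is essentially a standard mammogram
(the **density** channel) and a recombined image showing iodinated-contrast
uptake, a proxy for lesion vascularity (the **contrast** channel).
Malignant lesions tend to concentrate both tissue density and contrast
enhancement near their core more than benign ones do. `cemradial` turns
that observation into a quantitative pipeline:

1. **Radial distribution features.** For each finding the center of mass is
   computed from the contour-masked density image (the contour is a
   hand-drawn region of interest; the same center is reused for the
   contrast channel, since the channels are co-registered). Concentric
   equal-width bands are laid from the center out to the farthest corner of
   the rectangular ROI. Per band, intensity is summed, divided by the
   band's empirical pixel area (which correctly handles bands clipped by
   the image border), and the resulting per-area masses are rescaled to
   unit sum. The histogram of these values over bands is the feature
   vector; the density and contrast histograms can also be concatenated.
2. **Classification.** A penalized linear discriminant analysis (PLDA)
   separates the classes. Radial-histogram bins are many and strongly
   correlated, so the within-class covariance $S_w$ is ridge-regularized:
   $w = (S_w + \lambda I)^{-1}(\mu_+ - \mu_-)$, with the decision threshold
   at the midpoint of the projected class means shifted by the log prior
   odds. Evaluation uses stratified 5-fold cross-validation with 5
   repetitions; $\lambda$ is chosen per training split by an inner 3-fold
   cross-validation over the grid $10^{-4}, \dots, 10^{2}$.
3. **Statistical models.** Logistic regressions give odds ratios for the
   clinical covariates (univariable and multivariable), and combined models
   couple the cross-validated PLDA discriminant score with the clinical
   covariates; models are compared by AUC-ROC with DeLong's test for
   correlated curves.

Two tasks are supported: malignant vs. benign findings (high-risk and
atypia findings are excluded), and invasive vs. non-invasive malignancy
(malignant findings only).

## The synthetic cohort generator

Real CEM images with pathology labels are not distributable, so the package
ships a generator that emulates the statistical structure the analysis
assumes, and every pipeline stage is exercised on it.

**Lesion model.** A lesion is an isotropic exponential kernel
$A \cdot e^{-d r}$ at a jittered interior position on top of a smooth
low-frequency background field plus i.i.d. Gaussian noise, clipped to the
16-bit range. The decay rate $d$ encodes the biology: benign lesions
default to $d = 0.04$/px, malignant to $d = 0.08$/px, and invasive
malignancies add $0.04$/px on the density channel only — so the density
channel alone carries the invasive/non-invasive signal, while the contrast
channel adds independent malignant/benign information. Per-case decays are
jittered log-normally (SD 0.30 on the log scale) so the classes overlap,
as real cohorts do; high-risk and atypia findings render with benign image
parameters, existing chiefly to exercise the exclusion logic.

The peak amplitude scales proportionally with the drawn decay rate
(`lesion_amplitude` is the peak of a benign-decay lesion, 40% of full scale
by default). This choice matters: with a fixed peak, a faster-decaying
lesion would simply contain *less* mass everywhere, including the innermost
band once the background dominates the image total, inverting the intended
ordering. Scaling amplitude with decay gives concentration — a brighter,
tighter core over a common background — which is the phenomenon the radial
histogram is designed to detect.

**Contours.** The stored contour is the half-maximum isocontour of the
noiseless kernel, polygonized at 64 vertices and clamped to the image
bounds. Real contours are hand-drawn; any closed curve containing the core
works, because the contour only determines the center of mass (by default
the histogram support is the full rectangular ROI; a contour-restricted
mode exists).

**Covariates.** Ages are Gaussian (SD 10 y) with the malignant mean shifted
by $\sigma^2 \log(\mathrm{OR})$, which makes the malignancy log-odds
*exactly* linear in age with slope $\log(\mathrm{OR})$ — the default
OR 1.07/year is the design value the logistic stage must recover.
Menopausal status thresholds age plus noise at 51 y; race, personal
history, breast density and background parenchymal enhancement (BPE) are
categorical draws matching the 159-finding design margins (e.g. 125/159
White, 94/159 post-menopausal, 70/10/8/71 benign/high-risk/atypia/malignant
with 51/71 invasive). BPE scales the background enhancement field on the
contrast channel (1×/2×/4× for minimal/moderate/marked).

**What the generator does not emulate.** Dual-energy physics, view
geometry, anatomic texture (the background is a smooth Gaussian field, not
fibroglandular structure), lesion anisotropy and spiculation (an anisotropy
factor exists but defaults to 1), pixel spacing and lesion-size
distributions (physical units are left arbitrary), and multi-lesion
images. Passing tests therefore certify
the *machinery* — feature correctness, classifier behavior, protocol
validity, link recovery — not clinical performance on real CEM data, whose
accuracies will differ from the synthetic cohort's.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_findings` | 159 | cohort size |
| `class_mix` | 70/10/8/71 of 159 | benign / high-risk / atypia / malignant |
| `invasive_fraction` | 51/71 | invasive share of malignancies |
| `image_size` | 300 px | ROI side length |
| `decay_benign`, `decay_malignant` | 0.04, 0.08 /px | radial decay rates |
| `decay_invasive_extra` | 0.04 /px | added for invasive, density channel only |
| `decay_jitter_sd` | 0.30 | log-normal per-case decay spread |
| `contrast_snr` | 4 | lesion vs. background enhancement amplitude ratio |
| `noise_sd` | 0.02 of full scale | additive Gaussian noise |
| `age_or_per_year` | 1.07 | age-malignancy odds link |
| `n_bands` | 32 | histogram bands per channel |

The number of bands is not dictated by anything physical; 32 gives band
widths of ~6.6 px on a 300-px ROI, and the feature-correctness properties
are asserted for 8–64 bands. Radial band edges are *relative* (per-case
span to the farthest ROI corner) so all histograms share one length
regardless of where the center falls; fixed pixel-width bands are available
via `band_width`.

## Numerical and protocol choices

- **Pixel convention:** 0-based row/column coordinates with pixel centers
  at integers; point-in-polygon rasterization uses the even-odd rule with
  boundary pixels included.
- **Band assignment:** half-open intervals $[e_b, e_{b+1})$ with the last
  band closed; an empty band (possible only in unusual geometries) yields
  value 0 with a warning; more bands than the radial extent in pixels is an
  error.
- **Normalization chain:** area-normalize then rescale to unit sum
  (default); the area-only chain is exposed via `normalize = "area"` since
  the exact original chain is underdetermined. Unit-sum rescaling makes
  lesions comparable regardless of exposure.
- **PLDA ties:** scores exactly at the threshold go to the negative class;
  inner-CV penalty ties go to the smallest penalty (closest to classical
  LDA). With penalty 0 and singular scatter the fit refuses with an
  instruction to use a positive penalty.
- **Fold sharing:** all feature sets of one task share fold assignments, so
  the paired t-test on the 25 per-fold accuracies is valid. An optional
  Nadeau–Bengio variance correction is available because repeated-CV
  training sets overlap, making the naive paired test anti-conservative.
- **Random-classifier baseline:** PLDA retrained on once-permuted labels
  under the identical protocol (folds included) — an honest empirical
  chance reference that typically lands near, often slightly below, the
  majority-class rate.
- **Combined models:** only cross-validated out-of-fold discriminant
  scores may enter (enforced via score provenance); the headline AUC comes
  from out-of-fold predicted probabilities of the logistic model under the
  same fold scheme, with the apparent (in-sample) AUC reported alongside.
  Separated logistic fits are flagged rather than reported silently, with
  an optional ridge refit.
- **AUC comparison:** DeLong's test for correlated curves, with a seeded
  bootstrap fallback when the DeLong variance degenerates.
- **BPE** enters the odds-ratio regressions but not the combined
  predictive models, whose clinical covariate set is age, race, history,
  menopausal status and breast density.
- **Atypia:** excluded from the malignant-vs-benign task alongside
  high-risk findings (they are neither pathology group); a switch
  (`include_atypia_as_benign`) retains them as benign.
- **Rounding:** summary percentages round half-up to one decimal, the
  convention of clinical characteristic tables (base R's round-half-even
  would print 40.25% as 40.2%).

## Reproducibility and problem sizes

Everything is driven by explicit integer seeds: the same `cohort_config`
regenerates bit-identical images and metadata, and the same `run_config`
produces byte-identical report tables (asserted in the test suite by
hashing two independent runs). The default end-to-end run — 159 findings at
300×300 px, 32 bands, three feature sets × two tasks under 5×5 CV plus the
model stage — completes in well under a minute; the heavier multi-seed
properties in the test suite (20-cohort ordering checks, DeLong null
calibration at 500 replicates) are sized to run in a few minutes total.

## Worked example

```{r example, eval = FALSE}
library(cemradial)
bundle <- run_pipeline(run_config(cohort = cohort_config(seed = 1),
                                  seed = 1))
bundle$tasks$malignant_vs_benign$metric_table
bundle$models$auc_table
```

The numbered scripts under `analysis/` walk the same pipeline step by step
(simulate → features → classify → models → one-command report), writing
tables and figures under `results/`.

## Known limitations

- Synthetic accuracies are far higher than anything achievable on real CEM
  findings; the generator's class separation is controlled by
  `decay_jitter_sd` and `noise_sd`, not fit to data.
- The ridge-penalized scatter is one member of the penalized-LDA family;
  sparse/fused variants are not implemented.
- The invasive-vs-noninvasive task inherits a small negative class (20 of
  71), so its per-fold metrics are noisy at the default cohort size.
- The rectangular box ROI is carried for provenance but unused: the images
  already are the box crop.
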