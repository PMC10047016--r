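#' Synthetic CEM cohort configuration
#'
#' Bundles every parameter of the synthetic cohort generator: class mix,
#' lesion radial-decay rates per class, background/noise levels, the
#' age-malignancy odds link, and the covariate distributions. The defaults
#' encode the study conditions the analysis is designed around: 159 findings
#' with 70 benign / 10 high-risk / 8 atypia / 71 malignant, 51 of the 71
#' malignancies invasive, malignant lesions more centrally concentrated than
#' benign ones on both channels, and a univariable odds ratio of 1.07 per
#' year of age for malignancy.
#'
#' Lesion model: intensity ~ amplitude * exp(-decay * r) on top of a smooth
#' background plus i.i.d. Gaussian noise. `decay_malignant > decay_benign`
#' makes malignant lesions more centrally concentrated. Invasive malignancies
#' get `decay_invasive_extra` added on the density channel only. Per-case
#' decay is jittered log-normally (`decay_jitter_sd`) so the classes overlap,
#' as real cohorts do.
#'
#' @param n_findings number of findings (>= 2)
#' @param class_mix named proportions over benign / high_risk / atypia /
#'   malignant; must sum to 1
#' @param invasive_fraction fraction of malignant findings that are invasive
#' @param image_size ROI side length in pixels (>= 16)
#' @param decay_benign,decay_malignant radial decay rates (1/px), malignant
#'   strictly larger than benign
#' @param decay_invasive_extra decay added for invasive lesions on the
#'   density channel
#' @param decay_jitter_sd SD of the log-normal per-case decay jitter
#'   (0 = identical lesions within a class)
#' @param lesion_amplitude peak intensity of a benign-decay lesion on the
#'   density channel, as a fraction of full scale; actual peak amplitude
#'   scales proportionally with the drawn decay rate so faster-decaying
#'   lesions have a brighter core (central concentration) rather than simply
#'   less mass
#' @param background_level mean background intensity as a fraction of full
#'   scale
#' @param background_texture_sd SD of the smooth background texture on the
#'   density channel, fraction of full scale
#' @param contrast_snr ratio of lesion enhancement amplitude to background
#'   enhancement amplitude on the contrast channel
#' @param bg_enhance_amplitude background parenchymal enhancement amplitude
#'   (fraction of full scale) for minimal BPE; scaled up for moderate/marked
#' @param noise_sd additive Gaussian noise SD, fraction of full scale
#' @param anisotropy axis ratio of the lesion kernel (1 = isotropic)
#' @param age_or_per_year odds ratio linking one year of age to malignancy
#' @param covariate_params list of covariate distributions; see Details
#' @param seed integer master seed
#'
#' @details `covariate_params` accepts: `age_mean_base`, `age_sd` (years;
#'   malignant ages are shifted by `age_sd^2 * log(age_or_per_year)` so the
#'   malignancy log-odds is exactly linear in age), `menopause_age`,
#'   `menopause_noise_sd`, `race_probs`, `history_p`, `density_probs`
#'   (fatty/scattered/heterogeneously dense/extremely dense), `bpe_probs`
#'   (minimal/moderate/marked).
#'
#' @return an object of class `cohort_config` (a validated list)
#' @export
cohort_config <- function(n_findings = 159,
                          class_mix = c(benign = 70 / 159,
                                        high_risk = 10 / 159,
                                        atypia = 8 / 159,
                                        malignant = 71 / 159),
                          invasive_fraction = 51 / 71,
                          image_size = 300,
                          decay_benign = 0.04,
                          decay_malignant = 0.08,
                          decay_invasive_extra = 0.04,
                          decay_jitter_sd = 0.30,
                          lesion_amplitude = 0.40,
                          background_level = 0.20,
                          background_texture_sd = 0.04,
                          contrast_snr = 4,
                          bg_enhance_amplitude = 0.05,
                          noise_sd = 0.02,
                          anisotropy = 1,
                          age_or_per_year = 1.07,
                          covariate_params = list(),
                          seed = 1L) {
  defaults <- list(
    age_mean_base = 54, age_sd = 10,
    menopause_age = 51, menopause_noise_sd = 3,
    race_probs = c("White" = 125 / 159, "Black" = 23 / 159,
                   "Asian or Pacific Islander" = 4 / 159,
                   "Other Race or Race Not Recorded" = 7 / 159),
    history_p = 60 / 159,
    density_probs = c("Fatty" = 10 / 159, "Scattered" = 69 / 159,
                      "Heterogeneously Dense" = 58 / 159,
                      "Extremely Dense" = 22 / 159),
    bpe_probs = c("Minimal" = 117 / 159, "Moderate" = 36 / 159,
                  "Marked" = 6 / 159)
  )
  covariate_params <- utils::modifyList(defaults, covariate_params)

  cfg <- list(
    n_findings = as.integer(n_findings), class_mix = class_mix,
    invasive_fraction = invasive_fraction,
    image_size = as.integer(image_size),
    decay_benign = decay_benign, decay_malignant = decay_malignant,
    decay_invasive_extra = decay_invasive_extra,
    decay_jitter_sd = decay_jitter_sd,
    lesion_amplitude = lesion_amplitude,
    background_level = background_level,
    background_texture_sd = background_texture_sd,
    contrast_snr = contrast_snr,
    bg_enhance_amplitude = bg_enhance_amplitude,
    noise_sd = noise_sd, anisotropy = anisotropy,
    age_or_per_year = age_or_per_year,
    covariate_params = covariate_params, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param cfg a `cohort_config`
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_findings < 2L)
    stop("n_findings must be >= 2", call. = FALSE)
  if (cfg$image_size < 16L)
    stop("image_size must be >= 16", call. = FALSE)
  if (!setequal(names(cfg$class_mix), FINDING_CLASSES))
    stop("class_mix must be named over: ",
         paste(FINDING_CLASSES, collapse = ", "), call. = FALSE)
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1", call. = FALSE)
  if (any(c(cfg$decay_benign, cfg$decay_malignant) <= 0) ||
      cfg$decay_invasive_extra < 0)
    stop("decay parameters must be positive", call. = FALSE)
  if (cfg$decay_malignant <= cfg$decay_benign)
    stop("decay_malignant must exceed decay_benign ",
         "(malignant lesions are more centrally concentrated)", call. = FALSE)
  if (cfg$invasive_fraction < 0 || cfg$invasive_fraction > 1)
    stop("invasive_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$age_or_per_year <= 0)
    stop("age_or_per_year must be positive", call. = FALSE)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic CEM cohort configuration\n")
  cat(sprintf("  n_findings: %d, image %dx%d px, seed %d\n",
              x$n_findings, x$image_size, x$image_size, x$seed))
  cat(sprintf("  class mix: %s\n",
              paste(sprintf("%s %.3f", names(x$class_mix), x$class_mix),
                    collapse = ", ")))
  cat(sprintf("  decay (1/px): benign %.3f, malignant %.3f (+%.3f invasive), jitter sd %.2f\n",
              x$decay_benign, x$decay_malignant, x$decay_invasive_extra,
              x$decay_jitter_sd))
  cat(sprintf("  contrast SNR %.2f, noise sd %.3f, age OR/yr %.3f\n",
              x$contrast_snr, x$noise_sd, x$age_or_per_year))
  invisible(x)
}
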