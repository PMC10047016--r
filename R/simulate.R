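#' Generate one synthetic lesion ROI image
#'
#' Renders a single-channel 16-bit grayscale ROI containing one lesion with an
#' isotropic (or mildly anisotropic) exponential radial profile
#' `amplitude * exp(-decay * r)` on top of a smooth background field plus
#' i.i.d. Gaussian noise, clipped at zero. Malignant lesions decay faster than
#' benign ones, i.e. their intensity is more concentrated near the center of
#' mass; invasive malignancies decay faster still on the density channel.
#' Draws from the current R random stream: seed before calling for
#' reproducibility.
#'
#' @param class_label one of `"benign"`, `"high_risk"`, `"atypia"`,
#'   `"malignant"` (high-risk and atypia render with benign image parameters)
#' @param channel `"density"` (low-energy image) or `"contrast"`
#'   (recombined image)
#' @param params a [cohort_config()]
#' @param invasive logical; adds `decay_invasive_extra` on the density channel
#' @param bpe background parenchymal enhancement level
#'   (`"Minimal"`/`"Moderate"`/`"Marked"`); scales the background enhancement
#'   field on the contrast channel
#' @param center optional lesion center `c(row, col)` in 0-based pixel
#'   coordinates; drawn uniformly in the central quarter of the ROI when NULL.
#'   Pass the same center for both channels of one finding.
#' @param decay optional fixed decay rate (1/px), overriding the class draw;
#'   used for noise-free templates
#' @return list with `image` (integer-valued matrix, 0..65535), `contour`
#'   (data.frame of 64 x,y vertices at the half-maximum isocontour of the
#'   noiseless kernel, 0-based), `center`, `decay`
#' @export
generate_lesion_image <- function(class_label, channel, params,
                                  invasive = FALSE, bpe = "Minimal",
                                  center = NULL, decay = NULL) {
  if (!class_label %in% FINDING_CLASSES)
    stop("unknown finding class: ", class_label, call. = FALSE)
  channel <- match.arg(channel, c("density", "contrast"))
  validate_cohort_config(params)
  s <- params$image_size

  base_decay <- if (class_label == "malignant") {
    params$decay_malignant +
      (if (isTRUE(invasive) && channel == "density")
         params$decay_invasive_extra else 0)
  } else {
    params$decay_benign
  }
  if (is.null(decay))
    decay <- base_decay * exp(stats::rnorm(1, 0, params$decay_jitter_sd))
  if (!is.finite(decay) || decay <= 0)
    stop("lesion decay rate must be positive", call. = FALSE)

  if (is.null(center)) {
    mid <- (s - 1) / 2
    center <- mid + stats::runif(2, -s / 8, s / 8)
  }

  # squared distance from the lesion center at every pixel center (0-based)
  dr <- (seq_len(s) - 1) - center[1]
  dc <- ((seq_len(s) - 1) - center[2]) * params$anisotropy
  r <- sqrt(outer(dr^2, dc^2, `+`))

  full <- FULL_SCALE
  bpe_scale <- c(Minimal = 1, Moderate = 2, Marked = 4)[[bpe]]
  # peak amplitude scales with the decay rate: faster-decaying lesions pack
  # a comparable mass into a brighter core, which is what makes malignant
  # lesions more centrally concentrated on top of a common background
  amp_gain <- decay / params$decay_benign
  if (channel == "density") {
    amp <- params$lesion_amplitude * full * amp_gain
    bg <- params$background_level * full +
      params$background_texture_sd * full * low_freq_field(s)
  } else {
    bg_amp <- params$bg_enhance_amplitude * bpe_scale * full
    amp <- params$contrast_snr * bg_amp * amp_gain
    bg <- params$background_level * full +
      bg_amp * low_freq_field(s)
  }

  img <- amp * exp(-decay * r) + bg +
    matrix(stats::rnorm(s * s, 0, params$noise_sd * full), s, s)
  img <- round(pmin(pmax(img, 0), full))

  # contour: half-maximum isocontour of the noiseless kernel (an ellipse of
  # effective radius log(2)/decay), polygonized at 64 vertices and clamped
  # to the image bounds
  rad <- log(2) / decay
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  contour <- data.frame(
    x = pmin(pmax(center[2] + rad * sin(theta) / params$anisotropy, 0), s - 1),
    y = pmin(pmax(center[1] + rad * cos(theta), 0), s - 1)
  )
  list(image = img, contour = contour,
       center = c(row = center[1], col = center[2]), decay = decay)
}

#' Generate clinical/demographic covariates for a set of findings
#'
#' Draws one metadata row per finding from the configured covariate
#' distributions. Age is drawn so that the log-odds of malignancy is exactly
#' linear in age with slope `log(age_or_per_year)`: non-malignant ages are
#' `N(age_mean_base, age_sd^2)` and malignant ages are shifted by
#' `age_sd^2 * log(age_or_per_year)` years (a Gaussian discriminant identity).
#' Menopausal status is a thresholded noisy function of age; race, personal
#' history of breast cancer, breast density category, and background
#' parenchymal enhancement come from the configured categorical
#' distributions. Uses the current R random stream.
#'
#' @param class_labels character vector of finding classes, already drawn
#' @param params a [cohort_config()]
#' @return data.frame with one row per finding: age, race, history,
#'   menopause, density_category, bpe
#' @export
generate_covariates <- function(class_labels, params) {
  n <- length(class_labels)
  if (n == 0L) stop("class_labels is empty", call. = FALSE)
  if (!all(class_labels %in% FINDING_CLASSES))
    stop("unknown finding class in class_labels", call. = FALSE)
  cp <- params$covariate_params
  malignant <- class_labels == "malignant"

  shift <- cp$age_sd^2 * log(params$age_or_per_year)
  age <- stats::rnorm(n, cp$age_mean_base + shift * malignant, cp$age_sd)
  menopause <- ifelse(
    age + stats::rnorm(n, 0, cp$menopause_noise_sd) > cp$menopause_age,
    "Post-Menopausal", "Pre-Menopausal")
  data.frame(
    age = age,
    race = sample(names(cp$race_probs), n, TRUE, cp$race_probs),
    history = stats::runif(n) < cp$history_p,
    menopause = menopause,
    density_category = sample(names(cp$density_probs), n, TRUE,
                              cp$density_probs),
    bpe = sample(names(cp$bpe_probs), n, TRUE, cp$bpe_probs),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic CEM cohort
#'
#' Draws finding classes from the configured mix, invasive status for
#' malignancies, clinical covariates, and paired density/contrast ROI images
#' with a shared lesion center per finding. Entirely determined by
#' `config$seed`: the same configuration reproduces the cohort bit for bit.
#'
#' @param config a [cohort_config()]
#' @return an object of class `synthetic_cohort`: `cases` (list; each with
#'   case_id, density_image, contrast_image, contour, box, class_label,
#'   invasive_flag, covariates), `metadata` (one data.frame row per case),
#'   `config_used`
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_findings
  classes <- sample(FINDING_CLASSES, n, TRUE,
                    config$class_mix[FINDING_CLASSES])
  invasive <- rep(NA, n)
  mal <- classes == "malignant"
  invasive[mal] <- stats::runif(sum(mal)) < config$invasive_fraction
  covs <- generate_covariates(classes, config)

  s <- config$image_size
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    mid <- (s - 1) / 2
    ctr <- mid + stats::runif(2, -s / 8, s / 8)
    den <- generate_lesion_image(classes[i], "density", config,
                                 invasive = isTRUE(invasive[i]),
                                 bpe = covs$bpe[i], center = ctr)
    con <- generate_lesion_image(classes[i], "contrast", config,
                                 invasive = isTRUE(invasive[i]),
                                 bpe = covs$bpe[i], center = ctr)
    cases[[i]] <- list(
      case_id = sprintf("case_%03d", i),
      density_image = den$image, contrast_image = con$image,
      contour = den$contour,
      box = c(row0 = 0, col0 = 0, row1 = s - 1, col1 = s - 1),
      class_label = classes[i], invasive_flag = invasive[i],
      covariates = covs[i, , drop = FALSE]
    )
  }
  metadata <- cbind(
    data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
               class = classes, invasive_flag = invasive,
               stringsAsFactors = FALSE),
    covs
  )
  structure(list(cases = cases, metadata = metadata, config_used = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(factor(x$metadata$class, FINDING_CLASSES))
  cat(sprintf("Synthetic CEM cohort: %d findings (%s), %dx%d px images\n",
              nrow(x$metadata),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$config_used$image_size, x$config_used$image_size))
  invisible(x)
}

#' Deterministic metadata table with the design cohort margins
#'
#' Builds a 159-row metadata table whose per-field counts are exactly the
#' demographic, imaging and pathology margins the synthetic generator's
#' defaults are calibrated to: 70 benign / 10 high-risk / 8 atypia / 71
#' malignant findings (51 invasive), 125/23/4/7 race levels, 60 with a
#' personal history of breast cancer, 94 post-menopausal, breast density
#' 10/69/58/22, background parenchymal enhancement 117/36/6 and finding
#' categories 64/45/32/9/8/1. Columns are filled margin-by-margin (the joint
#' distribution is unspecified), so the table is for count/percentage
#' summaries, not for fitting models. Ages are a fixed grid and carry no
#' class association.
#'
#' @return data.frame with the same columns as `synthetic_cohort$metadata`
#'   plus `finding_category`
#' @export
design_cohort_metadata <- function() {
  n <- 159L
  fill <- function(counts) rep(names(counts), times = counts)
  cls <- fill(c(benign = 70, high_risk = 10, atypia = 8, malignant = 71))
  invasive <- rep(NA, n)
  invasive[cls == "malignant"] <- rep(c(TRUE, FALSE), c(51, 20))
  data.frame(
    case_id = sprintf("case_%03d", seq_len(n)),
    class = cls, invasive_flag = invasive,
    age = seq(40, 75, length.out = n),
    race = fill(c("White" = 125, "Black" = 23,
                  "Asian or Pacific Islander" = 4,
                  "Other Race or Race Not Recorded" = 7)),
    history = rep(c(TRUE, FALSE), c(60, 99)),
    menopause = fill(c("Pre-Menopausal" = 65, "Post-Menopausal" = 94)),
    density_category = fill(c("Fatty" = 10, "Scattered" = 69,
                              "Heterogeneously Dense" = 58,
                              "Extremely Dense" = 22)),
    bpe = fill(c(Minimal = 117, Moderate = 36, Marked = 6)),
    finding_category = fill(c(
      "Mass" = 64, "Asymmetry" = 45, "Calcifications" = 32,
      "Architectural Distortion" = 9, "Non-Mass Enhancement" = 8,
      "Solitary Dilated Duct" = 1)),
    stringsAsFactors = FALSE
  )
}
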