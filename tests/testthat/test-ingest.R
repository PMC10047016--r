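test_that("write then read round-trips pixels, contours and covariates exactly", {
  coh <- simulate_cohort(tiny_config(seed = 21, n = 6, size = 32))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  expect_equal(nrow(manifest), 6)

  cases <- read_cohort(manifest_path)
  for (i in seq_along(cases)) {
    expect_identical(cases[[i]]$density_image, coh$cases[[i]]$density_image)
    expect_identical(cases[[i]]$contrast_image, coh$cases[[i]]$contrast_image)
    expect_equal(as.matrix(cases[[i]]$contour),
                 as.matrix(coh$cases[[i]]$contour), tolerance = 1e-12)
    expect_identical(cases[[i]]$class_label, coh$cases[[i]]$class_label)
    expect_equal(cases[[i]]$covariates$age, coh$cases[[i]]$covariates$age,
                 tolerance = 1e-12)
  }
  expect_true(file.exists(file.path(dir, "config.toml")))
})

test_that("manifest validation names the case with a missing file", {
  coh <- simulate_cohort(tiny_config(seed = 22, n = 4, size = 32))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  unlink(file.path(dir, manifest$contrast_path[2]))
  expect_error(validate_manifest(manifest, dir), "case_002")
})

test_that("read_case rejects malformed cases", {
  coh <- simulate_cohort(tiny_config(seed = 23, n = 4, size = 32))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)

  # channel shape mismatch
  bad <- manifest[1, , drop = FALSE]
  tiff::writeTIFF(matrix(0.5, 31, 32), file.path(dir, bad$contrast_path),
                  bits.per.sample = 16)
  expect_error(read_case(bad, dir), "31x32")

  # malignant case without an invasive flag
  i_mal <- which(manifest$class == "malignant")[1]
  skip_if(is.na(i_mal), "no malignant case in this tiny draw")
  row <- manifest[i_mal, , drop = FALSE]
  row$invasive_flag <- NA
  expect_error(read_case(row, dir), "invasive_flag")

  # unknown category level is named
  row2 <- manifest[2, , drop = FALSE]
  row2$density_category <- "Mostly Cloudy"
  expect_error(read_case(row2, dir), "Mostly Cloudy")
})

test_that("density categories dichotomize as dense vs non-dense", {
  meta <- data.frame(age = 50, race = "White", history = FALSE,
                     menopause = "Pre-Menopausal",
                     density_category = c("Fatty", "Scattered",
                                          "Heterogeneously Dense",
                                          "Extremely Dense"),
                     bpe = "Minimal")
  coded <- code_covariates(meta)
  expect_equal(coded$dense, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("square contour rasterizes to the point-in-polygon oracle count", {
  sq <- data.frame(x = c(1, 1, 4, 4), y = c(1, 4, 4, 1))
  msk <- rasterize_contour(sq, c(6, 6))
  expect_equal(sum(msk), 16)  # pixel centers with 1 <= x,y <= 4, inclusive
  # whole-image polygon -> all-true mask
  full <- data.frame(x = c(0, 0, 5, 5), y = c(0, 5, 5, 0))
  expect_true(all(rasterize_contour(full, c(6, 6))))
  expect_error(rasterize_contour(data.frame(x = c(0, 1), y = c(0, 1)),
                                 c(6, 6)), "degenerate")
  expect_error(rasterize_contour(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)),
                                 c(6, 6)), "zero area")
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(31)
  for (rep in 1:20) {
    size <- sample(8:64, 1)
    poly <- random_polygon(n_vert = sample(5:12, 1),
                           center = c(size / 2 + 0.13, size / 2 - 0.21),
                           rad = size / 3)
    msk <- rasterize_contour(poly, c(size, size))
    px <- rep(0:(size - 1), each = size)
    py <- rep(0:(size - 1), times = size)
    inside <- mgcv::in.out(cbind(c(poly$x, poly$x[1]), c(poly$y, poly$y[1])),
                           cbind(px, py))
    expect_identical(as.vector(msk), inside)
  }
})

test_that("task filtering keeps the right classes and logs exclusions", {
  meta <- design_cohort_metadata()
  flt <- exclusion_filter(meta, "malignant_vs_benign")
  expect_equal(nrow(flt$cases), 141)  # 70 benign + 71 malignant
  expect_equal(sum(flt$labels), 71)
  expect_equal(nrow(flt$exclusion_log), 18)
  expect_setequal(unique(flt$exclusion_log$class), c("high_risk", "atypia"))

  flt2 <- exclusion_filter(meta, "invasive_vs_noninvasive")
  expect_equal(nrow(flt2$cases), 71)
  expect_equal(sum(flt2$labels), 51)

  flt3 <- exclusion_filter(meta, "malignant_vs_benign",
                           include_atypia_as_benign = TRUE)
  expect_equal(nrow(flt3$cases), 149)

  allhr <- data.frame(case_id = sprintf("c%d", 1:10), class = "high_risk",
                      invasive_flag = NA)
  expect_error(exclusion_filter(allhr, "malignant_vs_benign"),
               "fewer than 2")
})
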