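test_that("center of mass matches hand cases and the brute-force oracle", {
  img <- matrix(0, 10, 10)
  img[8, 4] <- 3  # 0-based (7, 3)
  expect_equal(center_of_mass(img), c(row = 7, col = 3))

  img2 <- matrix(0, 4, 4)
  img2[2, 2] <- 1; img2[2, 3] <- 1  # 0-based (1,1) and (1,2)
  expect_equal(center_of_mass(img2), c(row = 1, col = 1.5))

  set.seed(41)
  for (rep in 1:10) {
    im <- matrix(runif(81), 9, 9)
    msk <- matrix(runif(81) < 0.7, 9, 9)
    msk[5, 5] <- TRUE
    expect_equal(center_of_mass(im, msk), com_oracle(im, msk),
                 tolerance = 1e-12)
  }
  expect_error(center_of_mass(matrix(0, 5, 5)), "degenerate")
  expect_error(center_of_mass(matrix(1, 5, 5), matrix(FALSE, 5, 5)),
               "degenerate")
})

test_that("radial histogram reproduces hand cases", {
  # constant image: per-area mass constant, so values are uniform
  h <- radial_histogram(matrix(1, 21, 21), c(10, 10), n_bands = 5)
  expect_equal(h$values, rep(1 / 5, 5), tolerance = 1e-12)

  # all intensity at the center pixel
  img <- matrix(0, 21, 21); img[11, 11] <- 7
  h2 <- radial_histogram(img, c(10, 10), n_bands = 5)
  expect_equal(h2$values, c(1, 0, 0, 0, 0))
  expect_equal(h2$total_mass, 7)

  expect_error(radial_histogram(matrix(1, 21, 21), c(30, 10), 5), "outside")
  expect_error(radial_histogram(matrix(1, 21, 21), c(10, 10), 40), "exceeds")
  expect_error(radial_histogram(matrix(1, 21, 21), c(10, 10), 1), ">= 2")
})

test_that("radial histogram matches the per-pixel binning oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:12) {
    nr <- sample(5:32, 1); nc <- sample(5:32, 1)
    img <- matrix(runif(nr * nc), nr, nc)
    ctr <- c(runif(1, 0, nr - 1), runif(1, 0, nc - 1))
    for (b in c(2, 4, 5)) {
      h <- radial_histogram(img, ctr, b)
      o <- radial_oracle(img, ctr, b)
      expect_equal(h$values, o$values, tolerance = 1e-12)
      expect_equal(h$band_mass, o$mass, tolerance = 1e-12)
      expect_equal(h$band_area, o$area)
      # conservation: band masses sum to the total image intensity
      expect_equal(sum(h$band_mass), sum(img), tolerance = 1e-12)
    }
  }
})

test_that("histogram is invariant to rotation and intensity scaling", {
  set.seed(43)
  # 90-degree rotation about the center of an odd-sized image permutes the
  # pixel grid while preserving distances to the center exactly, so the
  # histogram is unchanged for any image
  img <- matrix(runif(29 * 29), 29, 29)
  ctr <- c(14, 14)
  h <- radial_histogram(img, ctr, 8)
  rot <- t(img[29:1, ])  # 90-degree rotation
  h_rot <- radial_histogram(rot, ctr, 8)
  expect_equal(h$values, h_rot$values, tolerance = 1e-12)

  h_scaled <- radial_histogram(3.7 * img, ctr, 8)
  expect_equal(h_scaled$values, h$values, tolerance = 1e-12)
  expect_equal(h_scaled$total_mass, 3.7 * h$total_mass, tolerance = 1e-12)
})

test_that("area-only normalization chain is exposed alongside the default", {
  set.seed(44)
  img <- matrix(runif(100), 10, 10)
  h_area <- radial_histogram(img, c(4.5, 4.5), 4, normalize = "area")
  h_unit <- radial_histogram(img, c(4.5, 4.5), 4)
  expect_equal(h_unit$values, h_area$values / sum(h_area$values),
               tolerance = 1e-12)
  expect_equal(sum(h_unit$values), 1, tolerance = 1e-12)
})

test_that("concatenation stacks blocks without renormalizing", {
  set.seed(45)
  img <- matrix(runif(100), 10, 10)
  hd <- radial_histogram(img, c(4.5, 4.5), 4, channel = "density")
  hc <- radial_histogram(img * 2 + 1, c(4.5, 4.5), 4, channel = "contrast")
  v <- concatenate_histograms(hd, hc)
  expect_length(v, 8)
  expect_equal(unname(v[1:4]), hd$values)
  expect_equal(unname(v[5:8]), hc$values)
  expect_equal(sum(v[1:4]), 1, tolerance = 1e-12)
  expect_equal(sum(v[5:8]), 1, tolerance = 1e-12)
  h5 <- radial_histogram(img, c(4.5, 4.5), 5)
  expect_error(concatenate_histograms(hd, h5), "band counts differ")
})

test_that("class-average profiles average per bin and order malignant first band above benign", {
  m <- rbind(c(1, 0), c(0, 1))
  avg <- class_average_profile(m, c("a", "b"))
  expect_equal(unname(avg["a", ]), c(1, 0))
  one_class <- class_average_profile(rbind(c(0.5, 0.5), c(0.5, 0.5),
                                           c(1, 0)), c("x", "x", "y"))
  expect_equal(unname(one_class["x", ]), c(0.5, 0.5))
  expect_error(class_average_profile(m, c("a", "a")), "two classes")

  # noiseless class templates: the faster-decaying malignant template has
  # strictly more mass in band 0
  cfg <- cohort_config(n_findings = 4, image_size = 64, noise_sd = 0,
                       background_level = 0, background_texture_sd = 0,
                       bg_enhance_amplitude = 1e-6, decay_jitter_sd = 0)
  set.seed(46)
  ctr <- c(31.5, 31.5)
  mal <- generate_lesion_image("malignant", "density", cfg, center = ctr)
  ben <- generate_lesion_image("benign", "density", cfg, center = ctr)
  hm <- radial_histogram(mal$image, ctr, 16)
  hb <- radial_histogram(ben$image, ctr, 16)
  expect_gt(hm$values[1], hb$values[1])
})

test_that("cohort mean profiles put malignant above benign in the innermost band", {
  coh <- simulate_cohort(cohort_config(n_findings = 120, image_size = 96,
                                       seed = 48))
  flt <- exclusion_filter(coh$cases, "malignant_vs_benign")
  f <- cohort_features(flt$cases, 16)
  grp <- factor(flt$labels, c(0, 1), c("benign", "malignant"))
  for (ch in c("density", "contrast")) {
    m <- class_average_profile(lapply(f$histograms, `[[`, ch), grp)
    expect_gt(m["malignant", 1], m["benign", 1])
  }
})

test_that("cohort features share the density-derived center across channels", {
  coh <- simulate_cohort(tiny_config(seed = 47, n = 6, size = 48))
  f <- cohort_features(coh$cases, n_bands = 8)
  expect_equal(dim(f$density), c(6, 8))
  expect_equal(dim(f$concatenated), c(6, 16))
  expect_identical(f$concatenated[, 1:8], f$density)
  expect_identical(f$concatenated[, 9:16], f$contrast)
  for (i in 1:6)
    expect_equal(f$histograms[[i]]$density$center,
                 f$histograms[[i]]$contrast$center)
})
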