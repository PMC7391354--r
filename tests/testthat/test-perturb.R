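test_that("zero amplitude returns the input mask unchanged", {
  les <- disc_lesion()
  p <- perturbation_params(amplitude = 0)
  expect_identical(perturb_mask(les$mask, p, 1, 1), les$mask)
})

test_that("sub-millimetre perturbation of a 10 mm disc keeps Dice in the expected band", {
  # band frozen from a 100-draw Monte-Carlo run of the signed-distance
  # perturbation before the main build
  les <- disc_lesion(radius = 10)
  p <- perturbation_params(amplitude = 0.5, corr_len = 4)
  d <- vapply(1:100, function(s) dice(perturb_mask(les$mask, p, 1, s), les$mask),
              numeric(1))
  expect_gte(median(d), 0.85)
  expect_lte(median(d), 0.99)
})

test_that("multi-component input masks are rejected", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE
  m[12:15, 12:15] <- TRUE
  expect_error(perturb_mask(m, perturbation_params(), 1, 1), "single connected")
  expect_error(perturb_mask(matrix(FALSE, 5, 5), perturbation_params(), 1, 1),
               "empty")
})

test_that("perturbed masks are deterministic in the seed and single-component", {
  les <- textured_lesion()
  p <- perturbation_params(amplitude = 2, corr_len = 4)
  a <- perturb_mask(les$mask, p, 1, 11)
  expect_identical(a, perturb_mask(les$mask, p, 1, 11))
  for (s in 1:10) {
    expect_equal(radstab:::n_components(perturb_mask(les$mask, p, 1, s)), 1)
  }
})

test_that("rater sets honour size, acceptance rule and determinism", {
  les <- disc_lesion()
  p <- perturbation_params(amplitude = 2, corr_len = 4, accept_threshold = 0.3)
  rs <- sample_rater_set(les$mask, p, k = 25, spacing = 1, seed = 5)
  expect_length(rs, 25)
  d <- vapply(rs, function(m) dice(m, les$mask), numeric(1))
  expect_true(all(d > 0.3))
  rs2 <- sample_rater_set(les$mask, p, k = 25, spacing = 1, seed = 5)
  expect_identical(rs, rs2)
})

test_that("unreachable acceptance thresholds raise a slot-naming error", {
  les <- disc_lesion()
  p <- perturbation_params(amplitude = 12, corr_len = 4,
                           accept_threshold = 0.99, max_attempts = 5)
  expect_error(sample_rater_set(les$mask, p, k = 2, spacing = 1, seed = 1),
               "slot")
})

test_that("median pairwise Dice decreases monotonically with amplitude", {
  les <- disc_lesion()
  amps <- c(0.5, 1, 2, 4, 8)
  med <- vapply(amps, function(a) {
    p <- perturbation_params(amplitude = a, corr_len = 4)
    d <- vapply(1:50, function(s) dice(perturb_mask(les$mask, p, 1, s), les$mask),
                numeric(1))
    median(d)
  }, numeric(1))
  expect_lt(cor(amps, med, method = "spearman"), 0)
  expect_true(all(diff(med) <= 0))
})

test_that("amplitude calibration hits the target on a held-out seed and is monotone", {
  les <- disc_lesion()
  base <- perturbation_params(corr_len = 4)
  cal87 <- calibrate_amplitude(les$mask, 0.87, base, 1, seed = 21)
  rs <- sample_rater_set(les$mask, cal87, k = 20, spacing = 1, seed = 9901)
  dm <- pairwise_dice(rs)
  expect_lt(abs(median(dm[upper.tri(dm)]) - 0.87), 0.02)

  cal999 <- calibrate_amplitude(les$mask, 0.999, base, 1, seed = 21)
  expect_lt(cal999$amplitude, 0.2)

  cal80 <- calibrate_amplitude(les$mask, 0.80, base, 1, seed = 21)
  cal90 <- calibrate_amplitude(les$mask, 0.90, base, 1, seed = 21)
  expect_gt(cal80$amplitude, cal90$amplitude)
})

test_that("unattainable calibration targets report the achieved range", {
  les <- disc_lesion(radius = 4, image_size = 24)
  expect_error(
    calibrate_amplitude(les$mask, 0.05, perturbation_params(corr_len = 4), 1,
                        seed = 3, amplitude_range = c(1e-3, 2)),
    "unattainable")
})
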