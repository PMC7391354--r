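test_that("the hand sums-of-squares example is reproduced exactly", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  # MSB = 8, MSW = 0.5 -> ICC = 7.5 / 8.5
  expect_equal(icc_1_1(m), 7.5 / 8.5, tolerance = 1e-12)
})

test_that("duplicated-rater tables give ICC exactly 1, constant tables NA", {
  m <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_1_1(m), 1)
  expect_true(is.na(icc_1_1(matrix(3, 4, 3))))
})

test_that("the estimator matches an independent aov-based computation", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:20, 1); k <- sample(2:6, 1)
    m <- simulate_icc_table(n, k, sigma_b2 = runif(1, 0.2, 4),
                            sigma_w2 = runif(1, 0.05, 2))
    expect_equal(icc_1_1(m), oracle_icc_aov(m), tolerance = 1e-8)
  }
})

test_that("negative estimates are reported unfloored", {
  set.seed(8)
  found_negative <- FALSE
  for (rep in 1:50) {
    m <- simulate_icc_table(4, 2, sigma_b2 = 1e-4, sigma_w2 = 4)
    v <- icc_1_1(m)
    expect_equal(v, oracle_icc_aov(m), tolerance = 1e-8)
    if (v < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("ICC is invariant under affine transforms of the table", {
  set.seed(13)
  m <- simulate_icc_table(20, 4, 1, 0.3)
  base <- icc_1_1(m)
  expect_equal(icc_1_1(m + 57.3), base, tolerance = 1e-10)
  expect_equal(icc_1_1(m * -2.5), base, tolerance = 1e-10)
  expect_equal(icc_1_1(m * 0.01 + 1000), base, tolerance = 1e-10)
})

test_that("bootstrap CIs are deterministic, degenerate for perfect agreement", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  ci <- bootstrap_icc_ci(m, n_boot = 200, seed = 4)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(2)
  m2 <- simulate_icc_table(15, 4, 1, 0.3)
  ci_a <- bootstrap_icc_ci(m2, n_boot = 300, seed = 9)
  ci_b <- bootstrap_icc_ci(m2, n_boot = 300, seed = 9)
  expect_identical(ci_a, ci_b)
  ci_c <- bootstrap_icc_ci(m2, n_boot = 300, seed = 10)
  expect_false(identical(ci_a, ci_c))
  expect_lte(ci_a[["low"]], icc_1_1(m2))
})

test_that("icc_table flags constant features instead of dropping them", {
  set.seed(21)
  feats <- tidyr::expand_grid(lesion_id = sprintf("l%02d", 1:8),
                              rater_id = sprintf("r%d", 1:3))
  feats$firstorder_Mean <- rnorm(24, rep(1:8, each = 3), 0.1)
  feats$shape_Sphericity <- 0.9   # constant -> undefined
  tab <- icc_table(feats, n_boot = 100, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$icc[tab$feature == "shape_Sphericity"]))
  expect_equal(tab$flag[tab$feature == "shape_Sphericity"], "undefined")
  expect_gt(tab$icc[tab$feature == "firstorder_Mean"], 0.9)
  expect_equal(tab$category, c("firstorder", "shape"))
})

test_that("bootstrap seed changes the CI but never the point estimate", {
  set.seed(77)
  feats <- tidyr::expand_grid(lesion_id = sprintf("l%02d", 1:10),
                              rater_id = sprintf("r%d", 1:4))
  feats$glcm_Contrast <- rnorm(40, rep(seq_len(10), each = 4), 0.5)
  t1 <- icc_table(feats, n_boot = 150, seed = 1)
  t2 <- icc_table(feats, n_boot = 150, seed = 2)
  expect_identical(t1$icc, t2$icc)
  expect_false(identical(t1$ci_low, t2$ci_low))
})

test_that("category summaries average defined ICCs and count exceedances", {
  recs <- tibble::tibble(
    feature = paste0("f", 1:5),
    category = c("glcm", "glcm", "shape", "shape", "shape"),
    icc = c(0.9, 0.94, 0.7, 0.85, NA)
  )
  class(recs) <- c("icc_tbl", class(recs))
  s <- category_summary(recs, thresholds = c(0.8, 0.9))
  glcm <- s[s$category == "glcm", ]
  expect_equal(glcm$mean_icc, 0.92)
  expect_equal(glcm$frac_gt_0.8, 1)
  expect_equal(glcm$frac_gt_0.9, 0.5)   # 0.9 is not > 0.9
  shape <- s[s$category == "shape", ]
  expect_equal(shape$mean_icc, 0.775)
  expect_equal(shape$n_undefined, 1)
  overall <- s[s$category == "overall", ]
  expect_equal(overall$mean_icc, mean(c(0.9, 0.94, 0.7, 0.85)))
  expect_equal(overall$frac_gt_0.8, 3 / 4)
})

test_that("ICC-vector comparison reproduces the textbook correlation", {
  mk <- function(v) {
    t <- tibble::tibble(feature = paste0("f", seq_along(v)),
                        category = "glcm", icc = v)
    class(t) <- c("icc_tbl", class(t)); t
  }
  expect_equal(compare_icc(mk(c(0.2, 0.5, 0.9)), mk(c(0.2, 0.5, 0.9)))$pearson_r, 1)
  expect_equal(compare_icc(mk(c(0.1, 0.5, 0.9)), mk(1 - c(0.1, 0.5, 0.9)))$pearson_r, -1)
  set.seed(3)
  a <- runif(20); b <- runif(20)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cmp <- compare_icc(mk(a), mk(b))
  expect_equal(cmp$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(nrow(tidy(cmp)), 20)
  expect_equal(glance(cmp)$n_features, 20)
  expect_error(compare_icc(mk(c(0.1, NA, NA)), mk(c(0.2, 0.3, 0.4))), "at least 3")
})

test_that("stability classification applies both published conventions", {
  cl <- classify_stability(c(0.95, 0.8, 0.5, NA))
  expect_equal(cl$rule_075, c("excellent", "excellent", "fair", NA))
  expect_equal(cl$rule_090, c("excellent", "good", "moderate", NA))
})
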