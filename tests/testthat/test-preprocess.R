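test_that("resampling at the identity spacing is a no-op and preserves constants", {
  img <- image_grid(matrix(7, 10, 10), c(1, 1))
  msk <- matrix(FALSE, 10, 10); msk[4:6, 4:6] <- TRUE
  out <- resample(img, msk, 1)
  expect_equal(unclass(out$image), unclass(img), ignore_attr = TRUE)
  expect_identical(out$mask, msk)

  img2 <- image_grid(matrix(42, 10, 10), c(2, 2))
  out2 <- resample(img2, msk, 1)
  expect_equal(dim(out2$image), c(20L, 20L))
  expect_true(all(out2$image == 42))
})

test_that("a rectangle mask resampled 2 mm -> 1 mm matches the scaled rectangle", {
  msk <- matrix(FALSE, 30, 30)
  msk[11:20, 6:25] <- TRUE   # 10 x 20 px at 2 mm
  img <- image_grid(matrix(0, 30, 30), c(2, 2))
  out <- resample(img, msk, 1)
  # analytic oracle: the physical rectangle rasterised on the 1 mm grid
  xs <- (seq_len(60) - 0.5) * 1
  expect_rows <- xs > (11 - 1) * 2 & xs < 20 * 2
  expect_cols <- xs > (6 - 1) * 2 & xs < 25 * 2
  oracle <- outer(expect_rows, expect_cols, "&")
  expect_gte(dice(out$mask, oracle), 0.95)
  expect_lt(abs(sum(out$mask) - 4 * sum(msk)) / (4 * sum(msk)), 0.1)
})

test_that("crop centring follows the minimal-rectangle midpoint with low tie-break", {
  img <- image_grid(matrix(0, 60, 60), c(1, 1))
  msk <- matrix(FALSE, 60, 60)
  msk[10:20, 30:50] <- TRUE
  out <- crop_roi(img, msk, 32)
  expect_equal(out$centre, c(15, 40))
  expect_equal(dim(out$image), c(32L, 32L))

  # a truly central lesion needs no padding and keeps its centre pixel
  msk_c <- matrix(FALSE, 60, 60); msk_c[25:35, 25:35] <- TRUE
  out_c <- crop_roi(img, msk_c, 20)
  expect_equal(out_c$centre, c(30, 30))
  expect_false(out_c$padded)
  expect_equal(sum(out_c$mask), sum(msk_c))

  # even extent: rows 10..21 -> midpoint 15.5 -> 15
  msk2 <- matrix(FALSE, 60, 60); msk2[10:21, 30:50] <- TRUE
  expect_equal(crop_roi(img, msk2, 32)$centre[1], 15)
})

test_that("crops near the image edge are padded to full size and flagged", {
  img <- image_grid(matrix(5, 30, 30), c(1, 1))
  msk <- matrix(FALSE, 30, 30); msk[1:4, 1:4] <- TRUE
  out <- crop_roi(img, msk, 20, pad_value = -1000)
  expect_equal(dim(out$mask), c(20L, 20L))
  expect_true(out$padded)
  expect_true(any(out$image == -1000))
  expect_equal(sum(out$mask), 16)
  expect_error(crop_roi(img, matrix(FALSE, 30, 30), 20), "empty")
})

test_that("organ masking replaces exactly the out-of-organ pixels", {
  img <- matrix(rnorm(100), 10, 10)
  expect_identical(apply_organ_mask(img, matrix(TRUE, 10, 10)), img)
  all_fill <- apply_organ_mask(img, matrix(FALSE, 10, 10), fill = -1000)
  expect_true(all(all_fill == -1000))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  out <- apply_organ_mask(img, half, fill = 0)
  expect_identical(out[, 1:5], img[, 1:5])
  expect_true(all(out[, 6:10] == 0))
  expect_error(apply_organ_mask(img, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("principal-slice selection picks the largest area with low-index ties", {
  mk <- function(n) { m <- matrix(FALSE, 6, 6); if (n > 0) m[seq_len(n)] <- TRUE; m }
  expect_equal(select_principal_slice(list(mk(3), mk(7), mk(7), mk(2))), 2)
  expect_equal(select_principal_slice(list(mk(0), mk(0), mk(4))), 3)
  expect_error(select_principal_slice(list(mk(0), mk(0))), "empty")
  # brute-force oracle on random stacks
  set.seed(1)
  for (i in 1:10) {
    stack <- lapply(1:5, function(j) matrix(runif(36) < 0.3, 6, 6))
    areas <- vapply(stack, sum, numeric(1))
    if (all(areas == 0)) next
    expect_equal(select_principal_slice(stack), which.max(areas))
  }
})

test_that("eligibility applies the volume floor and component rule", {
  sq <- function(n) { m <- matrix(FALSE, 20, 20); m[1:n, 1:n] <- TRUE; m }
  expect_true(eligibility_filter(sq(6), 1, 1, 30)$accept)    # 36 mm^3
  r <- eligibility_filter(sq(4), 1, 1, 30)                   # 16 mm^3
  expect_false(r$accept); expect_equal(r$reason, "volume")
  two <- matrix(FALSE, 30, 30); two[1:8, 1:8] <- TRUE; two[20:27, 20:27] <- TRUE
  r2 <- eligibility_filter(two, 1, 1, 30)
  expect_false(r2$accept); expect_equal(r2$reason, "components")
  # diagonal-touching fragments count as one component under 8-connectivity
  diagm <- matrix(FALSE, 12, 12); diagm[2:7, 2:7] <- TRUE; diagm[8, 8] <- TRUE
  expect_true(eligibility_filter(diagm, 1, 1, 30)$accept)
})

test_that("enlarging a mask never flips a volume-based accept to reject", {
  m <- matrix(FALSE, 30, 30); m[10:15, 10:15] <- TRUE
  accepted <- eligibility_filter(m, 1, 1, 30)$accept
  expect_true(accepted)
  for (grow in 1:5) {
    m[10:(15 + grow), 10:(15 + grow)] <- TRUE
    expect_true(eligibility_filter(m, 1, 1, 30)$accept)
  }
})

test_that("minimum sphere radius matches the closed form", {
  expect_equal(min_sphere_radius(30), (3 * 30 / (4 * pi))^(1 / 3))
  expect_lt(abs(min_sphere_radius(30) - 1.92), 0.01)   # printed 2 d.p. value
  expect_equal(min_sphere_radius(4 * pi / 3), 1)
  expect_equal(min_sphere_radius(8 * 4 * pi / 3), 2)
  expect_error(min_sphere_radius(0), "positive")
})

test_that("discretisation follows the min-anchored floor formula", {
  img <- matrix(c(-10, 0, 30, 60), 2, 2)
  msk <- matrix(TRUE, 2, 2)
  roi <- discretize(image_grid(img), msk, 25)
  expect_equal(as.vector(roi$levels), c(1, 1, 2, 3))
  expect_equal(roi$Ng, 3)

  roi_c <- discretize(image_grid(matrix(100, 3, 3)), matrix(TRUE, 3, 3), 25)
  expect_true(all(roi_c$levels == 1))
  expect_equal(roi_c$Ng, 1)

  set.seed(9)
  vals <- runif(1000, -1000, 400)
  img2 <- matrix(vals, 25, 40)
  roi2 <- discretize(image_grid(img2), matrix(TRUE, 25, 40), 25)
  oracle <- floor((vals - min(vals)) / 25) + 1   # elementwise oracle
  expect_equal(as.vector(roi2$levels), oracle)
  expect_error(discretize(image_grid(img2), matrix(FALSE, 25, 40), 25), "empty")
})

test_that("discretisation is invariant to constant intensity shifts", {
  set.seed(4)
  img <- matrix(rnorm(64, sd = 80), 8, 8)
  msk <- matrix(runif(64) < 0.8, 8, 8); msk[1, 1] <- TRUE
  a <- discretize(image_grid(img), msk, 25)
  b <- discretize(image_grid(img + 137.5), msk, 25)
  expect_identical(a$levels, b$levels)
})
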