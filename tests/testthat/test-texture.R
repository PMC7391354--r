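# Texture-matrix builders and features versus naive brute-force oracles.

test_that("the 2x2 toy GLCM matches exhaustive pair enumeration", {
  roi <- roi_from_levels(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE))
  g <- build_glcm(roi, angles = 0)[["0"]]
  expect_equal(g[1, 1], 0.5)
  expect_equal(g[1, 2], 0.25)
  expect_equal(g[2, 1], 0.25)
  expect_equal(g[2, 2], 0)
  f <- radstab:::glcm_features_single(g)
  expect_equal(f[["MaximumProbability"]], 0.5)
  expect_equal(f[["JointEnergy"]], 0.375)
})

test_that("GLCMs are normalised, symmetric, and zero-diagonal on a checkerboard", {
  roi <- random_roi(2, n = 8, ng = 4, p_mask = 0.8)
  for (g in build_glcm(roi)) {
    expect_equal(sum(g), 1)
    expect_equal(g, t(g))
  }
  chk <- roi_from_levels(1 + (outer(1:6, 1:6, "+") %% 2))
  gs <- build_glcm(chk, angles = c(0, 90))
  expect_equal(sum(diag(gs[["0"]])), 0)
  expect_equal(sum(diag(gs[["90"]])), 0)
})

test_that("single-level ROIs take the documented GLCM limit values", {
  roi <- roi_from_levels(matrix(1, 4, 4))
  f <- glcm_features(build_glcm(roi))
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["MaximumProbability"]], 1)
  expect_equal(f[["Correlation"]], 1)
  expect_equal(f[["Imc1"]], 0)
  expect_equal(f[["Imc2"]], 0)
  expect_equal(f[["InverseVariance"]], 0)
})

test_that("all 22 GLCM features match the brute-force oracle on random ROIs", {
  offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                  `135` = c(-1, -1))
  for (seed in 1:20) {
    roi <- random_roi(seed, n = 8, ng = 5, p_mask = if (seed %% 2) 1 else 0.7)
    mats <- build_glcm(roi)
    per_angle <- sapply(names(offsets), function(a) {
      P_oracle <- oracle_glcm(roi$levels, offsets[[a]][1], offsets[[a]][2], roi$Ng)
      expect_equal(mats[[a]], P_oracle, tolerance = 1e-12)
      oracle_glcm_features(P_oracle)
    })
    expect_equal(unname(glcm_features(mats)), unname(rowMeans(per_angle)),
                 tolerance = 1e-9)
  }
})

test_that("run extraction matches the scan oracle and closed forms", {
  roi <- roi_from_levels(matrix(c(1, 1, 1, 2), 1, 4))
  m <- build_glrlm(roi)[["0"]]
  expect_equal(m[1, 3], 1)
  expect_equal(m[2, 1], 1)
  expect_equal(sum(m), 2)

  # constant row: one run of length N
  n <- 7
  roic <- roi_from_levels(matrix(1, 1, n))
  f <- radstab:::glrlm_features_single(build_glrlm(roic)[["0"]], n)
  expect_equal(f[["LongRunEmphasis"]], n^2)
  expect_equal(f[["RunPercentage"]], 1 / n)

  # checkerboard: all horizontal/vertical runs have length 1
  chk <- roi_from_levels(1 + (outer(1:6, 1:6, "+") %% 2))
  for (d in c("0", "90")) {
    f <- radstab:::glrlm_features_single(build_glrlm(chk)[[d]], 36)
    expect_equal(f[["RunPercentage"]], 1)
  }
})

test_that("all 16 GLRLM features match the brute-force oracle per direction", {
  dirs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(1, 0), `135` = c(1, 1))
  for (seed in 1:20) {
    roi <- random_roi(seed + 100, n = 8, ng = 4, p_mask = if (seed %% 2) 1 else 0.75)
    np <- sum(roi$mask)
    mats <- build_glrlm(roi)
    oracle_means <- rowMeans(sapply(names(dirs), function(d) {
      P_o <- oracle_glrlm_matrix(roi$levels, dirs[[d]][1], dirs[[d]][2],
                                 roi$Ng, ncol(mats[[d]]))
      expect_equal(mats[[d]], P_o, label = paste("dir", d, "seed", seed))
      oracle_rl_features(P_o, np, "run")
    }))
    expect_equal(unname(glrlm_features(mats, np)), unname(oracle_means),
                 tolerance = 1e-9)
  }
})

test_that("zone decomposition matches the flood-fill oracle", {
  roi <- roi_from_levels(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE))
  m <- build_glszm(roi)
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 2], 1)
  expect_equal(sum(m), 2)

  n <- 9
  roic <- roi_from_levels(matrix(1, 3, 3))
  f <- glszm_features(build_glszm(roic), n)
  expect_equal(f[["ZonePercentage"]], 1 / n)
  expect_equal(f[["LargeAreaEmphasis"]], n^2)
})

test_that("all 16 GLSZM features match the brute-force oracle on random ROIs", {
  for (seed in 1:20) {
    roi <- random_roi(seed + 200, n = 8, ng = 4, p_mask = if (seed %% 2) 1 else 0.7)
    np <- sum(roi$mask)
    P <- build_glszm(roi)
    P_o <- oracle_glszm_matrix(roi$levels, roi$Ng)
    expect_equal(P, P_o, label = paste("seed", seed))
    expect_equal(unname(glszm_features(P, np)),
                 unname(oracle_rl_features(P_o, np, "zone")), tolerance = 1e-9)
  }
})

test_that("NGTDM difference sums match hand and brute-force computation", {
  # 3x3 with one centre outlier: hand oracle
  lev <- matrix(1, 3, 3); lev[2, 2] <- 3
  roi <- roi_from_levels(lev)
  ngt <- build_ngtdm(roi)
  # centre: |3 - 1| = 2; each edge/corner neighbour of the centre sees it
  s_hand <- oracle_ngtdm_s(lev, 3)
  expect_equal(ngt$s, s_hand)
  expect_equal(ngt$s[3], 2)

  roic <- roi_from_levels(matrix(2, 4, 4) - 1)
  f <- ngtdm_features(build_ngtdm(roic))
  expect_equal(f[["Coarseness"]], 1e6)
  expect_equal(f[["Contrast"]], 0)
})

test_that("all 5 NGTDM features match the brute-force oracle on random ROIs", {
  for (seed in 1:20) {
    roi <- random_roi(seed + 300, n = 8, ng = 4, p_mask = if (seed %% 2) 1 else 0.7)
    ngt <- build_ngtdm(roi)
    expect_equal(ngt$s, oracle_ngtdm_s(roi$levels, roi$Ng), tolerance = 1e-12)
    expect_equal(unname(ngtdm_features(ngt)),
                 unname(oracle_ngtdm_features(roi$levels, roi$Ng)),
                 tolerance = 1e-9)
  }
})

test_that("GLRLM/GLSZM matrix totals count runs and zones exactly", {
  for (seed in c(7, 17)) {
    roi <- random_roi(seed, n = 10, ng = 5, p_mask = 0.8)
    runs0 <- oracle_runs(roi$levels, 0, 1)
    expect_equal(sum(build_glrlm(roi)[["0"]]), nrow(runs0))
    zones <- oracle_zones(roi$levels)
    expect_equal(sum(build_glszm(roi)), nrow(zones))
  }
})
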