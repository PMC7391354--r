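# Independent brute-force oracles: every routine here recomputes a quantity
# with naive explicit loops, sharing no code with the package internals.

# a discretized ROI with known levels: image value = (level - 1) * bin_width
roi_from_levels <- function(lev, mask = !is.na(lev), bin_width = 25) {
  img <- matrix(0, nrow(lev), ncol(lev))
  img[mask] <- (lev[mask] - 1) * bin_width
  discretize(image_grid(img), mask, bin_width)
}

random_roi <- function(seed, n = 8, ng = 5, p_mask = 1) {
  set.seed(seed)
  lev <- matrix(sample.int(ng, n * n, replace = TRUE), n, n)
  mask <- matrix(stats::runif(n * n) < p_mask, n, n)
  if (!any(mask)) mask[1, 1] <- TRUE
  lev[!mask] <- NA
  roi_from_levels(lev, mask)
}

# ---- GLCM oracle: enumerate every pixel pair explicitly -------------------
oracle_glcm <- function(lev, dr, dc, ng) {
  cnt <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lev))) {
    for (c in seq_len(ncol(lev))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
      a <- lev[r, c]; b <- lev[r2, c2]
      if (is.na(a) || is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1   # symmetric counting
    }
  }
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sdx <- sqrt(sum(((1:ng) - mux)^2 * px)); sdy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  l2 <- function(v) if (v > 0) log2(v) else 0
  acc <- cp <- cs <- ct <- con <- cor_num <- de <- dv <- je <- hxy <- 0
  idm <- idmn <- idf <- idn <- iv <- ss <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    je <- je + p^2
    hxy <- hxy - p * l2(p)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idf <- idf + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - mux)^2 * p
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  dent <- 0; for (k in 0:(ng - 1)) dent <- dent - pd[k + 1] * l2(pd[k + 1])
  dvar <- 0; for (k in 0:(ng - 1)) dvar <- dvar + (k - da)^2 * pd[k + 1]
  sent <- 0; for (k in 2:(2 * ng)) sent <- sent - ps[k] * l2(ps[k])
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * l2(px[i])
  hy <- 0; for (j in 1:ng) hy <- hy - py[j] * l2(py[j])
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    hxy1 <- hxy1 - P[i, j] * l2(q)
    hxy2 <- hxy2 - q * l2(q)
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (hxy2 < hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy)))
  corr <- if (sdx == 0 || sdy == 0) 1 else (cor_num - mux * muy) / (sdx * sdy)
  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent, DifferenceVariance = dvar,
    JointAverage = mux, JointEnergy = je, JointEntropy = hxy,
    Imc1 = imc1, Imc2 = imc2, Idm = idm, Idmn = idmn, Id = idf, Idn = idn,
    InverseVariance = iv, MaximumProbability = max(P), SumEntropy = sent,
    SumSquares = ss)
}

# ---- GLRLM oracle: naive scan along each direction ------------------------
oracle_runs <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  starts <- list()
  for (r in 1:nr) for (c in 1:nc) {
    pr <- r - dr; pc <- c - dc
    if (pr < 1 || pr > nr || pc < 1 || pc > nc) {
      starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_lev <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lev[r, c]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; c <- c + dc
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  do.call(rbind, runs)
}

oracle_glrlm_matrix <- function(lev, dr, dc, ng, max_len) {
  runs <- oracle_runs(lev, dr, dc)
  m <- matrix(0, ng, max_len)
  if (!is.null(runs)) {
    for (q in seq_len(nrow(runs))) m[runs[q, 1], runs[q, 2]] <- m[runs[q, 1], runs[q, 2]] + 1
  }
  m
}

oracle_rl_features <- function(P, n_pixels, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ng <- nrow(P); nl <- ncol(P)
  nr <- sum(P)
  sre <- lre <- gln <- rln <- glv1 <- rv1 <- ent <- lgl <- hgl <- 0
  srl <- srh <- lrl <- lrh <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- P[i, j] / nr
    mu_i <- mu_i + p * i; mu_j <- mu_j + p * j
  }
  ri <- numeric(ng); rj <- numeric(nl)
  for (i in 1:ng) for (j in 1:nl) { ri[i] <- ri[i] + P[i, j]; rj[j] <- rj[j] + P[i, j] }
  for (i in 1:ng) for (j in 1:nl) {
    v <- P[i, j]; p <- v / nr
    sre <- sre + v / j^2; lre <- lre + v * j^2
    glv1 <- glv1 + p * (i - mu_i)^2; rv1 <- rv1 + p * (j - mu_j)^2
    if (p > 0) ent <- ent - p * log2(p)
    lgl <- lgl + v / i^2; hgl <- hgl + v * i^2
    srl <- srl + v / (i^2 * j^2); srh <- srh + v * i^2 / j^2
    lrl <- lrl + v * j^2 / i^2; lrh <- lrh + v * i^2 * j^2
  }
  base <- c(sum(ri^2) / nr, sum(ri^2) / nr^2, sum(rj^2) / nr, sum(rj^2) / nr^2)
  out <- c(sre / nr, lre / nr, base[1], base[2], base[3], base[4],
           nr / n_pixels, glv1, rv1, ent, lgl / nr, hgl / nr,
           srl / nr, srh / nr, lrl / nr, lrh / nr)
  names(out) <- if (kind == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
      "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
      "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
      "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
      "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
      "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LargeAreaHighGrayLevelEmphasis")
  }
  out
}

# ---- GLSZM oracle: stack-based flood fill ---------------------------------
oracle_zones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0] || is.na(lev[r0, c0])) next
    g <- lev[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (seen[r, c] || is.na(lev[r, c]) || lev[r, c] != g) next
        seen[r, c] <- TRUE
        stack[[length(stack) + 1]] <- c(r, c)
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_matrix <- function(lev, ng) {
  z <- oracle_zones(lev)
  m <- matrix(0, ng, max(z[, 2]))
  for (q in seq_len(nrow(z))) m[z[q, 1], z[q, 2]] <- m[z[q, 1], z[q, 2]] + 1
  m
}

# ---- NGTDM oracle: per-pixel neighbour scan -------------------------------
oracle_ngtdm_s <- function(lev, ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  s <- numeric(ng)
  for (r in 1:nr) for (c in 1:nc) {
    v <- lev[r, c]
    if (is.na(v)) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!is.na(lev[rr, cc])) nb <- c(nb, lev[rr, cc])
    }
    if (length(nb) > 0) s[v] <- s[v] + abs(v - mean(nb))
  }
  s
}

oracle_ngtdm_features <- function(lev, ng) {
  s <- oracle_ngtdm_s(lev, ng)
  np <- sum(!is.na(lev))
  n <- numeric(ng)
  for (g in 1:ng) n[g] <- sum(lev == g, na.rm = TRUE)
  p <- n / np
  occ <- which(p > 0); ngp <- length(occ)
  coar <- if (sum(p * s) == 0) 1e6 else 1 / sum(p * s)
  con <- 0
  if (ngp > 1) {
    for (i in occ) for (j in occ) con <- con + p[i] * p[j] * (i - j)^2
    con <- con / (ngp * (ngp - 1)) * sum(s) / np
  }
  dbusy <- 0; for (i in occ) for (j in occ) dbusy <- dbusy + abs(i * p[i] - j * p[j])
  busy <- if (dbusy == 0) 0 else sum(p * s) / dbusy
  comp <- 0
  for (i in occ) for (j in occ) {
    comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  }
  comp <- comp / np
  stre <- 0; for (i in occ) for (j in occ) stre <- stre + (p[i] + p[j]) * (i - j)^2
  stre <- if (sum(s) == 0) 0 else stre / sum(s)
  c(Coarseness = coar, Contrast = con, Busyness = busy,
    Complexity = comp, Strength = stre)
}

# ---- ICC oracle via one-way aov (independent code path) -------------------
oracle_icc_aov <- function(m) {
  d <- data.frame(
    y = as.vector(t(m)),
    lesion = factor(rep(seq_len(nrow(m)), each = ncol(m)))
  )
  a <- summary(stats::aov(y ~ lesion, data = d))[[1]]
  msb <- a["lesion", "Mean Sq"]
  msw <- a["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# simulate a one-way random-effects table with given variance components
simulate_icc_table <- function(n, k, sigma_b2, sigma_w2, mu = 10) {
  b <- stats::rnorm(n, 0, sqrt(sigma_b2))
  mu + matrix(rep(b, k), n, k) + matrix(stats::rnorm(n * k, 0, sqrt(sigma_w2)), n, k)
}

# small helper lesions used across tests
disc_lesion <- function(radius = 10, image_size = 40, seed = 7, ...) {
  make_lesion(lesion_spec(
    background_hu = -800, background_noise_sd = 0, lesion_hu = 40,
    texture_sd = 0, texture_corr_len = 3, edge_blur_sigma = 0,
    radius_mean = radius, radius_irregularity = 0,
    image_size = image_size, spacing = 1, ...), seed)
}

textured_lesion <- function(seed = 3, image_size = 64, radius = 8) {
  make_lesion(lesion_preset("lung", image_size = image_size,
                            radius_mean = radius), seed)
}
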