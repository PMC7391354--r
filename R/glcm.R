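#' Build gray-level co-occurrence matrices
#'
#' For each of the four unique 2D directions (0, 45, 90, 135 degrees) at the
#' given pixel distance, counts co-occurrences of gray levels between pixel
#' pairs with both endpoints inside the mask, symmetrises, and normalises to
#' a probability table.
#'
#' @param roi a [discretize()]d ROI
#' @param distance pixel offset (>= 1)
#' @param angles subset of `c(0, 45, 90, 135)` (degrees)
#' @return named list of Ng x Ng probability matrices, one per angle
#' @export
build_glcm <- function(roi, distance = 1, angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(roi, "discretized_roi"), distance >= 1)
  ng <- roi$Ng
  if (ng == 0) stop("ROI has no gray levels")
  lev <- roi$levels
  offsets <- list(
    `0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1)
  )
  offsets <- offsets[as.character(angles)]
  lapply(offsets, function(off) {
    pr <- pair_levels(lev, off[1] * distance, off[2] * distance)
    counts <- matrix(0, ng, ng)
    if (nrow(pr) > 0) {
      tab <- tabulate((pr[, 2] - 1) * ng + pr[, 1], ng * ng)
      counts <- matrix(tab, ng, ng)
    }
    counts <- counts + t(counts)
    s <- sum(counts)
    if (s == 0) counts else counts / s
  })
}

# all ordered in-mask level pairs at offset (dr, dc)
pair_levels <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' GLCM texture features (22 features)
#'
#' Computes the 22 co-occurrence statistics per angle, then averages over
#' angles. All entropies use log base 2 with 0 log 0 = 0. Degenerate
#' single-level matrices take their limit values: `Correlation = 1`,
#' `Imc1 = Imc2 = 0`, `InverseVariance = 0`.
#'
#' @param matrices output of [build_glcm()]
#' @return named numeric vector of 22 features
#' @export
glcm_features <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  per_angle <- vapply(matrices, glcm_features_single, numeric(22))
  rowMeans(per_angle)
}

glcm_features_single <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # diagonal-band distributions
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))

  xlog2 <- function(v) ifelse(v > 0, log2(v), 0)
  ent <- function(v) -sum(v * xlog2(v))

  contrast <- sum((i - j)^2 * P)
  da <- sum(k_diff * pxmy)

  hx <- ent(px); hy <- ent(py); hxy <- ent(P)
  pxy_ind <- outer(px, py)
  hxy1 <- -sum(P * xlog2(pxy_ind))
  hxy2 <- -sum(pxy_ind * xlog2(pxy_ind))
  denom_imc1 <- max(hx, hy)
  imc1 <- if (denom_imc1 == 0) 0 else (hxy - hxy1) / denom_imc1
  imc2 <- if (hxy2 < hxy) 0 else sqrt(1 - exp(-2 * (hxy2 - hxy)))

  corr <- if (sdx == 0 || sdy == 0) 1 else
    (sum(i * j * P) - mux * muy) / (sdx * sdy)

  offdiag <- abs(i - j) > 0
  invvar <- if (any(P[offdiag] > 0))
    sum(P[offdiag] / (i - j)[offdiag]^2) else 0

  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = invvar,
    MaximumProbability = max(P),
    SumEntropy = ent(pxpy),
    SumSquares = sum((i - mux)^2 * P)
  )
}
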