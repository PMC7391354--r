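#' Build the gray-level size-zone matrix
#'
#' A zone is an 8-connected set of in-mask pixels sharing one gray level.
#' The matrix counts zones by (gray level, zone size); unlike run-length
#' counting there is no direction, so a single matrix is produced.
#'
#' @param roi a [discretize()]d ROI
#' @return Ng x max-zone-size count matrix
#' @export
build_glszm <- function(roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  lev <- roi$levels
  ng <- roi$Ng
  zones_lev <- integer(0); zones_size <- integer(0)
  for (g in seq_len(ng)) {
    sel <- !is.na(lev) & lev == g
    if (!any(sel)) next
    lab <- label_components(sel, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    zones_lev <- c(zones_lev, rep(g, length(sizes)))
    zones_size <- c(zones_size, sizes)
  }
  m <- matrix(0, ng, max(zones_size))
  for (q in seq_along(zones_lev)) {
    m[zones_lev[q], zones_size[q]] <- m[zones_lev[q], zones_size[q]] + 1
  }
  m
}

#' GLSZM texture features (16 features)
#'
#' Zone statistics mirroring the run-length set with "zone size" in place of
#' "run length".
#'
#' @param P output of [build_glszm()]
#' @param n_pixels in-mask pixel count (for `ZonePercentage`)
#' @return named numeric vector of 16 features
#' @export
glszm_features <- function(P, n_pixels) {
  nz <- sum(P)
  ng <- nrow(P); ns <- ncol(P)
  i <- matrix(seq_len(ng), ng, ns)
  s <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  p <- P / nz
  mu_i <- sum(p * i); mu_s <- sum(p * s)
  gi <- rowSums(P); zs <- colSums(P)
  xlog2 <- function(v) ifelse(v > 0, log2(v), 0)

  c(
    SmallAreaEmphasis = sum(P / s^2) / nz,
    LargeAreaEmphasis = sum(P * s^2) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
    SizeZoneNonUniformity = sum(zs^2) / nz,
    SizeZoneNonUniformityNormalized = sum(zs^2) / nz^2,
    ZonePercentage = nz / n_pixels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (s - mu_s)^2),
    ZoneEntropy = -sum(p * xlog2(p)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * s^2) / nz
  )
}
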