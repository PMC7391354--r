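#' First-order intensity statistics (18 features)
#'
#' Distributional statistics of the raw in-mask intensities; `Entropy` and
#' `Uniformity` are computed on the discretised gray-level probabilities
#' (log base 2, with 0 log 0 = 0). Percentiles use linear interpolation
#' between order statistics; `Variance` is the population variance;
#' `Kurtosis` is non-excess (a Gaussian scores 3); `TotalEnergy` scales
#' `Energy` by the physical voxel volume of the one-voxel-thick extrusion.
#'
#' @param roi a [discretize()]d ROI
#' @param spacing mm per pixel (length 1 or 2)
#' @param slice_thickness mm, extrusion thickness for `TotalEnergy`
#' @return named numeric vector of 18 features
#' @export
firstorder_features <- function(roi, spacing = roi$spacing,
                                slice_thickness = 1) {
  stopifnot(inherits(roi, "discretized_roi"))
  x <- roi$raw[roi$mask]
  if (length(x) == 0) stop("empty ROI")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  vox <- spacing[1] * spacing[2] * slice_thickness

  p <- tabulate(roi$levels[roi$mask], roi$Ng)
  p <- p[p > 0] / length(x)

  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90),
                        names = FALSE, type = 7)
  rx <- x[x >= qs[1] & x <= qs[5]]

  skew <- if (m2 == 0) 0 else mean((x - mu)^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean((x - mu)^4) / m2^2

  c(
    Energy = sum(x^2),
    TotalEnergy = vox * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rx - mean(rx))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
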