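#' The radiomic signature registry
#'
#' Stable registry of the extracted feature names: 18 first-order, 12 shape,
#' 22 GLCM, 16 GLSZM, 16 GLRLM and 5 NGTDM features. Column order in every
#' feature table follows this registry; names are prefixed by category
#' (e.g. `glcm_Contrast`).
#'
#' @return tibble with columns `category`, `name`, `feature`
#'   (the prefixed column name), 89 rows
#' @export
feature_registry <- function() {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  sh <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
          "Sphericity", "SphericalDisproportion", "Maximum2DDiameterSlice",
          "MajorAxisLength", "MinorAxisLength", "Elongation", "Perimeter",
          "PerimeterSurfaceRatio")
  gc <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
          "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
          "DifferenceEntropy", "DifferenceVariance", "JointAverage",
          "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id",
          "Idn", "InverseVariance", "MaximumProbability", "SumEntropy",
          "SumSquares")
  gz <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
          "SizeZoneNonUniformityNormalized", "ZonePercentage",
          "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
          "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  gr <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage",
          "GrayLevelVariance", "RunVariance", "RunEntropy",
          "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
          "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  nt <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  reg <- tibble::tibble(
    category = rep(c("firstorder", "shape", "glcm", "glszm", "glrlm", "ngtdm"),
                   times = c(18, 12, 22, 16, 16, 5)),
    name = c(fo, sh, gc, gz, gr, nt)
  )
  reg$feature <- paste(reg$category, reg$name, sep = "_")
  reg
}

#' Extract the full radiomic feature vector from one image/mask pair
#'
#' Runs the eligibility filter, discretises the in-mask intensities at the
#' configured bin width, and computes all six feature categories. Values are
#' raw — no standardisation or scaling is applied.
#'
#' @param image numeric matrix (HU) with spacing attribute
#' @param mask logical matrix on the same grid
#' @param cfg a [preprocess_config()]
#' @param spacing override for the grid spacing
#' @return named numeric vector of 89 features, ordered as
#'   [feature_registry()]
#' @export
extract_all <- function(image, mask, cfg = preprocess_config(),
                        spacing = grid_spacing(image)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  elig <- eligibility_filter(mask, spacing, cfg$slice_thickness,
                             cfg$min_volume)
  if (!elig$accept) {
    stop("mask fails eligibility filter: ", elig$reason,
         " (volume ", round(elig$volume_mm3, 1), " mm^3, ",
         elig$n_components, " component(s))")
  }
  roi <- discretize(image_grid(image, spacing), mask, cfg$bin_width)
  npx <- sum(mask)

  fo <- firstorder_features(roi, spacing, cfg$slice_thickness)
  sh <- shape_features(mask, spacing, cfg$slice_thickness)
  gc <- glcm_features(build_glcm(roi))
  gz <- glszm_features(build_glszm(roi), npx)
  gr <- glrlm_features(build_glrlm(roi), npx)
  nt <- ngtdm_features(build_ngtdm(roi))

  out <- c(fo, sh, gc, gz, gr, nt)
  names(out) <- feature_registry()$feature
  out
}

#' Extract feature tables for a whole cohort
#'
#' Maps [extract_all()] over every (lesion, rater) mask in a simulated
#' cohort, including the ground-truth mask of each lesion (rater id
#' `"truth"`). Masks failing the eligibility filter are skipped with a
#' warning and recorded in the `skipped` attribute.
#'
#' @param cohort a cohort tibble from [simulate_cohort()]
#' @param cfg a [preprocess_config()]
#' @param include_truth also extract from the ground-truth masks
#' @return tibble with `lesion_id`, `rater_id` and 89 feature columns
#' @export
extract_features <- function(cohort, cfg = preprocess_config(),
                             include_truth = FALSE) {
  rows <- list()
  skipped <- list()
  for (li in seq_len(nrow(cohort))) {
    img <- cohort$image[[li]]
    sp <- grid_spacing(img)
    sets <- cohort$raters[[li]]
    ids <- names(sets) %||% paste0("rater_", seq_along(sets))
    if (include_truth) {
      sets <- c(list(cohort$truth[[li]]), sets)
      ids <- c("truth", ids)
    }
    for (ri in seq_along(sets)) {
      fv <- tryCatch(extract_all(img, sets[[ri]], cfg, sp),
                     error = function(e) e)
      if (inherits(fv, "error")) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          lesion_id = cohort$lesion_id[li], rater_id = ids[ri],
          reason = conditionMessage(fv))
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        lesion_id = cohort$lesion_id[li], rater_id = ids[ri],
        !!!as.list(fv))
    }
  }
  if (length(rows) == 0) stop("no eligible (lesion, rater) pairs")
  out <- dplyr::bind_rows(rows)
  if (length(skipped) > 0) {
    sk <- dplyr::bind_rows(skipped)
    warning(nrow(sk), " mask(s) skipped by the eligibility filter")
    attr(out, "skipped") <- sk
  }
  out
}
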