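#' Configuration of a full reproducibility experiment
#'
#' Bundles every tunable of the simulate -> preprocess -> extract ->
#' agreement -> reliability workflow. Defaults are the standard protocol:
#' 4 experts and 25 sampled segmentations per lesion, Dice > 0.3 acceptance,
#' expert agreement calibrated to a median pairwise Dice of 0.87 and the
#' sampled population to a median sample-vs-expert Dice of 0.85, 25 HU bins
#' on a 1 mm grid, 30 mm^3 volume floor, ICC(1,1) with 1000-replicate 95%
#' bootstrap intervals.
#'
#' @param n_lesions lesions in the cohort
#' @param k_experts simulated expert raters per lesion
#' @param k_samples simulated sampled segmentations per lesion
#' @param preset lesion contrast preset, `"lung"` or `"abdomen"`
#' @param target_dice_experts target median pairwise Dice among experts
#' @param target_dice_samples target median Dice of samples vs experts
#' @param corr_len mm smoothness of the boundary perturbation
#' @param accept_threshold Dice rejection-sampling cut-off
#' @param preprocess a [preprocess_config()]
#' @param n_boot bootstrap replicates for ICC CIs
#' @param alpha CI miss probability
#' @param thresholds ICC cut-offs reported in summaries
#' @param seed master seed; the whole experiment is a pure function of it
#' @param lesion_template optional [lesion_spec()] overriding the preset as
#'   the cohort template
#' @return a `run_config` object
#' @export
run_config <- function(n_lesions = 20, k_experts = 4, k_samples = 25,
                       preset = "lung", lesion_template = NULL,
                       target_dice_experts = 0.87,
                       target_dice_samples = 0.85,
                       corr_len = 4, accept_threshold = 0.3,
                       preprocess = preprocess_config(),
                       n_boot = 1000, alpha = 0.05,
                       thresholds = c(0.75, 0.8, 0.9), seed = 1) {
  stopifnot(n_lesions >= 2, k_experts >= 2, k_samples >= 2)
  structure(
    list(n_lesions = n_lesions, k_experts = k_experts, k_samples = k_samples,
         preset = preset, lesion_template = lesion_template,
         target_dice_experts = target_dice_experts,
         target_dice_samples = target_dice_samples, corr_len = corr_len,
         accept_threshold = accept_threshold, preprocess = preprocess,
         n_boot = n_boot, alpha = alpha, thresholds = thresholds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Simulate the two rater populations of a reproducibility experiment
#'
#' Per lesion: a ground-truth mask, `k_experts` perturbed "expert" masks
#' whose amplitude is calibrated once (on a template lesion) so their median
#' pairwise Dice hits `target_dice_experts`, and `k_samples` perturbed
#' "sampled" masks calibrated so their median Dice against the experts hits
#' `target_dice_samples`, accepted against any expert mask.
#'
#' @param config a [run_config()]
#' @return tibble: `lesion_id`, `image`, `truth`, `experts`, `samples`
#'   (list-columns), with the calibrated parameter sets as attributes
#' @export
simulate_two_populations <- function(config) {
  seeds <- derive_seeds(config$seed, 4)
  template <- config$lesion_template %||% lesion_preset(config$preset)
  # calibrate the perturbation amplitude on a 3-lesion panel drawn from the
  # same spec distribution as the cohort, so the pooled cohort-level Dice
  # distribution, not just one geometry, hits the target median
  cal_seeds <- derive_seeds(seeds[1], 6)
  cal_truths <- lapply(1:3, function(i) {
    make_lesion(sample_lesion_spec(template, cal_seeds[i]),
                cal_seeds[3 + i])$mask
  })
  base <- perturbation_params(corr_len = config$corr_len,
                              accept_threshold = config$accept_threshold)
  params_e <- calibrate_amplitude(cal_truths, config$target_dice_experts,
                                  base, spacing = template$spacing,
                                  seed = seeds[2])
  ref_seeds <- derive_seeds(seeds[2], length(cal_truths))
  ref_sets <- lapply(seq_along(cal_truths), function(i) {
    sample_rater_set(cal_truths[[i]], params_e, k = config$k_experts,
                     spacing = template$spacing, seed = ref_seeds[i])
  })
  params_s <- calibrate_amplitude(cal_truths, config$target_dice_samples,
                                  base, spacing = template$spacing,
                                  seed = seeds[3], reference_set = ref_sets)

  lesion_seeds <- derive_seeds(seeds[4], 4 * config$n_lesions)
  dim(lesion_seeds) <- c(config$n_lesions, 4)
  rows <- lapply(seq_len(config$n_lesions), function(i) {
    sp <- sample_lesion_spec(template, lesion_seeds[i, 1])
    les <- make_lesion(sp, lesion_seeds[i, 2])
    experts <- sample_rater_set(les$mask, params_e, k = config$k_experts,
                                spacing = sp$spacing,
                                seed = lesion_seeds[i, 3])
    names(experts) <- sprintf("expert_%02d", seq_along(experts))
    samples <- sample_rater_set(les$mask, params_s, k = config$k_samples,
                                spacing = sp$spacing,
                                seed = lesion_seeds[i, 4],
                                reference_masks = experts)
    names(samples) <- sprintf("sample_%02d", seq_along(samples))
    tibble::tibble(lesion_id = sprintf("lesion_%03d", i),
                   image = list(les$image), truth = list(les$mask),
                   experts = list(experts), samples = list(samples))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params_experts") <- params_e
  attr(out, "params_samples") <- params_s
  out
}

#' Run the full reproducibility experiment
#'
#' Executes simulate -> extract -> agreement -> reliability and writes the
#' result tables as CSVs plus a machine-readable run manifest. Identical
#' configurations produce identical outputs.
#'
#' Files written under `output_dir`: `features_experts.csv`,
#' `features_samples.csv`, `dice_experts.csv`, `dice_samples.csv`,
#' `dice_cross.csv` (per-lesion agreement summaries), `icc_experts.csv`,
#' `icc_samples.csv`, `category_summary_experts.csv`,
#' `category_summary_samples.csv`, `icc_comparison.csv`, `manifest.json`.
#'
#' @param config a [run_config()]
#' @param output_dir directory for the CSV outputs (created if missing)
#' @return invisibly, a `radstab_run` list with all result tibbles
#' @export
run_experiment <- function(config, output_dir = tempfile("radstab_run_")) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_two_populations(config)

  dice_rows <- function(col_a, col_b = NULL, label) {
    dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
      m <- if (is.null(col_b)) pairwise_dice(cohort[[col_a]][[i]])
        else pairwise_dice(cohort[[col_a]][[i]], cohort[[col_b]][[i]])
      dplyr::mutate(dice_summary(m),
                    lesion_id = cohort$lesion_id[i], comparison = label,
                    .before = 1)
    }))
  }
  dice_experts <- dice_rows("experts", label = "within_experts")
  dice_samples <- dice_rows("samples", label = "within_samples")
  dice_cross <- dice_rows("samples", "experts", label = "samples_vs_experts")

  cfgp <- config$preprocess
  as_pop <- function(col) {
    x <- cohort[, c("lesion_id", "image", "truth")]
    x$raters <- cohort[[col]]
    x
  }
  feats_e <- extract_features(as_pop("experts"), cfgp)
  feats_s <- extract_features(as_pop("samples"), cfgp)

  seeds <- derive_seeds(config$seed + 1L, 2)
  icc_e <- icc_table(feats_e, config$n_boot, config$alpha, seeds[1])
  icc_s <- icc_table(feats_s, config$n_boot, config$alpha, seeds[2])
  summ_e <- category_summary(icc_e, config$thresholds[-1])
  summ_s <- category_summary(icc_s, config$thresholds[-1])
  comp <- compare_icc(icc_e, icc_s)

  wr <- function(x, f) readr::write_csv(tibble::as_tibble(x),
                                        file.path(output_dir, f))
  wr(feats_e, "features_experts.csv")
  wr(feats_s, "features_samples.csv")
  wr(dice_experts, "dice_experts.csv")
  wr(dice_samples, "dice_samples.csv")
  wr(dice_cross, "dice_cross.csv")
  wr(icc_e, "icc_experts.csv")
  wr(icc_s, "icc_samples.csv")
  wr(summ_e, "category_summary_experts.csv")
  wr(summ_s, "category_summary_samples.csv")
  wr(dplyr::mutate(comp$data, pearson_r = comp$pearson_r),
     "icc_comparison.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("radstab")),
    config = config[setdiff(names(config), c("preprocess", "lesion_template"))],
    lesion_template = if (!is.null(config$lesion_template))
      unclass(config$lesion_template),
    preprocess = unclass(config$preprocess),
    calibrated_amplitude_experts = attr(cohort, "params_experts")$amplitude,
    calibrated_amplitude_samples = attr(cohort, "params_samples")$amplitude,
    n_lesions_dropped_experts = attr(icc_e, "n_lesions_dropped"),
    n_lesions_dropped_samples = attr(icc_s, "n_lesions_dropped")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  res <- structure(
    list(output_dir = output_dir, cohort = cohort,
         features_experts = feats_e, features_samples = feats_s,
         dice_experts = dice_experts, dice_samples = dice_samples,
         dice_cross = dice_cross,
         icc_experts = icc_e, icc_samples = icc_s,
         summary_experts = summ_e, summary_samples = summ_s,
         comparison = comp, config = config),
    class = "radstab_run"
  )
  invisible(res)
}

#' @export
print.radstab_run <- function(x, ...) {
  cat("radstab reproducibility experiment\n")
  cat(sprintf("  %d lesions; %d experts + %d samples per lesion\n",
              x$config$n_lesions, x$config$k_experts, x$config$k_samples))
  cat(sprintf("  median within-expert Dice: %.3f\n",
              stats::median(x$dice_experts$median)))
  cat(sprintf("  median sample-vs-expert Dice: %.3f\n",
              stats::median(x$dice_cross$median)))
  cat(sprintf("  expert/sample ICC correlation: r = %.3f\n",
              x$comparison$pearson_r))
  cat("  outputs: ", x$output_dir, "\n")
  invisible(x)
}

#' Tidy a reproducibility run
#'
#' @param x a `radstab_run`
#' @param ... unused
#' @return the per-feature ICC tables of both populations, stacked with a
#'   `population` column
#' @export
tidy.radstab_run <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$icc_experts), population = "experts"),
    dplyr::mutate(tibble::as_tibble(x$icc_samples), population = "samples")
  )
}

#' One-row summary of a reproducibility run
#'
#' @param x a `radstab_run`
#' @param ... unused
#' @return tibble with the headline agreement and reliability quantities
#' @export
glance.radstab_run <- function(x, ...) {
  ov_e <- x$summary_experts[x$summary_experts$category == "overall", ]
  ov_s <- x$summary_samples[x$summary_samples$category == "overall", ]
  tibble::tibble(
    n_lesions = x$config$n_lesions,
    median_dice_experts = stats::median(x$dice_experts$median),
    median_dice_samples_vs_experts = stats::median(x$dice_cross$median),
    mean_icc_experts = ov_e$mean_icc,
    mean_icc_samples = ov_s$mean_icc,
    frac_icc_gt_0.8_experts = ov_e$frac_gt_0.8,
    frac_icc_gt_0.8_samples = ov_s$frac_gt_0.8,
    pearson_r = x$comparison$pearson_r
  )
}

#' Extract features from NIfTI image/mask files
#'
#' Real-data entry point: reads each image once and every mask drawn on it,
#' resamples both to the configured isotropic spacing, and extracts the
#' full feature vector. Masks failing the eligibility filter, or files that
#' cannot be read or do not match the image geometry, are skipped and
#' collected in the `errors` attribute.
#'
#' @param image_paths character vector of NIfTI images (one per lesion)
#' @param mask_paths list (parallel to `image_paths`) of character vectors
#'   of NIfTI mask files for that image
#' @param config a [preprocess_config()]
#' @return tibble keyed by `lesion_id` (image filename) and `rater_id`
#'   (mask filename) with the 89 feature columns
#' @export
extract_from_niftis <- function(image_paths, mask_paths,
                                config = preprocess_config()) {
  stopifnot(length(image_paths) == length(mask_paths))
  rows <- list(); errs <- list()
  for (i in seq_along(image_paths)) {
    img <- tryCatch(read_nifti_grid(image_paths[i]), error = function(e) e)
    if (inherits(img, "error")) {
      errs[[length(errs) + 1]] <- tibble::tibble(
        file = image_paths[i], error = conditionMessage(img))
      next
    }
    for (mp in mask_paths[[i]]) {
      fv <- tryCatch({
        msk <- read_nifti_grid(mp, as_mask = TRUE)
        if (!identical(dim(msk), dim(img))) stop("mask/image geometry mismatch")
        rs <- resample(img, msk, config$target_spacing)
        extract_all(rs$image, rs$mask, config)
      }, error = function(e) e)
      if (inherits(fv, "error")) {
        errs[[length(errs) + 1]] <- tibble::tibble(
          file = mp, error = conditionMessage(fv))
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        lesion_id = basename(image_paths[i]), rater_id = basename(mp),
        !!!as.list(fv))
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    stop("no readable, eligible (image, mask) pairs")
  if (length(errs) > 0) attr(out, "errors") <- dplyr::bind_rows(errs)
  out
}
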