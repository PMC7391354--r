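#' Draw one lesion specification from the cohort distribution
#'
#' The default per-lesion sampler used by [simulate_cohort()] and
#' [run_experiment()]: starting from a template, it draws the boundary
#' radius uniformly within +/- 30%, the irregularity uniformly in
#' `[0.1, 0.4]`, the mean lesion density uniformly within +/- 30 HU, and
#' the texture amplitude within +/- 30% — the way size, shape and density
#' vary across patients in a lesion test set.
#'
#' @param template a [lesion_spec()]
#' @param seed integer seed
#' @return a `lesion_spec`
#' @export
sample_lesion_spec <- function(template, seed) {
  with_seed(seed, {
    s <- template
    s$radius_mean <- template$radius_mean * stats::runif(1, 0.7, 1.3)
    s$radius_irregularity <- stats::runif(1, 0.1, 0.4)
    s$lesion_hu <- template$lesion_hu + stats::runif(1, -30, 30)
    s$texture_sd <- template$texture_sd * stats::runif(1, 0.7, 1.3)
    s
  })
}

#' Simulate a cohort of lesions with rater populations
#'
#' Generates `n_lesions` synthetic lesions and, for each, a set of
#' `k_raters` plausible segmentations from the boundary-perturbation
#' simulator. Lesion geometry and contrast vary across the cohort via
#' [sample_lesion_spec()], emulating the spread of a lesion test set.
#' Everything is a pure function of `seed`.
#'
#' @param n_lesions number of lesions (>= 2)
#' @param k_raters raters per lesion (>= 2; 25 matches a probabilistic
#'   sampler, 4 a small expert panel)
#' @param spec a [lesion_spec()] used as the cohort template, or a function
#'   `(i, seed)` returning one spec per lesion
#' @param params a [perturbation_params()] (calibrate beforehand with
#'   [calibrate_amplitude()] to hit a target median Dice)
#' @param seed integer seed
#' @param vary_lesions draw per-lesion geometry and contrast around the
#'   template with [sample_lesion_spec()] (ignored when `spec` is a
#'   function)
#' @return tibble of class `radstab_cohort`: `lesion_id`, `image`, `truth`,
#'   `raters` (list-columns), `seed`
#' @export
simulate_cohort <- function(n_lesions, k_raters = 25,
                            spec = lesion_preset("lung"),
                            params = perturbation_params(),
                            seed = 1, vary_lesions = TRUE) {
  stopifnot(n_lesions >= 2, k_raters >= 2)
  seeds <- derive_seeds(seed, 3 * n_lesions)
  dim(seeds) <- c(n_lesions, 3)

  make_spec <- if (is.function(spec)) {
    spec
  } else if (vary_lesions) {
    function(i, s) sample_lesion_spec(spec, s)
  } else {
    function(i, s) spec
  }

  rows <- lapply(seq_len(n_lesions), function(i) {
    sp <- make_spec(i, seeds[i, 1])
    les <- make_lesion(sp, seeds[i, 2])
    raters <- sample_rater_set(les$mask, params, k = k_raters,
                               spacing = sp$spacing, seed = seeds[i, 3])
    names(raters) <- sprintf("rater_%02d", seq_len(k_raters))
    tibble::tibble(
      lesion_id = sprintf("lesion_%03d", i),
      image = list(les$image), truth = list(les$mask),
      raters = list(raters), seed = seeds[i, 2]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("radstab_cohort", class(out))
  attr(out, "params") <- params
  out
}

#' Write a cohort to a directory of NIfTI files
#'
#' Layout: `cohort/<lesion_id>/{image.nii.gz, truth.nii.gz,
#' rater_<j>.nii.gz}`, with the pixel spacing stored in the header.
#'
#' @param cohort a [simulate_cohort()] tibble
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    ldir <- file.path(dir, cohort$lesion_id[i])
    dir.create(ldir, showWarnings = FALSE)
    sp <- grid_spacing(cohort$image[[i]])
    wr <- function(m, path) {
      RNifti::writeNifti(
        RNifti::asNifti(array(as.numeric(m), dim = dim(m)),
                        pixdim = sp), path)
    }
    wr(cohort$image[[i]], file.path(ldir, "image.nii.gz"))
    wr(cohort$truth[[i]], file.path(ldir, "truth.nii.gz"))
    rs <- cohort$raters[[i]]
    for (j in seq_along(rs)) {
      wr(rs[[j]], file.path(ldir, paste0(names(rs)[j], ".nii.gz")))
    }
  }
  invisible(dir)
}

#' Read one NIfTI image or mask as a matrix grid
#'
#' @param path NIfTI file
#' @param as_mask threshold at 0.5 and return logical
#' @return matrix with spacing attribute from the header
#' @export
read_nifti_grid <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:2]
  m <- as.matrix(img[, , drop = TRUE])
  if (as_mask) m <- m > 0.5
  image_grid(m, sp)
}
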