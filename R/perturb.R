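#' Parameters of the stochastic boundary perturbation
#'
#' Controls the segmentation simulator that stands in for a population of
#' raters: a smooth random displacement of the contour, plus the
#' rejection-sampling rule that discards implausible draws (a draw is kept
#' only if its Dice overlap with a reference segmentation exceeds
#' `accept_threshold`; the default 0.3 mirrors common practice for filtering
#' degenerate samples).
#'
#' @param amplitude mm scale of the boundary displacement (>= 0)
#' @param corr_len mm smoothness of the displacement field
#' @param accept_threshold Dice value for rejection sampling, in `[0, 1)`
#' @param max_attempts retries per draw before giving up
#' @return a `perturbation_params` object
#' @export
perturbation_params <- function(amplitude = 1, corr_len = 4,
                                accept_threshold = 0.3, max_attempts = 50L) {
  stopifnot(amplitude >= 0, corr_len > 0,
            accept_threshold >= 0, accept_threshold < 1, max_attempts >= 1)
  structure(
    list(amplitude = amplitude, corr_len = corr_len,
         accept_threshold = accept_threshold,
         max_attempts = as.integer(max_attempts)),
    class = "perturbation_params"
  )
}

#' Perturb a binary mask by displacing its boundary
#'
#' Computes the signed Euclidean distance field of the mask (positive inside,
#' in mm), adds a smooth zero-mean random field (white noise smoothed with a
#' Gaussian of width `corr_len`, standardised and scaled to `amplitude`),
#' re-thresholds at zero and keeps the largest 8-connected component. With
#' `amplitude = 0` the input is returned unchanged. Assumes isotropic pixel
#' spacing (the distance field lives on the pixel lattice); the synthetic
#' generator and the 1 mm resampling step both guarantee this.
#'
#' @param mask logical matrix, non-empty, single connected component
#' @param params a [perturbation_params()]
#' @param spacing mm per pixel (length 1 or 2; must be isotropic)
#' @param seed integer seed
#' @return a logical matrix of the same shape
#' @export
perturb_mask <- function(mask, params, spacing = 1, seed) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  if (n_components(mask) > 1) stop("mask must be a single connected component")
  if (length(spacing) > 1) {
    if (abs(spacing[1] - spacing[2]) > 1e-9)
      stop("perturb_mask requires isotropic spacing; resample first")
    spacing <- spacing[1]
  }
  if (params$amplitude == 0) return(mask)

  sdf <- signed_distance(mask) * spacing
  with_seed(seed, {
    for (attempt in seq_len(params$max_attempts)) {
      noise <- params$amplitude *
        random_field(nrow(mask), ncol(mask), params$corr_len / spacing)
      out <- (sdf + noise) > 0
      if (any(out)) return(largest_component(out))
    }
    stop("perturbation produced an empty mask in ", params$max_attempts,
         " attempts")
  })
}

#' Sample a set of simulated raters for one lesion
#'
#' Draws `k` perturbed masks from [perturb_mask()] under rejection sampling:
#' a draw is accepted only if its Dice coefficient with at least one
#' reference mask strictly exceeds `params$accept_threshold`. References
#' default to the ground truth alone; passing a list of expert masks mirrors
#' acceptance against "any of the expert segmentations".
#'
#' @param truth ground-truth logical mask to perturb
#' @param params a [perturbation_params()]
#' @param k number of raters to simulate (>= 2)
#' @param spacing mm per pixel
#' @param seed integer seed
#' @param reference_masks list of masks used in the acceptance test
#'   (default: the truth itself)
#' @return list of `k` logical masks (a rater set)
#' @export
sample_rater_set <- function(truth, params, k, spacing = 1, seed,
                             reference_masks = list(truth)) {
  stopifnot(k >= 2)
  seeds <- derive_seeds(seed, k * params$max_attempts)
  dim(seeds) <- c(k, params$max_attempts)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (attempt in seq_len(params$max_attempts)) {
      m <- perturb_mask(truth, params, spacing, seeds[j, attempt])
      dvals <- vapply(reference_masks, function(r) dice(m, r), numeric(1))
      if (any(dvals > params$accept_threshold, na.rm = TRUE)) {
        out[[j]] <- m
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("rater slot ", j, ": no draw exceeded Dice ",
           params$accept_threshold, " in ", params$max_attempts, " attempts")
    }
  }
  out
}

#' Calibrate the perturbation amplitude to a target Dice agreement
#'
#' Bisection on `amplitude` (fixed `corr_len`) until the median pairwise Dice
#' of a 20-draw rater set falls within +/- 0.02 of `target_median_dice`.
#' Every evaluation reuses the same seed (common random numbers), so the
#' evaluated agreement is a deterministic, monotone-decreasing function of
#' amplitude and bisection converges cleanly. With `reference_set` supplied,
#' the objective is instead the median cross Dice between the draws and
#' those fixed reference masks (used to match one rater population's
#' agreement against another).
#'
#' @param truth ground-truth logical mask, or a list of masks; with several
#'   masks the objective is the median of the Dice values pooled over all of
#'   them (calibrating a whole cohort's agreement distribution)
#' @param target_median_dice target median pairwise Dice, in (0, 1)
#' @param params starting [perturbation_params()]; amplitude is overwritten
#' @param spacing mm per pixel
#' @param seed integer seed for the calibration draws
#' @param amplitude_range search interval in mm
#' @param n_draws raters per evaluation (default 20)
#' @param reference_set optional list of fixed masks (or, with several
#'   truths, a parallel list of such lists); calibrates the median cross
#'   Dice against them instead of the within-set median
#' @return `params` with the calibrated amplitude
#' @export
calibrate_amplitude <- function(truth, target_median_dice, params,
                                spacing = 1, seed,
                                amplitude_range = c(1e-3, 25), n_draws = 20,
                                reference_set = NULL) {
  stopifnot(target_median_dice > 0, target_median_dice < 1)
  truths <- if (is.list(truth)) truth else list(truth)
  refsets <- if (is.null(reference_set)) {
    NULL
  } else if (is.matrix(reference_set[[1]])) {
    rep(list(reference_set), length(truths))
  } else {
    stopifnot(length(reference_set) == length(truths))
    reference_set
  }
  truth_seeds <- derive_seeds(seed, length(truths))
  # an amplitude at which rejection sampling cannot produce accepted draws
  # is simply far below the target agreement; score it 0 so bisection backs
  # off rather than aborting
  eval_median <- function(amp) {
    p <- params
    p$amplitude <- amp
    dm <- tryCatch(
      unlist(lapply(seq_along(truths), function(i) {
        rs <- sample_rater_set(truths[[i]], p, k = n_draws, spacing = spacing,
                               seed = truth_seeds[i])
        if (is.null(refsets)) {
          m <- pairwise_dice(rs)
          m[upper.tri(m)]
        } else {
          as.vector(pairwise_dice(rs, refsets[[i]]))
        }
      })),
      error = function(e) 0
    )
    stats::median(dm, na.rm = TRUE)
  }
  lo <- amplitude_range[1]; hi <- amplitude_range[2]
  f_lo <- eval_median(lo); f_hi <- eval_median(hi)
  if (f_lo < target_median_dice - 0.02 || f_hi > target_median_dice + 0.02) {
    stop(sprintf(
      "target median Dice %.3f unattainable: achieved range [%.3f, %.3f] over amplitudes [%g, %g]",
      target_median_dice, f_hi, f_lo, lo, hi))
  }
  amp <- (lo + hi) / 2
  for (i in 1:40) {
    amp <- (lo + hi) / 2
    f <- eval_median(amp)
    if (abs(f - target_median_dice) <= 0.01 || (hi - lo) < 1e-4) break
    if (f > target_median_dice) lo <- amp else hi <- amp
  }
  params$amplitude <- amp
  params
}
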