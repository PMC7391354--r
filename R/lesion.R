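#' Specify a synthetic CT lesion phantom
#'
#' Describes one CT-like lesion: a star-convex bright (or dark) body with
#' correlated intratumoral texture on a noisy background, blurred at the edge
#' to mimic partial-volume averaging. Units are Hounsfield units (HU) for
#' intensities and millimetres for lengths.
#'
#' @param background_hu mean HU of the surrounding tissue
#' @param background_noise_sd HU standard deviation of background white noise
#' @param lesion_hu mean HU inside the lesion
#' @param texture_sd HU amplitude of the correlated intralesional random field
#' @param texture_corr_len correlation length of that field, mm
#' @param edge_blur_sigma Gaussian blur applied to the final image, mm
#' @param radius_mean mean boundary radius, mm (must be positive)
#' @param radius_irregularity in `[0, 1)`; amplitude of the smooth periodic
#'   modulation of the boundary radius (0 = perfect disc)
#' @param image_size pixels per side of the square grid
#' @param spacing mm per pixel (isotropic)
#' @return a `lesion_spec` object (a validated list)
#' @seealso [lesion_preset()] for the built-in contrast regimes
#' @export
lesion_spec <- function(background_hu, background_noise_sd, lesion_hu,
                        texture_sd, texture_corr_len, edge_blur_sigma,
                        radius_mean, radius_irregularity,
                        image_size, spacing = 1) {
  stopifnot(
    radius_mean > 0, spacing > 0, image_size >= 8,
    radius_irregularity >= 0, radius_irregularity < 1,
    background_noise_sd >= 0, texture_sd >= 0,
    texture_corr_len > 0, edge_blur_sigma >= 0
  )
  structure(
    list(
      background_hu = background_hu, background_noise_sd = background_noise_sd,
      lesion_hu = lesion_hu, texture_sd = texture_sd,
      texture_corr_len = texture_corr_len, edge_blur_sigma = edge_blur_sigma,
      radius_mean = radius_mean, radius_irregularity = radius_irregularity,
      image_size = as.integer(image_size), spacing = spacing
    ),
    class = "lesion_spec"
  )
}

#' Built-in lesion contrast presets
#'
#' Two regimes bracket the contrast conditions seen in thoracic and abdominal
#' CT. `"lung"` is a high-contrast nodule (~40 HU lesion on an ~-800 HU
#' aerated-lung background, 128 px grid); `"abdomen"` is a low-contrast
#' parenchymal tumour (~50 HU lesion on a ~90 HU enhancing-organ background,
#' 192 px grid). Lesion-background contrast is the main driver of non-shape
#' feature instability under contour variation, so both regimes should be
#' exercised when judging feature robustness.
#'
#' @param preset `"lung"` or `"abdomen"`
#' @param ... overrides passed to [lesion_spec()] fields
#' @return a `lesion_spec`
#' @export
lesion_preset <- function(preset = c("lung", "abdomen"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    lung = list(
      background_hu = -800, background_noise_sd = 40, lesion_hu = 40,
      texture_sd = 30, texture_corr_len = 3, edge_blur_sigma = 0.7,
      radius_mean = 8, radius_irregularity = 0.3,
      image_size = 128, spacing = 1
    ),
    abdomen = list(
      background_hu = 90, background_noise_sd = 15, lesion_hu = 50,
      texture_sd = 15, texture_corr_len = 4, edge_blur_sigma = 1,
      radius_mean = 15, radius_irregularity = 0.25,
      image_size = 192, spacing = 1
    )
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(lesion_spec, base)
}

#' Generate one synthetic lesion image and its ground-truth mask
#'
#' The boundary is star-convex: radius(theta) = `radius_mean` * (1 +
#' `radius_irregularity` * s(theta)) where s is a smooth periodic harmonic
#' noise normalised to max |s| = 1. Lesion pixels carry `lesion_hu` plus a
#' correlated Gaussian texture field; background pixels carry `background_hu`
#' plus white noise; the composite is blurred by `edge_blur_sigma`. Identical
#' (spec, seed) pairs give bit-identical output.
#'
#' @param spec a [lesion_spec()]
#' @param seed integer seed
#' @return list with `image` (numeric matrix with spacing attribute, HU) and
#'   `mask` (logical matrix, single connected component)
#' @export
make_lesion <- function(spec, seed) {
  stopifnot(inherits(spec, "lesion_spec"))
  n <- spec$image_size
  sp <- spec$spacing
  max_r <- spec$radius_mean * (1 + spec$radius_irregularity)
  if (max_r + 2 * sp > (n / 2) * sp) {
    stop("lesion (radius up to ", round(max_r, 1),
         " mm) does not fit in a ", n, "-pixel image with a 2-pixel margin")
  }

  with_seed(seed, {
    ctr <- (n + 1) / 2
    xs <- (seq_len(n) - ctr) * sp
    X <- matrix(xs, n, n, byrow = TRUE)   # col offsets, mm
    Y <- matrix(xs, n, n)                 # row offsets, mm
    r <- sqrt(X^2 + Y^2)
    th <- atan2(Y, X)

    if (spec$radius_irregularity > 0) {
      harm <- 2:5
      a <- stats::rnorm(length(harm)) / harm
      b <- stats::rnorm(length(harm)) / harm
      sfun <- function(t) {
        s <- 0
        for (i in seq_along(harm)) s <- s + a[i] * cos(harm[i] * t) + b[i] * sin(harm[i] * t)
        s
      }
      smax <- max(abs(sfun(seq(0, 2 * pi, length.out = 721))))
      modf <- if (smax > 0) sfun(th) / smax else 0
    } else {
      modf <- 0
    }
    rim <- spec$radius_mean * (1 + spec$radius_irregularity * modf)
    mask <- r <= rim

    bg <- spec$background_hu +
      if (spec$background_noise_sd > 0)
        matrix(stats::rnorm(n * n, sd = spec$background_noise_sd), n, n)
      else 0
    tex <- spec$lesion_hu +
      if (spec$texture_sd > 0)
        spec$texture_sd * random_field(n, n, spec$texture_corr_len / sp)
      else 0
    img <- ifelse(mask, tex, bg)
    if (spec$edge_blur_sigma > 0) {
      img <- smooth_gaussian(img, spec$edge_blur_sigma / sp)
    }
    list(image = image_grid(img, sp), mask = largest_component(mask))
  })
}
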