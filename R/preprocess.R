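#' Preprocessing protocol configuration
#'
#' The fixed image-conditioning protocol applied before feature extraction:
#' isotropic resampling, fixed-bin-width intensity discretisation, lesion
#' eligibility rules, and the crop taken around the lesion centre. Defaults
#' are the protocol constants used throughout: 1 mm spacing, 25 HU bins,
#' 30 mm^3 minimum lesion volume, and a fill of -1000 HU (air) outside organ
#' masks.
#'
#' @param target_spacing mm, isotropic resampling target
#' @param bin_width HU, fixed bin width for gray-level discretisation
#' @param crop_size pixels per side of the square crop (128 suits lung
#'   fields of view, 192 abdominal ones)
#' @param min_volume mm^3, minimum lesion volume to be eligible
#' @param mask_fill_value HU written outside an organ mask
#' @param slice_thickness mm assigned to the analysed slice when 2D areas are
#'   promoted to volumes (one-voxel-thick extrusion)
#' @return a `preprocess_config` object
#' @export
preprocess_config <- function(target_spacing = 1, bin_width = 25,
                              crop_size = 128, min_volume = 30,
                              mask_fill_value = -1000, slice_thickness = 1) {
  stopifnot(target_spacing > 0, bin_width > 0, min_volume >= 0,
            crop_size >= 8, slice_thickness > 0)
  structure(
    list(target_spacing = target_spacing, bin_width = bin_width,
         crop_size = as.integer(crop_size), min_volume = min_volume,
         mask_fill_value = mask_fill_value, slice_thickness = slice_thickness),
    class = "preprocess_config"
  )
}

#' Resample an image and mask to an isotropic spacing
#'
#' The image is interpolated bilinearly, the mask by nearest neighbour.
#' Output pixel centres sit at `(i - 0.5) * target_spacing`; input values are
#' looked up at the corresponding physical point with edge clamping. If the
#' input spacing already equals the target, the inputs are returned
#' untouched.
#'
#' @param image numeric matrix with a spacing attribute (see [image_grid()])
#' @param mask logical matrix on the same grid
#' @param target_spacing mm, the isotropic output spacing
#' @param spacing override for the input spacing (defaults to the attribute)
#' @return list with resampled `image` and `mask`
#' @export
resample <- function(image, mask, target_spacing = 1,
                     spacing = grid_spacing(image)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (any(spacing <= 0)) stop("input spacing must be positive")
  stopifnot(target_spacing > 0)
  if (all(abs(spacing - target_spacing) < 1e-12)) {
    return(list(image = image_grid(image, spacing), mask = mask))
  }
  n_in <- dim(image)
  n_out <- pmax(1L, as.integer(round(n_in * spacing / target_spacing)))

  # continuous input index (1-based pixel centres) of each output centre
  coord <- function(n, s_in, s_t) ((seq_len(n) - 0.5) * s_t) / s_in + 0.5
  ri <- coord(n_out[1], spacing[1], target_spacing)
  ci <- coord(n_out[2], spacing[2], target_spacing)

  bilinear <- function(m, ri, ci) {
    r0 <- pmin(pmax(floor(ri), 1), nrow(m)); r1 <- pmin(r0 + 1, nrow(m))
    c0 <- pmin(pmax(floor(ci), 1), ncol(m)); c1 <- pmin(c0 + 1, ncol(m))
    fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
    FR <- matrix(fr, length(ri), length(ci))
    FC <- matrix(fc, length(ri), length(ci), byrow = TRUE)
    m[r0, c0] * (1 - FR) * (1 - FC) + m[r1, c0] * FR * (1 - FC) +
      m[r0, c1] * (1 - FR) * FC + m[r1, c1] * FR * FC
  }
  nearest <- function(m, ri, ci) {
    r <- pmin(pmax(round(ri), 1), nrow(m))
    c <- pmin(pmax(round(ci), 1), ncol(m))
    m[r, c]
  }
  list(
    image = image_grid(bilinear(image, ri, ci), target_spacing),
    mask = nearest(mask, ri, ci)
  )
}

#' Crop a fixed-size window around the lesion centre
#'
#' The lesion centre is the centre of the minimal axis-aligned rectangle
#' covering the mask; on even extents the tie breaks toward the lower index.
#' If the window overruns the image it is padded with `pad_value` (image) and
#' `FALSE` (mask), and the result carries a `padded` attribute.
#'
#' @param image numeric matrix
#' @param mask non-empty logical matrix, same shape
#' @param crop_size output side length in pixels
#' @param pad_value HU used where the crop exceeds the image
#' @return list with cropped `image` and `mask` (both `crop_size` square)
#' @export
crop_roi <- function(image, mask, crop_size, pad_value = -1000) {
  if (!any(mask)) stop("cannot crop around an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  if ((r2 - r1 + 1) > crop_size || (c2 - c1 + 1) > crop_size) {
    stop("lesion bounding box exceeds crop_size")
  }
  ctr <- c(floor((r1 + r2) / 2), floor((c1 + c2) / 2))
  half_lo <- floor((crop_size - 1) / 2)
  rows <- (ctr[1] - half_lo):(ctr[1] - half_lo + crop_size - 1)
  cols <- (ctr[2] - half_lo):(ctr[2] - half_lo + crop_size - 1)

  img_out <- matrix(pad_value, crop_size, crop_size)
  msk_out <- matrix(FALSE, crop_size, crop_size)
  rin <- rows >= 1 & rows <= nrow(image)
  cin <- cols >= 1 & cols <= ncol(image)
  img_out[rin, cin] <- image[rows[rin], cols[cin]]
  msk_out[rin, cin] <- mask[rows[rin], cols[cin]]
  padded <- !(all(rin) && all(cin))
  out_img <- image_grid(img_out, grid_spacing(image))
  attr(out_img, "padded") <- padded
  list(image = out_img, mask = msk_out, centre = ctr, padded = padded)
}

#' Mask an image to an organ, filling the outside
#'
#' Pixels outside the organ mask are replaced by `fill` (default air); pixels
#' inside are untouched. Prevents tissue outside the organ of interest from
#' leaking into the analysis.
#'
#' @param image numeric matrix
#' @param organ logical matrix, same shape
#' @param fill HU value written outside the organ
#' @return the masked image
#' @export
apply_organ_mask <- function(image, organ, fill = -1000) {
  if (!identical(dim(image), dim(organ))) stop("image and organ shapes differ")
  out <- image
  out[!organ] <- fill
  out
}

#' Select the principal slice of a 3D mask stack
#'
#' Returns the index of the slice with the largest segmented area — the
#' slice on which the 2D analysis is performed. Ties break toward the lowest
#' index.
#'
#' @param mask3d a 3D logical array (row, col, slice) or list of 2D masks
#' @return integer slice index
#' @export
select_principal_slice <- function(mask3d) {
  areas <- if (is.list(mask3d)) {
    vapply(mask3d, sum, numeric(1))
  } else {
    apply(mask3d, 3, sum)
  }
  if (all(areas == 0)) stop("all slices are empty")
  which.max(areas)
}

#' Lesion eligibility filter
#'
#' A lesion slice enters the analysis only if its mask is one connected
#' component (8-connectivity; disconnected fragments make shape features
#' incomparable) and its extruded volume `area x spacing^2 x slice_thickness`
#' reaches `min_volume` (default 30 mm^3; smaller lesions are dominated by
#' partial-volume effects).
#'
#' @param mask logical matrix
#' @param spacing mm per pixel (length 1 or 2)
#' @param slice_thickness mm
#' @param min_volume mm^3
#' @return a one-row tibble: `accept` (logical), `reason` (`NA` if accepted,
#'   else `"empty"`, `"components"` or `"volume"`), `volume_mm3`,
#'   `n_components`
#' @export
eligibility_filter <- function(mask, spacing = 1, slice_thickness = 1,
                               min_volume = 30) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  area_px <- sum(mask)
  vol <- area_px * spacing[1] * spacing[2] * slice_thickness
  ncomp <- if (area_px > 0) n_components(mask) else 0L
  reason <- if (area_px == 0) "empty"
    else if (ncomp > 1) "components"
    else if (vol < min_volume) "volume"
    else NA_character_
  tibble::tibble(accept = is.na(reason), reason = reason,
                 volume_mm3 = vol, n_components = ncomp)
}

#' Radius of the sphere with a given volume
#'
#' `(3 V / 4 pi)^(1/3)`; e.g. the 30 mm^3 eligibility floor corresponds to a
#' 1.92 mm sphere radius.
#'
#' @param volume mm^3, positive
#' @return radius in mm
#' @export
min_sphere_radius <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Discretise in-mask intensities with a fixed bin width
#'
#' Gray level `floor((x - min_in_mask) / bin_width) + 1`, anchored at the ROI
#' minimum so that levels start at 1 and the discretisation is invariant to
#' any constant intensity shift. Levels are defined only inside the mask.
#'
#' @param image numeric matrix (HU)
#' @param mask non-empty logical matrix
#' @param bin_width HU per gray level
#' @return a `discretized_roi`: list with `levels` (integer matrix, `NA`
#'   outside mask), `mask`, `raw` (original HU), `Ng` (highest occupied
#'   level)
#' @export
discretize <- function(image, mask, bin_width = 25) {
  if (!any(mask)) stop("cannot discretize an empty ROI")
  stopifnot(bin_width > 0)
  vals <- image[mask]
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  lev[mask] <- as.integer(floor((vals - min(vals)) / bin_width) + 1)
  structure(
    list(levels = lev, mask = mask, raw = image, Ng = max(lev, na.rm = TRUE),
         spacing = grid_spacing(image)),
    class = "discretized_roi"
  )
}
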