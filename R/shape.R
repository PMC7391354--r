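#' 2D shape features of a lesion mask (12 features)
#'
#' Geometry of the segmented region, computed in physical units on the
#' analysed slice, with areas promoted to volumes by a one-voxel-thick
#' extrusion of thickness `slice_thickness`. The boundary polygon comes from
#' a marching-squares contour of the mask at the half level, giving
#' `Perimeter` and the mesh area; the extruded body then has
#' `MeshVolume = area x thickness` and
#' `SurfaceArea = 2 x area + perimeter x thickness`, from which
#' `SurfaceVolumeRatio`, `Sphericity` (`(36 pi V^2)^(1/3) / A`) and
#' `SphericalDisproportion` (its reciprocal) follow.
#' `Maximum2DDiameterSlice` is the largest distance between boundary pixel
#' centres; `MajorAxisLength`/`MinorAxisLength` are `4 sqrt(lambda)` from the
#' eigenvalues of the physical pixel-coordinate covariance, and `Elongation`
#' is `sqrt(lambda_minor / lambda_major)`. `PerimeterSurfaceRatio` is the 2D
#' perimeter over the mesh (slice) area.
#'
#' @param mask non-empty, single-component logical matrix
#' @param spacing mm per pixel (length 1 or 2)
#' @param slice_thickness mm of the extrusion
#' @return named numeric vector of 12 features
#' @export
shape_features <- function(mask, spacing = 1, slice_thickness = 1) {
  if (!any(mask)) stop("empty mask")
  if (n_components(mask) > 1) stop("mask must be a single connected component")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  t <- slice_thickness

  npx <- sum(mask)
  voxel_volume <- npx * spacing[1] * spacing[2] * t

  geo <- mask_contour_geometry(mask, spacing)
  area <- geo$area
  perim <- geo$perimeter

  mesh_volume <- area * t
  surface <- 2 * area + perim * t
  svr <- surface / mesh_volume
  sphericity <- (36 * pi * mesh_volume^2)^(1 / 3) / surface

  # boundary pixel centres: in-mask pixels with an out-of-mask 4-neighbour
  b <- boundary_pixels(mask)
  pts <- cbind(b[, 1] * spacing[1], b[, 2] * spacing[2])
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  maxdiam <- if (nrow(hp) < 2) 0 else max(stats::dist(hp))

  idx <- which(mask, arr.ind = TRUE)
  phys <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
  if (nrow(phys) > 1) {
    ev <- sort(eigen(stats::cov(phys) * (nrow(phys) - 1) / nrow(phys),
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
  } else {
    ev <- c(0, 0)
  }
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] == 0) 1 else sqrt(ev[2] / ev[1])

  c(
    MeshVolume = mesh_volume,
    VoxelVolume = voxel_volume,
    SurfaceArea = surface,
    SurfaceVolumeRatio = svr,
    Sphericity = sphericity,
    SphericalDisproportion = 1 / sphericity,
    Maximum2DDiameterSlice = maxdiam,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Elongation = elong,
    Perimeter = perim,
    PerimeterSurfaceRatio = perim / area
  )
}

# marching-squares contour of the mask at level 0.5 on a zero-padded grid;
# returns total polygon perimeter and net enclosed area (holes subtracted),
# both in physical units
mask_contour_geometry <- function(mask, spacing) {
  padded <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask)
  xs <- (seq_len(nrow(padded)) - 1) * spacing[1]
  ys <- (seq_len(ncol(padded)) - 1) * spacing[2]
  cl <- grDevices::contourLines(xs, ys, padded, levels = 0.5)
  if (length(cl) == 0) stop("no contour found")
  seg_len <- function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  shoelace <- function(p) {
    x <- p$x; y <- p$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  areas <- vapply(cl, shoelace, numeric(1))
  # single component: the largest contour is the outer boundary, any others
  # are holes
  net_area <- if (length(areas) == 1) areas else {
    2 * max(areas) - sum(areas)
  }
  list(perimeter = sum(vapply(cl, seg_len, numeric(1))), area = net_area)
}

# row/col indices of in-mask pixels touching the outside (4-neighbourhood,
# image border counts as outside)
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb_all <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(core & !nb_all, arr.ind = TRUE)
}
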