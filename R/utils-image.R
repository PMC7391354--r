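# Internal image primitives shared by the simulator, preprocessing and the
# texture extractors. All operate on plain numeric/logical matrices; physical
# spacing is carried separately (mm per pixel).

#' Attach physical pixel spacing to a matrix
#'
#' Images and masks are plain matrices; spacing (mm per pixel, one value per
#' axis) travels as an attribute so grids stay pipe-friendly.
#'
#' @param x numeric or logical matrix
#' @param spacing numeric length-1 or length-2, mm per pixel (row, col)
#' @return `x` with a `spacing` attribute
#' @export
image_grid <- function(x, spacing = c(1, 1)) {
  stopifnot(is.matrix(x), all(spacing > 0))
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  attr(x, "spacing") <- as.numeric(spacing[1:2])
  x
}

#' Read the spacing attribute of a grid
#'
#' @param x matrix created with [image_grid()] (or any matrix; defaults to 1 mm)
#' @return numeric length-2 spacing in mm
#' @export
grid_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1) else s
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive n reproducible child seeds (< 2^31) from one parent seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# separable Gaussian smoothing via row-normalised banded matrix products.
# Row normalisation preserves constants, behaving like replicate padding at
# the edges. sigma in pixels; sigma = 0 returns the input.
smooth_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  band <- function(n) {
    idx <- seq_len(n)
    k <- exp(-(outer(idx, idx, "-"))^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  kr <- band(nrow(x))
  kc <- band(ncol(x))
  kr %*% x %*% t(kc)
}

# a smooth zero-mean unit-sd Gaussian random field (draws from the current
# RNG stream); corr_len_px controls the correlation length in pixels
random_field <- function(nrow, ncol, corr_len_px) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  f <- smooth_gaussian(z, corr_len_px)
  s <- stats::sd(as.vector(f))
  if (s == 0) matrix(0, nrow, ncol) else (f - mean(f)) / s
}

# connected-component labelling: 4-connectivity from EBImage::bwlabel, with
# a union-find merge of diagonally touching labels for 8-connectivity.
# Returns an integer matrix, 0 = background, components numbered 1..n.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  lab <- matrix(as.integer(round(
    EBImage::bwlabel(matrix(as.numeric(mask), nr, nc)))), nr, nc)
  nl <- max(lab)
  if (connectivity == 8 && nl > 1 && nr > 1 && nc > 1) {
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # / diagonal
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(nl)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      pairs <- unique(pairs)
      for (q in seq_len(nrow(pairs))) {
        ra <- find(pairs[q, 1]); rb <- find(pairs[q, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nl), find, integer(1))
      relab <- match(roots, unique(roots))
      lab[mask] <- relab[lab[mask]]
    }
  }
  lab
}

n_components <- function(mask, connectivity = 8) {
  max(label_components(mask, connectivity))
}

# keep only the largest connected component (8-connectivity); ties broken
# toward the component appearing first in column-major order
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  mask & (lab == which.max(sizes))
}

# signed Euclidean distance field in pixels: positive inside, negative
# outside. distmap() returns >= 1 for any foreground pixel, so half a pixel
# is subtracted on each side to place the zero level on the mask boundary
# (between pixel centres); sub-pixel displacements then behave correctly.
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1 - m))
  ifelse(mask, din - 0.5, 0.5 - dout)
}
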