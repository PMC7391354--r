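#' Build the neighbourhood gray-tone difference matrix
#'
#' For each occupied gray level i, sums over all in-mask pixels of that
#' level the absolute difference between i and the mean gray level of the
#' pixel's in-mask 8-neighbours (the pixel itself excluded). Pixels with no
#' in-mask neighbour contribute zero.
#'
#' @param roi a [discretize()]d ROI
#' @return list with `s` (per-level difference sums), `n` (per-level pixel
#'   counts), `p` (level probabilities), `Ng`, `Np`
#' @export
build_ngtdm <- function(roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  lev <- roi$levels
  mask <- roi$mask
  ng <- roi$Ng
  nr <- nrow(lev); nc <- ncol(lev)

  vals <- ifelse(mask, lev, 0)
  cnt <- matrix(as.numeric(mask), nr, nc)
  pad_sum <- function(m) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    out
  }
  nb_sum <- pad_sum(vals)
  nb_cnt <- pad_sum(cnt)

  diffs <- matrix(0, nr, nc)
  has_nb <- mask & nb_cnt > 0
  diffs[has_nb] <- abs(lev[has_nb] - nb_sum[has_nb] / nb_cnt[has_nb])

  s <- vapply(seq_len(ng), function(g) sum(diffs[mask & lev == g]), numeric(1))
  n <- vapply(seq_len(ng), function(g) sum(mask & lev == g), numeric(1))
  np <- sum(mask)
  list(s = s, n = n, p = n / np, Ng = ng, Np = np)
}

#' NGTDM texture features (5 features)
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' neighbourhood gray-tone difference table. When the difference sums are
#' all zero (a constant ROI), Coarseness is capped at 1e6 and
#' Busyness/Strength are 0; Contrast is 0 when only one level is occupied.
#'
#' @param ngt output of [build_ngtdm()]
#' @return named numeric vector of 5 features
#' @export
ngtdm_features <- function(ngt) {
  p <- ngt$p; s <- ngt$s; np <- ngt$Np
  occ <- which(p > 0)
  ngp <- length(occ)
  iv <- seq_along(p)

  denom_coarse <- sum(p * s)
  coarseness <- if (denom_coarse == 0) 1e6 else 1 / denom_coarse

  contrast <- if (ngp <= 1) 0 else {
    ij <- expand.grid(i = occ, j = occ)
    sum(p[ij$i] * p[ij$j] * (ij$i - ij$j)^2) / (ngp * (ngp - 1)) *
      sum(s) / np
  }

  denom_busy <- if (ngp == 0) 0 else {
    ij <- expand.grid(i = occ, j = occ)
    sum(abs(ij$i * p[ij$i] - ij$j * p[ij$j]))
  }
  busyness <- if (denom_busy == 0) 0 else sum(p * s) / denom_busy

  complexity <- if (ngp == 0) 0 else {
    ij <- expand.grid(i = occ, j = occ)
    sum(abs(ij$i - ij$j) *
          (p[ij$i] * s[ij$i] + p[ij$j] * s[ij$j]) /
          (p[ij$i] + p[ij$j])) / np
  }

  denom_strength <- sum(s)
  strength <- if (denom_strength == 0) 0 else {
    ij <- expand.grid(i = occ, j = occ)
    sum((p[ij$i] + p[ij$j]) * (ij$i - ij$j)^2) / denom_strength
  }

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
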