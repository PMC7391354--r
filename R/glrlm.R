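#' Build gray-level run-length matrices
#'
#' A run is a maximal collinear segment of in-mask pixels sharing one gray
#' level. Runs are counted separately along the four unique 2D directions
#' (0, 45, 90, 135 degrees); out-of-mask pixels break runs.
#'
#' @param roi a [discretize()]d ROI
#' @return named list of four Ng x max-run-length count matrices
#' @export
build_glrlm <- function(roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  lev <- roi$levels
  ng <- roi$Ng
  lines_by_dir <- list(
    `0` = matrix_lines(lev, "row"),
    `45` = matrix_lines(lev, "anti"),
    `90` = matrix_lines(lev, "col"),
    `135` = matrix_lines(lev, "diag")
  )
  max_len <- max(sum(roi$mask), 1)
  lapply(lines_by_dir, function(lines) {
    runs <- run_table(lines)
    m <- matrix(0, ng, max(runs$len, 1))
    for (q in seq_along(runs$lev)) {
      m[runs$lev[q], runs$len[q]] <- m[runs$lev[q], runs$len[q]] + 1
    }
    m
  })
}

# decompose a level matrix into scan lines for a direction
matrix_lines <- function(lev, dir) {
  nr <- nrow(lev); nc <- ncol(lev)
  switch(dir,
    row = lapply(seq_len(nr), function(r) lev[r, ]),
    col = lapply(seq_len(nc), function(c) lev[, c]),
    # main diagonals, r - c constant (direction (+1, +1))
    diag = lapply((1 - nc):(nr - 1), function(k) {
      r <- max(1, 1 + k):min(nr, nc + k)
      c <- r - k
      lev[cbind(r, c)]
    }),
    # anti-diagonals, r + c constant (direction (-1, +1))
    anti = lapply(seq_len(nr + nc - 1), function(d) {
      r <- max(1, d - nc + 1):min(nr, d)
      c <- d - r + 1
      lev[cbind(r, c)]
    })
  )
}

# enumerate (level, run length) for all maximal runs over NA-broken lines
run_table <- function(lines) {
  levs <- integer(0); lens <- integer(0)
  for (v in lines) {
    if (all(is.na(v))) next
    r <- rle(ifelse(is.na(v), -1L, v))
    keep <- r$values != -1L
    levs <- c(levs, r$values[keep])
    lens <- c(lens, r$lengths[keep])
  }
  list(lev = levs, len = lens)
}

#' GLRLM texture features (16 features)
#'
#' Run-length statistics computed per direction and averaged over the four
#' directions. `Np` is the in-mask pixel count; `Nr` the total run count per
#' direction.
#'
#' @param matrices output of [build_glrlm()]
#' @param n_pixels in-mask pixel count (for `RunPercentage`)
#' @return named numeric vector of 16 features
#' @export
glrlm_features <- function(matrices, n_pixels) {
  per_dir <- vapply(matrices, glrlm_features_single,
                    numeric(16), n_pixels = n_pixels)
  rowMeans(per_dir)
}

glrlm_features_single <- function(P, n_pixels) {
  nr_tot <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- P / nr_tot
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  ri <- rowSums(P); rj <- colSums(P)
  xlog2 <- function(v) ifelse(v > 0, log2(v), 0)

  c(
    ShortRunEmphasis = sum(P / j^2) / nr_tot,
    LongRunEmphasis = sum(P * j^2) / nr_tot,
    GrayLevelNonUniformity = sum(ri^2) / nr_tot,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr_tot^2,
    RunLengthNonUniformity = sum(rj^2) / nr_tot,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr_tot^2,
    RunPercentage = nr_tot / n_pixels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = -sum(p * xlog2(p)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr_tot,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr_tot,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr_tot,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr_tot,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr_tot,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr_tot
  )
}
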