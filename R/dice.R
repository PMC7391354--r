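#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. When both masks are empty the overlap is
#' undefined and `NA` is returned (never 0 or 1); such pairs are dropped,
#' with a count, from any downstream summary.
#'
#' @param a,b logical matrices of identical shape
#' @return Dice coefficient in `[0, 1]`, or `NA` if both masks are empty
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

#' Pairwise Dice matrix of one or two rater sets
#'
#' Within-set mode (`set_b = NULL`) returns the symmetric k x k matrix with
#' unit diagonal; cross mode returns all `length(set_a) x length(set_b)`
#' pairs. Use [dice_summary()] for the median/IQR the agreement analyses
#' report.
#'
#' @param set_a list of logical masks
#' @param set_b optional second list for cross comparison
#' @return a numeric matrix of class `dice_matrix`, with a `mode` attribute
#'   (`"within"` or `"cross"`)
#' @export
pairwise_dice <- function(set_a, set_b = NULL) {
  if (is.null(set_b)) {
    k <- length(set_a)
    stopifnot(k >= 2)
    m <- diag(1, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- dice(set_a[[i]], set_a[[j]])
      }
    }
    dimnames(m) <- list(names(set_a) %||% paste0("r", seq_len(k)),
                        names(set_a) %||% paste0("r", seq_len(k)))
    attr(m, "mode") <- "within"
  } else {
    stopifnot(length(set_a) >= 1, length(set_b) >= 1)
    m <- matrix(NA_real_, length(set_a), length(set_b))
    for (i in seq_along(set_a)) {
      for (j in seq_along(set_b)) {
        m[i, j] <- dice(set_a[[i]], set_b[[j]])
      }
    }
    dimnames(m) <- list(names(set_a) %||% paste0("a", seq_along(set_a)),
                        names(set_b) %||% paste0("b", seq_along(set_b)))
    attr(m, "mode") <- "cross"
  }
  class(m) <- c("dice_matrix", class(m))
  m
}

#' Summarise a Dice matrix as median and interquartile range
#'
#' Within-set matrices are summarised over the off-diagonal upper triangle;
#' cross matrices over all entries. Undefined (both-empty) pairs are dropped
#' and counted. IQR bounds are the 25th/75th percentiles with linear
#' interpolation.
#'
#' @param m a `dice_matrix` from [pairwise_dice()]
#' @return a one-row tibble: `median`, `iqr_low`, `iqr_high`, `n_pairs`,
#'   `n_undefined`
#' @export
dice_summary <- function(m) {
  vals <- if (identical(attr(m, "mode"), "cross")) as.vector(m) else m[upper.tri(m)]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    n_pairs = length(vals), n_undefined = n_undef
  )
}

#' @importFrom rlang %||%
NULL
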