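#' ICC(1,1): one-way random-effects intraclass correlation
#'
#' For an `n x k` table of one feature measured by `k` raters on `n`
#' lesions: `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` where MSB/MSW are the
#' between-/within-lesion mean squares of the one-way random-effects ANOVA.
#' The estimate may be negative (it is not floored); perfect agreement
#' (`MSW = 0` with between-lesion spread) gives exactly 1; a table with zero
#' total variance has no defined ICC and returns `NA`.
#'
#' @param table numeric matrix or data frame, lesions in rows, raters in
#'   columns, no missing cells
#' @return the ICC point estimate (possibly negative), or `NA` if undefined
#' @export
icc_1_1 <- function(table) {
  x <- as.matrix(table)
  stopifnot(is.numeric(x), nrow(x) >= 2, ncol(x) >= 2, !anyNA(x))
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm <- rowMeans(x)
  ssb <- k * sum((rm - grand)^2)
  ssw <- sum((x - rm)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb == 0 && msw == 0) return(NA_real_)
  if (msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Percentile bootstrap confidence interval for ICC(1,1)
#'
#' Resamples lesions (rows) with replacement, recomputes the ICC per
#' replicate, and returns the `alpha/2` and `1 - alpha/2` percentiles.
#' Replicates with an undefined ICC are dropped and counted; more than 50%
#' undefined is an error.
#'
#' @param table `n x k` measurement table
#' @param n_boot bootstrap replicates (>= 100; 1000 in the standard
#'   protocol)
#' @param alpha two-sided miss probability (0.05 for a 95% interval)
#' @param seed integer seed
#' @return named numeric `c(low, high)` with attribute `n_undefined`
#' @export
bootstrap_icc_ci <- function(table, n_boot = 1000, alpha = 0.05, seed = 1) {
  stopifnot(n_boot >= 100)
  x <- as.matrix(table)
  n <- nrow(x)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      icc_1_1(x[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  n_undef <- sum(is.na(reps))
  if (n_undef > n_boot / 2) {
    stop("more than half of the bootstrap replicates had undefined ICC")
  }
  reps <- reps[!is.na(reps)]
  ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  out <- c(low = ci[1], high = ci[2])
  attr(out, "n_undefined") <- n_undef
  out
}

#' Per-feature reliability table
#'
#' Pivots a cohort feature table (one row per lesion x rater) into one
#' `n x k` measurement table per feature and computes the ICC(1,1) point
#' estimate plus its bootstrap CI. Features that are constant over the whole
#' table get an undefined (`NA`) ICC and are flagged, not dropped; lesions
#' with missing raters are dropped whole and counted.
#'
#' @param features tibble from [extract_features()] (columns `lesion_id`,
#'   `rater_id` and the 89 feature columns, or any subset of them)
#' @param n_boot bootstrap replicates for the CIs
#' @param alpha CI miss probability
#' @param seed integer seed for the bootstrap
#' @return tibble of class `icc_tbl`: `feature`, `category`, `icc`,
#'   `ci_low`, `ci_high`, `n_lesions`, `k_raters`, `n_boot`, `flag`
#' @export
icc_table <- function(features, n_boot = 1000, alpha = 0.05, seed = 1) {
  reg <- feature_registry()
  feat_cols <- intersect(names(features), reg$feature)
  if (length(feat_cols) == 0) {
    feat_cols <- setdiff(names(features), c("lesion_id", "rater_id"))
  }
  stopifnot(length(feat_cols) >= 1)

  counts <- table(features$lesion_id)
  k <- max(counts)
  keep <- names(counts)[counts == k]
  n_dropped <- sum(counts != k)
  dat <- features[features$lesion_id %in% keep, , drop = FALSE]
  dat <- dat[order(dat$lesion_id, dat$rater_id), , drop = FALSE]
  n <- length(keep)
  stopifnot(n >= 2, k >= 2)

  seeds <- derive_seeds(seed, length(feat_cols))
  rows <- lapply(seq_along(feat_cols), function(fi) {
    f <- feat_cols[fi]
    m <- matrix(dat[[f]], nrow = n, ncol = k, byrow = TRUE)
    est <- icc_1_1(m)
    if (is.na(est)) {
      ci <- c(NA_real_, NA_real_)
      flag <- "undefined"
    } else {
      # a mostly-degenerate bootstrap (tiny n with zero within-lesion
      # spread) fails for this feature only, not for the whole table
      ci <- tryCatch(bootstrap_icc_ci(m, n_boot, alpha, seeds[fi]),
                     error = function(e) c(NA_real_, NA_real_))
      flag <- if (anyNA(ci)) "ci_undefined"
        else if (est < 0) "negative"
        else NA_character_
    }
    cat_f <- reg$category[match(f, reg$feature)]
    tibble::tibble(
      feature = f, category = cat_f %||% NA_character_,
      icc = est, ci_low = ci[1], ci_high = ci[2],
      n_lesions = n, k_raters = k, n_boot = n_boot, flag = flag
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_lesions_dropped") <- n_dropped
  class(out) <- c("icc_tbl", class(out))
  out
}

#' Per-category reliability summary
#'
#' Arithmetic mean of the defined ICCs per feature category, plus the
#' fraction of features exceeding the reproducibility thresholds (ICC > 0.8
#' and > 0.9 by default), per category and overall. Fractions are over
#' defined-ICC features; the count of undefined features is reported
#' alongside. Categories with no defined record are omitted with a warning.
#'
#' @param records an `icc_tbl` from [icc_table()]
#' @param thresholds ICC cut-offs for the exceedance fractions
#' @return tibble: `category` (including `"overall"`), `mean_icc`,
#'   `n_features`, `n_undefined`, one `frac_gt_<t>` column per threshold
#' @export
category_summary <- function(records, thresholds = c(0.8, 0.9)) {
  summarise_one <- function(d, label) {
    def <- d$icc[!is.na(d$icc)]
    if (length(def) == 0) return(NULL)
    row <- tibble::tibble(
      category = label,
      mean_icc = mean(def),
      n_features = nrow(d),
      n_undefined = sum(is.na(d$icc))
    )
    for (t in thresholds) {
      row[[sprintf("frac_gt_%g", t)]] <- mean(def > t)
    }
    row
  }
  cats <- unique(records$category)
  rows <- lapply(cats, function(cc) {
    r <- summarise_one(records[records$category %in% cc, ], cc)
    if (is.null(r)) warning("category '", cc, "' has no defined ICCs; omitted")
    r
  })
  dplyr::bind_rows(c(rows, list(summarise_one(records, "overall"))))
}

#' Correlate two ICC vectors over their common features
#'
#' Pearson correlation of paired ICC point estimates from two rater
#' populations (e.g. a small expert panel vs. a large sampled population)
#' over features defined in both.
#'
#' @param a,b `icc_tbl`s sharing feature names
#' @return object of class `icc_comparison`: list with `pearson_r`,
#'   `n_features`, and the paired `data` tibble
#' @export
compare_icc <- function(a, b) {
  merged <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), feature, icc_a = icc),
    dplyr::select(tibble::as_tibble(b), feature, icc_b = icc),
    by = "feature"
  )
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 3) stop("need at least 3 common defined features")
  structure(
    list(pearson_r = stats::cor(merged$icc_a, merged$icc_b),
         n_features = nrow(merged), data = merged),
    class = "icc_comparison"
  )
}

#' @export
print.icc_comparison <- function(x, ...) {
  cat(sprintf("ICC comparison over %d features: Pearson r = %.3f\n",
              x$n_features, x$pearson_r))
  invisible(x)
}

#' Tidy an ICC comparison
#'
#' @param x an `icc_comparison`
#' @param ... unused
#' @return the paired per-feature tibble
#' @export
tidy.icc_comparison <- function(x, ...) x$data

#' One-row summary of an ICC comparison
#'
#' @param x an `icc_comparison`
#' @param ... unused
#' @return tibble with `pearson_r` and `n_features`
#' @export
glance.icc_comparison <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n_features = x$n_features)
}

#' Generic tidiers
#'
#' Broom-style generics re-exported for the package's result objects.
#' @param x object to tidy or summarise
#' @param ... passed to methods
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Classify ICC values under two published conventions
#'
#' Reliability bands under the 0.75-rule (poor < 0.4, fair 0.4-0.59, good
#' 0.6-0.74, excellent >= 0.75) and the more conservative 0.9-rule (poor
#' < 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9), reported side
#' by side because the field has not settled on one cut-off.
#'
#' @param icc numeric vector of ICC estimates (`NA` allowed)
#' @return tibble with `icc`, `rule_075`, `rule_090`
#' @export
classify_stability <- function(icc) {
  rule_075 <- dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc >= 0.75 ~ "excellent",
    icc >= 0.6 ~ "good",
    icc >= 0.4 ~ "fair",
    TRUE ~ "poor"
  )
  rule_090 <- dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc > 0.9 ~ "excellent",
    icc >= 0.75 ~ "good",
    icc >= 0.5 ~ "moderate",
    TRUE ~ "poor"
  )
  tibble::tibble(icc = icc, rule_075 = rule_075, rule_090 = rule_090)
}
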