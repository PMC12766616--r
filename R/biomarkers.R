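#' Sign validity of raw segmental strain
#'
#' Peak systolic strain has a fixed physiological sign per direction:
#' longitudinal and circumferential shortening are negative, radial
#' thickening is positive. Values with the wrong sign (or exactly zero, or
#' non-finite) are non-sensical tracking output and fail validation.
#'
#' @param value Numeric vector of raw signed strain values (%).
#' @param direction `"longitudinal"`, `"circumferential"` or `"radial"`
#'   (scalar or vector recycled against `value`).
#' @return Logical vector: `TRUE` where the sign is physiologically valid.
#' @export
#' @examples
#' validate_sign(c(-18.1, 5.0), "longitudinal")
validate_sign <- function(value, direction) {
  if (!all(direction %in% .directions))
    abort("`direction` must be longitudinal, circumferential or radial")
  ok <- is.finite(value) & sign(value) == direction_sign(direction)
  ok & value != 0
}

#' Cohort-level IQR outlier fences
#'
#' Computes the fences `Q1 - k * IQR` and `Q3 + k * IQR` (default k = 3)
#' with quartiles by linear interpolation between order statistics. Values
#' strictly outside the fences are flagged as outliers; values exactly on a
#' fence are retained.
#'
#' @param values Numeric vector (at least 4 finite values).
#' @param k Fence multiplier (default 3).
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' cohort_outlier_fences(1:100)
cohort_outlier_fences <- function(values, k = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    abort("outlier fences need at least 4 finite values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

is_outlier <- function(values, fences) {
  is.finite(values) & (values < fences[["lower"]] | values > fences[["upper"]])
}

#' Global strain from valid segments
#'
#' Arithmetic mean of the absolute peak systolic strain over valid segments.
#'
#' @param values Numeric vector of segmental strain (raw signed or absolute).
#' @return Mean absolute strain (%), or `NA` with zero valid segments.
#' @export
global_strain <- function(values) {
  v <- abs(values[is.finite(values)])
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Strain coefficient of variation
#'
#' SD of absolute segmental strain divided by its mean, the contractile
#' heterogeneity biomarker. Requires more than `min_segments - 1` valid
#' segments (default rule: a CoV derived from 6 or fewer segments is
#' unreliable and reported missing). The SD uses the sample (n-1)
#' denominator by default; a population denominator is available since the
#' defining equation leaves the divisor ambiguous.
#'
#' @param values Numeric vector of segmental strain (raw signed or absolute).
#' @param min_segments Minimum number of valid segments (default 7).
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Dimensionless ratio >= 0, or `NA` when ineligible.
#' @export
#' @examples
#' strain_cov(c(rep(15, 8), rep(25, 8)))
strain_cov <- function(values, min_segments = 7,
                       denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  v <- abs(values[is.finite(values)])
  n <- length(v)
  if (n < min_segments || n < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  s <- sd(v)
  if (denominator == "population") s <- s * sqrt((n - 1) / n)
  s / m
}

#' Standardize a biomarker column to z-scores
#'
#' Centers and scales by the sample mean and SD of the non-missing entries;
#' missing values propagate.
#'
#' @param values Numeric vector with at least 2 non-missing values and
#'   non-zero spread.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) abort("standardize needs >= 2 non-missing values")
  s <- sd(v)
  if (s == 0) abort("standardize: zero spread")
  (values - mean(v)) / s
}

#' Impact of missing segments on strain CoV
#'
#' Evidence surface behind the minimum-segment rule: starting from a
#' complete 16-segment set, recomputes the CoV over size-k subsets for each
#' k and reports the mean bias and spread relative to the full-set CoV.
#' Subsets are enumerated exhaustively when there are at most `exhaustive_max`
#' of them, otherwise sampled.
#'
#' @param values Complete numeric vector of 16 segmental strain values.
#' @param k_range Integer vector of subset sizes (each in 2..16).
#' @param n_draws Number of random subsets per k when not exhaustive.
#' @param exhaustive_max Enumerate all subsets when `choose(16, k)` is at
#'   most this (default 13000, i.e. always exhaustive for k <= 4 or >= 12 and
#'   for every k when affordable).
#' @param denominator Passed to [strain_cov()].
#' @return Tibble: k, n_subsets, exhaustive, mean_cov, bias, sd_cov, full_cov.
#' @export
assess_missing_segment_impact <- function(values, k_range = 2:16,
                                          n_draws = 500,
                                          exhaustive_max = 13000,
                                          denominator = "sample") {
  values <- abs(values)
  if (length(values) != 16 || any(!is.finite(values)))
    abort("a complete 16-segment set is required")
  if (any(k_range < 2 | k_range > 16))
    abort("subset sizes must be in 2..16 (CoV undefined below 2)")
  full_cov <- strain_cov(values, min_segments = 2,
                         denominator = denominator)
  bind_rows(lapply(sort(unique(k_range)), function(k) {
    n_all <- choose(16, k)
    exhaustive <- n_all <= exhaustive_max
    covs <- if (exhaustive) {
      apply(combn(16, k), 2, function(ix)
        strain_cov(values[ix], min_segments = 2, denominator = denominator))
    } else {
      replicate(n_draws, strain_cov(values[sample.int(16, k)],
                                    min_segments = 2,
                                    denominator = denominator))
    }
    tibble(k = k, n_subsets = length(covs), exhaustive = exhaustive,
           mean_cov = mean(covs), bias = mean(covs) - full_cov,
           sd_cov = if (length(covs) > 1) sd(covs) else 0,
           full_cov = full_cov)
  }))
}
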