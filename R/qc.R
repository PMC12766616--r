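#' Cohort-level strain quality control cascade
#'
#' Executes the QC pipeline on a long-format strain table, in order:
#' 1. participants with no strain measurements are recorded as excluded
#'    (they have no rows; supply `roster` to count them);
#' 2. wrong-sign values are invalidated ([validate_sign()]);
#' 3. cohort fences (`Q1 - k IQR`, `Q3 + k IQR`) are computed per direction
#'    on the absolute values of the sign-valid cells and values strictly
#'    outside are invalidated;
#' 4. per participant and direction, biomarkers are computed from the valid
#'    cells; a CoV derived from 6 or fewer valid segments is set missing
#'    (`too_few_segments`), while global strain only requires one valid
#'    segment;
#' 5. cohort fences are additionally applied to the derived biomarkers
#'    (global strain and CoV per direction) and outlying biomarker values
#'    are set missing.
#'
#' Cells are never deleted: `valid` and `flag` are recomputed from the raw
#' values, so applying QC to its own output reproduces it exactly.
#'
#' @param strain Long tibble: participant_id, direction, segment, value.
#' @param roster Optional vector of all participant ids in the cohort (used
#'   to count participants with no strain at all).
#' @param fence_multiplier IQR multiplier for the outlier fences (default 3).
#' @param min_segments Minimum valid segments for a CoV (default 7).
#' @param denominator SD denominator for the CoV, `"sample"` or
#'   `"population"`.
#' @param fence_scope Which metric families get fences: `"both"` (default),
#'   `"segmental"` or `"biomarker"`.
#' @return An object of class `strain_qc`: list with `strain` (input plus
#'   `valid`, `flag`), `biomarkers` (one row per participant), `report`
#'   (per-step exclusion counts), `inclusion_fraction` (participants with a
#'   complete set of 6 biomarkers over the roster) and the options used.
#' @export
apply_qc <- function(strain, roster = NULL, fence_multiplier = 3,
                     min_segments = 7,
                     denominator = c("sample", "population"),
                     fence_scope = c("both", "segmental", "biomarker")) {
  denominator <- match.arg(denominator)
  fence_scope <- match.arg(fence_scope)
  if (inherits(strain, "strain_qc")) strain <- strain$strain
  if (nrow(strain) == 0) abort("empty cohort: no strain rows")
  strain <- strain %>% select("participant_id", "direction", "segment",
                              "value")

  if (is.null(roster)) roster <- unique(strain$participant_id)
  n_no_strain <- sum(!roster %in% strain$participant_id)

  strain$valid <- validate_sign(strain$value, strain$direction)
  strain$flag <- ifelse(strain$valid, NA_character_, "bad_sign")
  n_bad_sign <- sum(!strain$valid)

  n_seg_outlier <- 0L
  if (fence_scope %in% c("both", "segmental")) {
    for (d in .directions) {
      ix <- strain$direction == d & strain$valid
      if (sum(ix) >= 4) {
        fences <- cohort_outlier_fences(abs(strain$value[ix]),
                                        k = fence_multiplier)
        out <- ix & is_outlier(abs(strain$value), fences)
        strain$valid[out] <- FALSE
        strain$flag[out] <- "outlier"
        n_seg_outlier <- n_seg_outlier + sum(out)
      }
    }
  }

  bio <- compute_biomarkers(strain, min_segments = min_segments,
                            denominator = denominator)
  n_too_few <- sum(bio$flag_too_few_ls, bio$flag_too_few_cs,
                   bio$flag_too_few_rs)

  n_bio_outlier <- 0L
  if (fence_scope %in% c("both", "biomarker")) {
    for (metric in c("gls", "gcs", "grs", "cov_ls", "cov_cs", "cov_rs")) {
      v <- bio[[metric]]
      ok <- is.finite(v)
      if (sum(ok) >= 4) {
        fences <- cohort_outlier_fences(v[ok], k = fence_multiplier)
        out <- ok & is_outlier(v, fences)
        bio[[metric]][out] <- NA_real_
        bio[[paste0("flag_outlier_", metric)]] <- out
        n_bio_outlier <- n_bio_outlier + sum(out)
      }
    }
  }

  complete <- stats::complete.cases(
    bio[, c("gls", "gcs", "grs", "cov_ls", "cov_cs", "cov_rs")])
  inclusion <- sum(complete) / length(roster)

  report <- tibble(
    step = c("no_strain", "bad_sign", "segmental_outlier",
             "too_few_segments", "biomarker_outlier"),
    unit = c("participants", "cells", "cells", "participant-directions",
             "participant-metrics"),
    n_excluded = c(n_no_strain, n_bad_sign, n_seg_outlier, n_too_few,
                   n_bio_outlier))

  structure(list(strain = strain, biomarkers = bio, report = report,
                 inclusion_fraction = inclusion,
                 options = list(fence_multiplier = fence_multiplier,
                                min_segments = min_segments,
                                denominator = denominator,
                                fence_scope = fence_scope)),
            class = "strain_qc")
}

#' @export
print.strain_qc <- function(x, ...) {
  cat("<strain_qc> inclusion fraction ",
      sprintf("%.3f", x$inclusion_fraction), "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Per-participant strain biomarkers from a (QC'd) strain table
#'
#' Computes global strain (mean absolute valid segmental strain) and strain
#' CoV (SD/mean of absolute valid segmental strain) per participant and
#' direction, honouring the minimum-segment rule for the CoV.
#'
#' @inheritParams apply_qc
#' @param strain Long strain tibble; an optional logical `valid` column
#'   restricts which cells count (non-finite values never count).
#' @return Tibble with one row per participant: gls/gcs/grs, cov_ls/cs/rs,
#'   n_valid per direction and too-few-segments flags.
#' @export
compute_biomarkers <- function(strain, min_segments = 7,
                               denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (inherits(strain, "strain_qc")) strain <- strain$strain
  if (!"valid" %in% names(strain)) strain$valid <- is.finite(strain$value)
  suffix <- c(longitudinal = "ls", circumferential = "cs", radial = "rs")
  per_dir <- strain %>%
    filter(.data$valid) %>%
    group_by(.data$participant_id, .data$direction) %>%
    summarise(n_valid = dplyr::n(),
              global = global_strain(.data$value),
              cov = strain_cov(.data$value, min_segments = min_segments,
                               denominator = denominator),
              .groups = "drop") %>%
    mutate(too_few = .data$n_valid < min_segments,
           sfx = suffix[.data$direction])

  wide <- per_dir %>%
    select("participant_id", "sfx", "global", "cov", "n_valid", "too_few") %>%
    tidyr::pivot_wider(names_from = "sfx",
                       values_from = c("global", "cov", "n_valid", "too_few"),
                       names_sep = "_")
  # ensure all 6 biomarker columns exist even for partial cohorts
  for (s in c("ls", "cs", "rs")) {
    for (p in c("global_", "cov_", "n_valid_", "too_few_")) {
      nm <- paste0(p, s)
      if (!nm %in% names(wide))
        wide[[nm]] <- if (p == "n_valid_") 0L
                      else if (p == "too_few_") TRUE else NA_real_
    }
  }
  wide %>%
    mutate(n_valid_ls = tidyr::replace_na(.data$n_valid_ls, 0L),
           n_valid_cs = tidyr::replace_na(.data$n_valid_cs, 0L),
           n_valid_rs = tidyr::replace_na(.data$n_valid_rs, 0L),
           flag_too_few_ls = tidyr::replace_na(.data$too_few_ls, TRUE),
           flag_too_few_cs = tidyr::replace_na(.data$too_few_cs, TRUE),
           flag_too_few_rs = tidyr::replace_na(.data$too_few_rs, TRUE)) %>%
    select(participant_id = "participant_id",
           gls = "global_ls", gcs = "global_cs", grs = "global_rs",
           cov_ls = "cov_ls", cov_cs = "cov_cs", cov_rs = "cov_rs",
           n_valid_ls = "n_valid_ls", n_valid_cs = "n_valid_cs",
           n_valid_rs = "n_valid_rs",
           flag_too_few_ls = "flag_too_few_ls",
           flag_too_few_cs = "flag_too_few_cs",
           flag_too_few_rs = "flag_too_few_rs") %>%
    arrange(.data$participant_id)
}
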