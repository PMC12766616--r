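drop_focal <- function(spec) {
  spec$covariates <- setdiff(spec$covariates,
                             paste0(spec$biomarker, "_z"))
  spec
}

#' Full model-comparison battery for one focal biomarker
#'
#' Fits the specified model and its reduction without the focal biomarker
#' on identical complete-case rows, then computes the comparison metrics:
#' Uno C-index difference (with optional bootstrap p), continuous NRI(>0)
#' at the horizon, Brier score difference at the horizon, and the
#' likelihood-ratio test with the AIC difference.
#'
#' @param data Analysis tibble from [endpoint_data()].
#' @param spec A [cox_model_spec()].
#' @param horizon Risk/NRI/Brier horizon in years (default 5).
#' @param B Bootstrap resamples for the C-index comparison and the NRI
#'   interval (0 skips both bootstraps).
#' @param seed Seed for the bootstraps.
#' @return List: `fit_full`, `fit_reduced` and a one-row `metrics` tibble.
#' @export
model_comparison <- function(data, spec, horizon = 5, B = 0, seed = 1) {
  df <- data[stats::complete.cases(
    data[, c("time", "event", spec$covariates)]), ]
  fit_full <- fit_cox(df, spec)
  fit_reduced <- fit_cox(df, drop_focal(spec))
  cc <- compare_c_index(fit_full, fit_reduced, B = B, seed = seed)
  risk_new <- predicted_risk(fit_full, horizon)
  risk_old <- predicted_risk(fit_reduced, horizon)
  nri <- continuous_nri(risk_old, risk_new, df$time, df$event, horizon,
                        B = B, seed = seed)
  brier_full <- brier_score(risk_new, df$time, df$event, horizon)
  brier_reduced <- brier_score(risk_old, df$time, df$event, horizon)
  lrt <- lrt_and_aic(fit_full, fit_reduced)
  focal_row <- tidy(fit_full) %>%
    filter(.data$term == paste0(spec$biomarker, "_z"))
  metrics <- tibble(
    endpoint = spec$endpoint, biomarker = spec$biomarker, tier = spec$tier,
    n = fit_full$fit$n, n_events = fit_full$fit$nevent,
    hr = focal_row$hr, conf.low = focal_row$conf.low,
    conf.high = focal_row$conf.high, p.value = focal_row$p.value,
    p.adjusted = focal_row$p.adjusted,
    c_index = cc$c_full, delta_c = cc$delta_c,
    p_delta_c = cc$p_unpaired_t,
    nri_pct = nri$nri_pct, nri_low = nri$conf.low, nri_high = nri$conf.high,
    brier = brier_full, delta_brier = brier_full - brier_reduced,
    delta_aic = lrt$delta_aic, lrt_chisq = lrt$chisq,
    p_lrt = lrt$p.value)
  list(fit_full = fit_full, fit_reduced = fit_reduced, metrics = metrics)
}

#' Run the full strain-heterogeneity analysis pipeline
#'
#' Executes the stages in order: simulate (or ingest) the cohort; QC the
#' strain table; compute biomarkers; derive healthy reference ranges and
#' regional-abnormality flags; descriptive group comparisons and biomarker
#' correlations; nested Cox models per endpoint and focal biomarker with the
#' model-comparison battery; restricted-cubic-spline non-linearity tests;
#' and LVEF-stratified tertile Kaplan-Meier panels. Everything is
#' deterministic given the configuration and seed.
#'
#' @param config A [sim_config()] (ignored when `input` is given).
#' @param input Optional [read_cohort_tables()] result to analyze instead of
#'   simulating.
#' @param endpoints Endpoints to model (default all five).
#' @param biomarkers Focal strain biomarkers to model (default all six).
#' @param tiers Model tiers to fit (default 1:3; comparisons use the
#'   highest requested tier).
#' @param horizon Risk horizon in years for NRI and Brier (default 5).
#' @param boot_B Bootstrap resamples for C-index/NRI inference (default 0 =
#'   point estimates only).
#' @param knot_rule Knot placement rule for the spline tests.
#' @param tertile_scope Tertile scope for the KM panels.
#' @param fence_multiplier,min_segments,denominator QC options, passed to
#'   [apply_qc()].
#' @param bonferroni_m Multiplicity factor (default 15).
#' @param seed Seed for all randomized stages (default: the config's seed).
#' @return Object of class `strain_report`: a list of result tibbles plus
#'   provenance (config, seed, package version).
#' @export
run_pipeline <- function(config = sim_config(),
                         input = NULL,
                         endpoints = sim_endpoints(),
                         biomarkers = strain_markers,
                         tiers = 1:3,
                         horizon = 5,
                         boot_B = 0,
                         knot_rule = "percentile",
                         tertile_scope = "stratum",
                         fence_multiplier = 3,
                         min_segments = 7,
                         denominator = "sample",
                         bonferroni_m = 15,
                         seed = NULL) {
  stage <- "simulate"
  result <- try({
    if (is.null(input)) {
      cohort <- simulate_cohort(config)
      seed <- seed %||% config$seed
    } else {
      cohort <- input
      seed <- seed %||% 1L
    }
    roster <- cohort$participants$participant_id

    stage <- "qc"
    qc <- apply_qc(cohort$strain, roster = roster,
                   fence_multiplier = fence_multiplier,
                   min_segments = min_segments,
                   denominator = denominator)
    bio <- qc$biomarkers

    stage <- "reference_ranges"
    joined <- cohort$participants %>%
      dplyr::inner_join(bio, by = "participant_id")
    healthy <- select_healthy_reference(joined)
    healthy_strain <- qc$strain %>%
      filter(.data$participant_id %in% healthy$participant_id)
    ranges <- reference_range_table(healthy, healthy_strain)
    regional <- regional_abnormality_flags(qc$strain, bio, ranges)

    stage <- "descriptives"
    descriptives <- descriptive_table(joined)
    correlations <- biomarker_correlations(joined)

    stage <- "models"
    top_tier <- max(tiers)
    model_rows <- list(); comparison_rows <- list()
    set.seed(seed)
    for (ep in endpoints) {
      dat <- endpoint_data(cohort$participants, bio, cohort$outcomes, ep,
                           regional = regional)
      for (bm in biomarkers) {
        for (tier in tiers) {
          spec <- cox_model_spec(ep, bm, tier = tier)
          fit <- try(fit_cox(dat, spec, bonferroni_m = bonferroni_m),
                     silent = TRUE)
          if (inherits(fit, "try-error")) next
          model_rows[[length(model_rows) + 1]] <-
            tidy(fit) %>%
            mutate(endpoint = ep, biomarker = bm, tier = tier,
                   n = fit$fit$n, n_events = fit$fit$nevent)
        }
        spec3 <- cox_model_spec(ep, bm, tier = top_tier)
        cmp <- try(model_comparison(dat, spec3, horizon = horizon,
                                    B = boot_B, seed = seed),
                   silent = TRUE)
        if (!inherits(cmp, "try-error"))
          comparison_rows[[length(comparison_rows) + 1]] <- cmp$metrics
      }
    }

    stage <- "nonlinearity"
    nl_rows <- list()
    for (ep in endpoints) {
      dat <- endpoint_data(cohort$participants, bio, cohort$outcomes, ep,
                           regional = regional)
      for (bm in intersect(biomarkers, c("cov_ls", "cov_cs", "cov_rs"))) {
        spec <- cox_model_spec(ep, bm, tier = max(tiers))
        nl <- try(test_nonlinearity(dat, spec, knot_rule = knot_rule),
                  silent = TRUE)
        if (!inherits(nl, "try-error"))
          nl_rows[[length(nl_rows) + 1]] <- nl %>%
            select(-"knots") %>%
            mutate(endpoint = ep, biomarker = bm)
      }
    }

    stage <- "km"
    km <- stratified_tertile_km(joined, cohort$outcomes,
                                biomarkers = biomarkers,
                                endpoints = endpoints,
                                tertile_scope = tertile_scope)

    structure(list(
      qc_report = qc$report,
      inclusion_fraction = qc$inclusion_fraction,
      biomarkers = bio,
      reference_ranges = ranges,
      regional_flags = regional,
      descriptives = descriptives,
      correlations = correlations,
      models = bind_rows(model_rows),
      comparisons = bind_rows(comparison_rows),
      nonlinearity = bind_rows(nl_rows),
      km_curves = km$curves,
      km_trend = km$trend,
      provenance = list(seed = seed,
                        config_hash = rlang::hash(unclass(config)),
                        version = as.character(
                          utils::packageVersion("strainhet")))),
      class = "strain_report")
  }, silent = TRUE)
  if (inherits(result, "try-error"))
    abort(paste0("pipeline failed at stage `", stage, "`: ",
                 attr(result, "condition")$message))
  result
}

#' @export
print.strain_report <- function(x, ...) {
  cat("<strain_report>\n")
  cat("  inclusion fraction:", sprintf("%.3f", x$inclusion_fraction), "\n")
  cat("  models:", nrow(x$models), "terms |",
      nrow(x$comparisons), "comparisons |",
      nrow(x$nonlinearity), "nonlinearity tests |",
      nrow(x$km_trend), "KM panels\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Persists every result table as CSV plus a JSON run summary carrying the
#' seed, configuration hash and headline numbers.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("qc_report", "biomarkers", "reference_ranges",
              "regional_flags", "descriptives", "correlations", "models",
              "comparisons", "nonlinearity", "km_curves", "km_trend")
  for (tb in tables)
    if (!is.null(report[[tb]]) && nrow(report[[tb]]) > 0)
      readr::write_csv(report[[tb]], file.path(dir, paste0(tb, ".csv")))
  summary <- c(report$provenance,
               list(inclusion_fraction = report$inclusion_fraction,
                    n_models = nrow(report$models),
                    n_comparisons = nrow(report$comparisons)))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Descriptive biomarker table stratified by risk groups
#'
#' Median (Q1, Q3) of each strain biomarker within standard dichotomies
#' (age > 65, sex, smoking, obesity, hypertension, diabetes) with the
#' Mann-Whitney p-value for the group difference.
#'
#' @param data Participant tibble joined with biomarkers.
#' @param biomarkers Biomarker columns (default the six strain markers).
#' @return Tibble: group, level, biomarker, n, median, q1, q3, p.
#' @export
descriptive_table <- function(data, biomarkers = strain_markers) {
  groups <- list(age_over_65 = data$age > 65,
                 male = data$male,
                 smoker = data$smoker,
                 obesity = data$obesity,
                 hypertension = data$hypertension,
                 diabetes = data$diabetes)
  rows <- list()
  for (g in names(groups)) {
    gv <- groups[[g]]
    for (bm in biomarkers) {
      v <- data[[bm]]
      p <- tryCatch(group_compare(v, gv)$p, error = function(e) NA_real_)
      for (lv in c(TRUE, FALSE)) {
        vv <- v[gv == lv & is.finite(v)]
        rows[[length(rows) + 1]] <-
          tibble(group = g, level = lv, biomarker = bm, n = length(vv),
                 median = median(vv), q1 = quantile(vv, 0.25, names = FALSE),
                 q3 = quantile(vv, 0.75, names = FALSE), p = p)
      }
    }
  }
  bind_rows(rows)
}

#' Spearman correlations among strain biomarkers and CMR volumetrics
#'
#' @param data Participant tibble joined with biomarkers.
#' @param columns Columns to correlate.
#' @return Tibble: var1, var2, rho.
#' @export
biomarker_correlations <- function(data,
                                   columns = c(strain_markers, "lvef",
                                               "lvmi", "lvedvi")) {
  columns <- intersect(columns, names(data))
  pairs <- combn(columns, 2)
  tibble(var1 = pairs[1, ], var2 = pairs[2, ],
         rho = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                               ~ correlate(data[[.x]], data[[.y]])))
}
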