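strain_markers <- c("cov_ls", "cov_cs", "cov_rs", "gls", "gcs", "grs")

reciprocal_marker <- function(biomarker) {
  map <- c(cov_ls = "gls", cov_cs = "gcs", cov_rs = "grs",
           gls = "cov_ls", gcs = "cov_cs", grs = "cov_rs")
  map[[biomarker]]
}

marker_direction_suffix <- function(biomarker) {
  sub("^(cov_|g)", "", biomarker)
}

#' Specify a nested Cox model
#'
#' Builds the model specification for the stepwise modeling scheme:
#' tier 1 is the z-scored focal strain biomarker alone; tier 2 adds the
#' cardiometabolic risk factors (age, sex, ethnicity, smoking, BMI,
#' dyslipidemia, hypertension, diabetes); tier 3 adds the CMR biomarkers
#' LVMi, LVEDVi, LVEF and the reciprocal strain marker (a CoV is paired
#' with its global counterpart and vice versa). Optionally the
#' regional-abnormality flag of the focal direction is added as an extra
#' adjuster.
#'
#' @param endpoint One of `composite_cv`, `mi`, `hf`, `arrhythmia`, `death`.
#' @param biomarker Focal marker: one of `cov_ls`, `cov_cs`, `cov_rs`,
#'   `gls`, `gcs`, `grs`.
#' @param tier Model tier 1, 2 or 3.
#' @param adjust_regional Add the regional-abnormality flag for the focal
#'   direction (sensitivity analysis).
#' @return Object of class `cox_model_spec`.
#' @export
cox_model_spec <- function(endpoint, biomarker, tier = 3,
                           adjust_regional = FALSE) {
  endpoint <- match.arg(endpoint, sim_endpoints())
  biomarker <- match.arg(biomarker, strain_markers)
  if (!tier %in% 1:3) abort("`tier` must be 1, 2 or 3")
  covars <- paste0(biomarker, "_z")
  if (tier >= 2)
    covars <- c(covars, "age", "male", "white", "smoker", "bmi",
                "dyslipidemia", "hypertension", "diabetes")
  if (tier >= 3)
    covars <- c(covars, "lvmi", "lvedvi", "lvef",
                paste0(reciprocal_marker(biomarker), "_z"))
  if (adjust_regional)
    covars <- c(covars,
                paste0("regional_", marker_direction_suffix(biomarker)))
  structure(list(endpoint = endpoint, biomarker = biomarker, tier = tier,
                 adjust_regional = adjust_regional, covariates = covars),
            class = "cox_model_spec")
}

#' @export
print.cox_model_spec <- function(x, ...) {
  cat("<cox_model_spec> ", x$endpoint, " ~ ", x$biomarker, " (tier ",
      x$tier, if (x$adjust_regional) " + regional flag", ")\n", sep = "")
  invisible(x)
}

#' Assemble the per-endpoint analysis table
#'
#' Joins the participant covariates, the QC'd biomarkers (z-scoring the six
#' strain markers over the analyzed sample), optional regional-abnormality
#' flags and the time/event pair for one endpoint, excluding participants
#' with that endpoint's condition prevalent at baseline (or any prevalent
#' CVD with `exclude = "any_cvd"`).
#'
#' @param participants Covariate tibble.
#' @param biomarkers Biomarker tibble ([compute_biomarkers()]).
#' @param outcomes Long outcome tibble (participant_id, endpoint, time,
#'   event, prevalent).
#' @param endpoint Endpoint name.
#' @param regional Optional regional-flag tibble
#'   ([regional_abnormality_flags()]).
#' @param exclude `"endpoint"` (default) excludes participants with the
#'   modeled endpoint prevalent; `"any_cvd"` excludes any prevalent CVD.
#' @return Analysis tibble with `time`, `event` and z-scored strain columns.
#' @export
endpoint_data <- function(participants, biomarkers, outcomes, endpoint,
                          regional = NULL,
                          exclude = c("endpoint", "any_cvd")) {
  exclude <- match.arg(exclude)
  oc <- outcomes %>% filter(.data$endpoint == .env$endpoint)
  if (exclude == "any_cvd") {
    any_cvd <- outcomes %>%
      group_by(.data$participant_id) %>%
      summarise(prev = any(.data$prevalent), .groups = "drop")
    oc <- oc %>%
      left_join(any_cvd, by = "participant_id") %>%
      filter(!.data$prev) %>%
      select(-"prev")
  } else {
    oc <- oc %>% filter(!.data$prevalent)
  }
  df <- participants %>%
    dplyr::inner_join(biomarkers, by = "participant_id") %>%
    dplyr::inner_join(oc %>% select("participant_id", "time", "event"),
                      by = "participant_id")
  if (!is.null(regional))
    df <- df %>% left_join(regional, by = "participant_id")
  for (m in strain_markers)
    if (m %in% names(df)) df[[paste0(m, "_z")]] <- standardize(df[[m]])
  df
}

#' Fit a nested Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default,
#' convergence at relative log-likelihood change below 1e-9 within 100
#' iterations) on the complete cases of the specified covariates, and
#' attaches per-term hazard ratios, Wald confidence intervals and
#' Bonferroni-adjusted p-values for the focal biomarker.
#'
#' @param data Analysis tibble from [endpoint_data()] (must contain `time`,
#'   `event` and the spec's covariates).
#' @param spec A [cox_model_spec()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param bonferroni_m Multiplicity factor for the adjusted p-values
#'   (default 15: 3 principal CoV-vs-global comparisons across 5 endpoints).
#' @return Object of class `strain_cox` wrapping the `survival::coxph` fit,
#'   with [tidy()] and [glance()] methods.
#' @export
fit_cox <- function(data, spec, ties = c("efron", "breslow"),
                    bonferroni_m = 15) {
  ties <- match.arg(ties)
  stopifnot(inherits(spec, "cox_model_spec"))
  missing_cols <- setdiff(c("time", "event", spec$covariates), names(data))
  if (length(missing_cols))
    abort(paste0("missing model columns: ",
                 paste(missing_cols, collapse = ", ")))
  df <- data[stats::complete.cases(data[, c("time", "event",
                                            spec$covariates)]), ]
  if (sum(df$event) == 0) abort("zero events: model not estimable")
  f <- as.formula(paste("survival::Surv(time, event) ~",
                        paste(spec$covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = df, ties = ties, model = TRUE,
                         x = TRUE, y = TRUE,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (any(is.na(coef(fit))))
    warn("singular design: some coefficients not estimable")
  structure(list(fit = fit, spec = spec, data = df,
                 bonferroni_m = bonferroni_m, ties = ties),
            class = "strain_cox")
}

#' @export
print.strain_cox <- function(x, ...) {
  print(x$spec)
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `strain_cox` object.
#' @param ... Unused.
#' @method tidy strain_cox
#' @export
tidy.strain_cox <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s),
         estimate = s[, "coef"],
         hr = exp(s[, "coef"]),
         std.error = s[, "se(coef)"],
         conf.low = exp(s[, "coef"] - qnorm(0.975) * s[, "se(coef)"]),
         conf.high = exp(s[, "coef"] + qnorm(0.975) * s[, "se(coef)"]),
         p.value = s[, "Pr(>|z|)"],
         p.adjusted = bonferroni_adjust(s[, "Pr(>|z|)"], x$bonferroni_m))
}

#' @rdname fit_cox
#' @method glance strain_cox
#' @export
glance.strain_cox <- function(x, ...) {
  fit <- x$fit
  k <- sum(!is.na(coef(fit)))
  tibble(n = fit$n, n_events = fit$nevent,
         loglik = as.numeric(fit$loglik[2]),
         loglik_null = as.numeric(fit$loglik[1]),
         aic = -2 * as.numeric(fit$loglik[2]) + 2 * k,
         n_terms = k,
         concordance = as.numeric(fit$concordance["concordance"]))
}

focal_term <- function(x) paste0(x$spec$biomarker, "_z")

#' Proportional-hazards and collinearity diagnostics
#'
#' Scaled Schoenfeld residual tests per covariate (correlation with time)
#' and variance inflation factors from auxiliary linear regressions on the
#' design matrix; the model passes when every VIF is below `vif_limit`.
#'
#' @param x A [fit_cox()] result.
#' @param vif_limit VIF pass threshold (default 5).
#' @return Tibble: term, schoenfeld_p, vif, vif_pass.
#' @export
check_diagnostics <- function(x, vif_limit = 5) {
  stopifnot(inherits(x, "strain_cox"))
  zp <- try(survival::cox.zph(x$fit), silent = TRUE)
  terms <- names(coef(x$fit))
  sp <- rep(NA_real_, length(terms))
  if (!inherits(zp, "try-error")) {
    tab <- zp$table
    # map each coefficient column to its originating model term
    asn <- x$fit$assign
    for (t in seq_along(asn)) {
      row <- match(names(asn)[t], rownames(tab))
      if (!is.na(row)) sp[asn[[t]]] <- tab[row, "p"]
    }
  }
  X <- x$fit$x
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (sd(X[, j]) == 0) return(Inf)
    r2 <- suppressWarnings(
      summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = terms, schoenfeld_p = as.numeric(sp), vif = vif,
         vif_pass = vif < vif_limit)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)`; the significance threshold for the principal biomarker
#' comparisons is `0.05 / m` (0.0033 at the default m = 15).
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of comparisons (default 15).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m = 15) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    abort("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' HFpEF-risk membership
#'
#' Preserved LVEF (>= 50%) plus at least 3 of: age > 65 years, obesity,
#' hypertension, diabetes, CKD, AF.
#'
#' @param data Covariate tibble with `lvef`, `age`, `obesity`,
#'   `hypertension`, `diabetes`, `ckd`, `af`.
#' @return Logical vector.
#' @export
hfpef_risk <- function(data) {
  criteria <- (data$age > 65) + data$obesity + data$hypertension +
    data$diabetes + data$ckd + data$af
  data$lvef >= 50 & criteria >= 3
}

#' Subgroup refits of a Cox model
#'
#' Refits the supplied model specification within predefined subgroups:
#' age > 65 / <= 65, male / female, prevalent CKD, prevalent MI, prevalent
#' AF and the HFpEF-risk group ([hfpef_risk()]). Subgroups where the model
#' is not estimable (e.g. zero events) are reported as not-estimable rows
#' rather than errors.
#'
#' @param data Analysis tibble from [endpoint_data()].
#' @param spec A [cox_model_spec()].
#' @param subgroups Named list of predicate functions of `data`; defaults to
#'   the standard set.
#' @return Tibble: subgroup, n, n_events, estimate, hr, conf.low, conf.high,
#'   p.value for the focal biomarker.
#' @export
subgroup_analysis <- function(data, spec, subgroups = NULL) {
  if (is.null(subgroups))
    subgroups <- list(
      age_over_65 = function(d) d$age > 65,
      age_65_or_less = function(d) d$age <= 65,
      male = function(d) d$male,
      female = function(d) !d$male,
      prevalent_ckd = function(d) d$ckd,
      prevalent_mi = function(d) d$prev_mi,
      prevalent_af = function(d) d$af,
      hfpef_risk = function(d) hfpef_risk(d))
  focal <- paste0(spec$biomarker, "_z")
  bind_rows(lapply(names(subgroups), function(nm) {
    sub <- data[subgroups[[nm]](data), , drop = FALSE]
    base <- tibble(subgroup = nm, n = nrow(sub),
                   n_events = sum(sub$event, na.rm = TRUE),
                   estimate = NA_real_, hr = NA_real_,
                   conf.low = NA_real_, conf.high = NA_real_,
                   p.value = NA_real_)
    if (nrow(sub) < 10 || sum(sub$event, na.rm = TRUE) == 0) return(base)
    fit <- try(fit_cox(sub, spec), silent = TRUE)
    if (inherits(fit, "try-error")) return(base)
    row <- tidy(fit) %>% filter(.data$term == focal)
    if (nrow(row) == 0 || is.na(row$estimate)) return(base)
    base$estimate <- row$estimate; base$hr <- row$hr
    base$conf.low <- row$conf.low; base$conf.high <- row$conf.high
    base$p.value <- row$p.value
    base
  }))
}
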