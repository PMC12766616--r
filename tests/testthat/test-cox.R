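test_that("Cox fit matches brute-force partial-likelihood maximization", {
  # n = 8, one binary covariate, no ties, no censoring
  set.seed(17)
  df <- tibble::tibble(time = c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2, 7.8, 9.4),
                       event = TRUE,
                       cov_cs_z = c(1, 0, 1, 1, 0, 0, 1, 0))
  spec <- cox_model_spec("hf", "cov_cs", tier = 1)
  fit <- fit_cox(df, spec, ties = "breslow")
  pl <- function(beta) {
    ll <- 0
    ord <- order(df$time)
    x <- df$cov_cs_z[ord]
    for (i in seq_along(x)) {
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[i:length(x)])))
    }
    ll
  }
  beta_hat <- stats::optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(coef(fit$fit)), beta_hat, tolerance = 1e-4)
})

test_that("rescaling a covariate rescales beta but not the HR per SD", {
  set.seed(18)
  n <- 400
  df <- tibble::tibble(
    time = rexp(n, 0.1), event = runif(n) < 0.7,
    cov_cs_z = rnorm(n))
  spec <- cox_model_spec("hf", "cov_cs", tier = 1)
  f1 <- fit_cox(df, spec)
  df2 <- df; df2$cov_cs_z <- df$cov_cs_z * 4
  f2 <- fit_cox(df2, spec)
  expect_equal(unname(coef(f2$fit)), unname(coef(f1$fit)) / 4,
               tolerance = 1e-8)
  # once standardized, the HR per SD is invariant to the raw scale
  df3 <- df; df3$cov_cs_z <- standardize(df$cov_cs_z * 4)
  df1s <- df; df1s$cov_cs_z <- standardize(df$cov_cs_z)
  f3 <- fit_cox(df3, spec)
  f1s <- fit_cox(df1s, spec)
  expect_equal(tidy(f3)$hr, tidy(f1s)$hr, tolerance = 1e-8)
})

test_that("tier covariate sets are nested and the focal term unique", {
  s1 <- cox_model_spec("hf", "cov_cs", tier = 1)
  s2 <- cox_model_spec("hf", "cov_cs", tier = 2)
  s3 <- cox_model_spec("hf", "cov_cs", tier = 3)
  expect_true(all(s1$covariates %in% s2$covariates))
  expect_true(all(s2$covariates %in% s3$covariates))
  expect_equal(sum(s3$covariates == "cov_cs_z"), 1)
  expect_true("gcs_z" %in% s3$covariates)   # reciprocal marker
  expect_true("gls_z" %in% cox_model_spec("hf", "cov_ls", 3)$covariates)
  expect_true("cov_rs_z" %in% cox_model_spec("hf", "grs", 3)$covariates)
  s3r <- cox_model_spec("hf", "cov_cs", 3, adjust_regional = TRUE)
  expect_true("regional_cs" %in% s3r$covariates)
  expect_error(cox_model_spec("hf", "cov_cs", tier = 4), "tier")
})

test_that("diagnostics report VIF near 1 when orthogonal, Inf when duplicated", {
  set.seed(19)
  n <- 500
  df <- tibble::tibble(time = rexp(n, 0.2), event = runif(n) < 0.6,
                       cov_cs_z = rnorm(n), gcs_z = rnorm(n),
                       age = rnorm(n, 65, 8), male = runif(n) < 0.5,
                       white = runif(n) < 0.9, smoker = runif(n) < 0.1,
                       bmi = rnorm(n, 26, 4),
                       dyslipidemia = runif(n) < 0.3,
                       hypertension = runif(n) < 0.3,
                       diabetes = runif(n) < 0.05,
                       lvmi = rnorm(n, 45, 8), lvedvi = rnorm(n, 76, 12),
                       lvef = rnorm(n, 60, 6))
  spec <- cox_model_spec("hf", "cov_cs", tier = 3)
  fit <- fit_cox(df, spec)
  dg <- check_diagnostics(fit)
  expect_true(all(dg$vif < 1.3))
  expect_true(all(dg$vif_pass))
  expect_true(all(is.finite(dg$schoenfeld_p)))

  df_dup <- df; df_dup$gcs_z <- df_dup$cov_cs_z
  fit_dup <- suppressWarnings(fit_cox(df_dup, spec))
  dg_dup <- check_diagnostics(fit_dup)
  expect_true(any(!is.finite(dg_dup$vif)))
  expect_false(all(dg_dup$vif_pass))
})

test_that("Bonferroni adjustment caps at 1 and sets the 0.0033 threshold", {
  expect_equal(bonferroni_adjust(0.001), 0.015)
  expect_equal(bonferroni_adjust(0.2), 1)
  expect_lt(abs(0.05 / 15 - 0.0033), 5e-5)
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(-0.1), "\\[0, 1\\]")
})

test_that("HFpEF-risk rule gates on preserved LVEF plus 3 criteria", {
  d <- tibble::tibble(age = c(70, 70, 70, 50),
                      lvef = c(55, 45, 55, 55),
                      obesity = c(TRUE, TRUE, FALSE, TRUE),
                      hypertension = c(TRUE, TRUE, TRUE, TRUE),
                      diabetes = c(TRUE, TRUE, FALSE, TRUE),
                      ckd = c(FALSE, TRUE, FALSE, FALSE),
                      af = c(FALSE, TRUE, FALSE, FALSE))
  # 1: age>65 + obesity + htn + diabetes = 4 criteria, LVEF 55 -> in
  # 2: 6 criteria but LVEF 45 -> gate fails
  # 3: age>65 + htn = 2 criteria -> out
  # 4: 3 criteria (obesity, htn, diabetes), age 50 -> in
  expect_equal(hfpef_risk(d), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("subgroup analysis reports not-estimable strata without crashing", {
  co <- simulate_cohort(sim_config(n_participants = 1200, seed = 20))
  qc_bio <- compute_biomarkers(co$strain)
  dat <- endpoint_data(co$participants, qc_bio, co$outcomes, "composite_cv")
  spec <- cox_model_spec("composite_cv", "cov_cs", tier = 2)
  res <- suppressWarnings(subgroup_analysis(dat, spec))
  expect_setequal(res$subgroup,
                  c("age_over_65", "age_65_or_less", "male", "female",
                    "prevalent_ckd", "prevalent_mi", "prevalent_af",
                    "hfpef_risk"))
  big <- res[res$subgroup %in% c("age_over_65", "male", "female"), ]
  expect_true(all(is.finite(big$hr)))
  # a subgroup with no members yields a not-estimable row
  dat0 <- dat; dat0$prev_mi <- FALSE
  res0 <- suppressWarnings(subgroup_analysis(dat0, spec))
  expect_true(is.na(res0$hr[res0$subgroup == "prevalent_mi"]))
})

test_that("endpoint assembly excludes prevalent cases and z-scores markers", {
  co <- simulate_cohort(sim_config(n_participants = 800, seed = 22))
  bio <- compute_biomarkers(co$strain)
  dat <- endpoint_data(co$participants, bio, co$outcomes, "hf")
  prev_ids <- co$participants$participant_id[co$participants$prev_hf]
  expect_false(any(dat$participant_id %in% prev_ids))
  expect_equal(mean(dat$cov_cs_z), 0, tolerance = 1e-10)
  expect_equal(sd(dat$cov_cs_z), 1, tolerance = 1e-10)
  # zero events errors cleanly
  dat_none <- dat; dat_none$event <- FALSE
  expect_error(fit_cox(dat_none, cox_model_spec("hf", "cov_cs", 1)),
               "zero events")
})
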