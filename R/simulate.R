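#' Simulate a synthetic CMR strain cohort
#'
#' Generates a cohort with the statistical structure the downstream analysis
#' assumes: clinical covariates and prevalent-disease flags, CMR volumetrics,
#' three 16-segment strain sets per participant (with optional contiguous
#' regional lesions), proportional-hazards time-to-event outcomes for five
#' endpoints, and configurable measurement artifacts with a full injection
#' ledger. Everything is driven by a single seed: the same configuration
#' always reproduces the cohort bit-identically.
#'
#' The hazard of each endpoint is Weibull-baseline proportional hazards on
#' the *measured* (lesion-inclusive, artifact-free) strain biomarkers and
#' covariates, so that model-recovery experiments can target a known hazard
#' ratio per SD. Death acts as a censoring event for the non-fatal endpoints
#' (cause-specific hazards).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `strain_cohort`: a list with tibbles
#'   `participants` (covariates + volumetrics + lesion status),
#'   `strain` (long format: participant_id, direction, segment, value),
#'   `outcomes` (participant_id, endpoint, time, event, prevalent),
#'   `ledger` (artifact injections), `true_biomarkers` (pre-artifact
#'   biomarkers used to build the linear predictors) and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 50, seed = 1))
#' cohort$participants
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "strain_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants

  participants <- simulate_covariates(n, config)
  lesion <- assign_lesions(n, config)
  participants$lesioned <- lesion$lesioned

  strain_mats <- simulate_strain_matrices(n, config, lesion)
  true_bio <- biomarkers_from_matrices(strain_mats)

  lp <- build_linear_predictors(participants, true_bio, config)
  outcomes <- simulate_outcomes(lp, config, prevalent_flags(participants))

  strain_long <- matrices_to_long(strain_mats)
  corrupted <- inject_artifacts(strain_long, config$artifact_rates)

  structure(list(participants = participants,
                 strain = corrupted$strain,
                 outcomes = outcomes,
                 ledger = corrupted$ledger,
                 true_biomarkers = true_bio,
                 config = config),
            class = "strain_cohort")
}

#' @export
print.strain_cohort <- function(x, ...) {
  cat("<strain_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$strain), " strain cells, ",
      sum(x$outcomes$event), " events across ",
      length(unique(x$outcomes$endpoint)), " endpoints\n", sep = "")
  invisible(x)
}

simulate_covariates <- function(n, config) {
  pv <- config$covariate_prevalences
  draw <- function(nm) runif(n) < pv[[nm]]
  bmi <- rnorm(n, config$bmi_mean, config$bmi_sd)
  lvef <- pmin(pmax(rnorm(n, config$lvef_mean, config$lvef_sd), 15), 80)
  lvmi <- exp(rnorm(n, config$lvmi_meanlog, config$lvmi_sdlog))
  lvedvi <- exp(rnorm(n, config$lvedvi_meanlog, config$lvedvi_sdlog))
  tibble(
    participant_id = seq_len(n),
    age = pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 45), 85),
    male = draw("male"), white = draw("white"), smoker = draw("smoker"),
    bmi = bmi, obesity = bmi >= 30,
    dyslipidemia = draw("dyslipidemia"), hypertension = draw("hypertension"),
    diabetes = draw("diabetes"), ckd = draw("ckd"),
    cad = draw("cad"), prev_mi = draw("prev_mi"),
    cerebrovascular = draw("cerebrovascular"), pvd = draw("pvd"),
    af = draw("af"), va = draw("va"),
    aortic_stenosis = draw("aortic_stenosis"),
    mitral_disease = draw("mitral_disease"),
    acm = draw("acm"), dcm = draw("dcm"), hcm = draw("hcm"),
    prev_hf = draw("prev_hf"),
    lvmi = lvmi, lvedvi = lvedvi,
    lvesvi = lvedvi * (1 - lvef / 100),
    lvmvr = lvmi / lvedvi, lvef = lvef)
}

assign_lesions <- function(n, config) {
  lesioned <- runif(n) < config$lesion_prevalence
  adjacency <- aha_segment_adjacency()
  masks <- matrix(FALSE, n, 16)
  ls_coupled <- rep(FALSE, n)
  idx <- which(lesioned)
  for (i in idx) {
    masks[i, ] <- grow_lesion_mask(config$lesion_n_segments, adjacency)
    ls_coupled[i] <- runif(1) < config$lesion_ls_coupling
  }
  list(lesioned = lesioned, masks = masks, ls_coupled = ls_coupled)
}

#' Simulate segmental strain for participants with known effects
#'
#' Low-level generator behind [simulate_cohort()]: per direction, each
#' segment's raw value is `sign(direction) * (mean + participant effect +
#' segment noise)`, with longitudinal/circumferential negative and radial
#' positive raw sign. Lesioned participants have a contiguous set of
#' segments multiplied by `lesion_attenuation` in magnitude; circumferential
#' and radial always share the lesion mask, the longitudinal direction only
#' for coupled lesions. Consumes the current RNG state.
#'
#' @param participant_effects Tibble with column `participant_id` plus
#'   `effect_longitudinal`, `effect_circumferential`, `effect_radial`
#'   (participant-level magnitude shifts, %); optionally logical `lesioned`.
#' @param config A [sim_config()].
#' @param masks Optional n x 16 logical lesion-mask matrix (a fresh
#'   contiguous mask is grown per lesioned participant when omitted).
#' @param ls_coupled Optional logical vector: lesion also affects the
#'   longitudinal direction.
#' @return Long tibble: participant_id, direction, segment, value.
#' @export
simulate_segmental_strain <- function(participant_effects, config,
                                      masks = NULL, ls_coupled = NULL) {
  n <- nrow(participant_effects)
  lesioned <- participant_effects[["lesioned"]] %||% rep(FALSE, n)
  if (is.null(masks)) {
    adjacency <- aha_segment_adjacency()
    masks <- matrix(FALSE, n, 16)
    for (i in which(lesioned))
      masks[i, ] <- grow_lesion_mask(config$lesion_n_segments, adjacency)
  }
  if (is.null(ls_coupled)) ls_coupled <- lesioned
  effects <- lapply(.directions, function(d)
    participant_effects[[paste0("effect_", d)]] %||% rep(0, n))
  names(effects) <- .directions
  lesion <- list(lesioned = lesioned, masks = masks, ls_coupled = ls_coupled)
  mats <- strain_matrices_from_effects(effects, config, lesion)
  out <- matrices_to_long(mats)
  ids <- participant_effects$participant_id
  out$participant_id <- ids[out$participant_id]
  out
}

simulate_strain_matrices <- function(n, config, lesion) {
  rho <- config$cs_rs_noise_cor %||% 0
  z_cs <- rnorm(n)
  effects <- list(
    longitudinal = rnorm(n, 0, config$between_participant_sd[["longitudinal"]]),
    circumferential = config$between_participant_sd[["circumferential"]] * z_cs,
    radial = config$between_participant_sd[["radial"]] *
      (rho * z_cs + sqrt(1 - rho^2) * rnorm(n)))
  strain_matrices_from_effects(effects, config, lesion)
}

strain_matrices_from_effects <- function(effects, config, lesion) {
  n <- length(effects[[1]])
  # standardized segment noise; circumferential and radial share a latent
  # per-segment factor (mid-wall fibre mechanics drive both directions)
  rho <- config$cs_rs_noise_cor %||% 0
  z <- list(longitudinal = matrix(rnorm(n * 16), n, 16),
            circumferential = matrix(rnorm(n * 16), n, 16))
  z$radial <- rho * z$circumferential +
    sqrt(1 - rho^2) * matrix(rnorm(n * 16), n, 16)
  mats <- list()
  for (d in .directions) {
    mag <- config$direction_means[[d]] + effects[[d]] +
      config$between_segment_sd[[d]] * z[[d]]
    mag <- pmax(mag, 0.1)  # magnitudes stay positive so raw signs are valid
    affected <- if (d == "longitudinal") {
      lesion$masks & lesion$ls_coupled
    } else {
      lesion$masks
    }
    mag[affected] <- mag[affected] * config$lesion_attenuation
    mats[[d]] <- direction_sign(d) * mag
  }
  mats
}

matrices_to_long <- function(mats) {
  n <- nrow(mats[[1]])
  bind_rows(lapply(.directions, function(d) {
    tibble(participant_id = rep(seq_len(n), times = 16),
           direction = d,
           segment = rep(1:16, each = n),
           value = as.vector(mats[[d]]))
  })) %>%
    arrange(.data$participant_id, .data$direction, .data$segment)
}

# fast per-row global strain / CoV from an n x 16 signed matrix
biomarkers_from_matrices <- function(mats) {
  one <- function(m) {
    a <- abs(m)
    mu <- rowMeans(a)
    s <- sqrt(pmax(rowSums((a - mu)^2) / (ncol(a) - 1), 0))
    list(global = mu, cov = s / mu)
  }
  ls <- one(mats$longitudinal); cs <- one(mats$circumferential)
  rs <- one(mats$radial)
  tibble(participant_id = seq_len(nrow(mats[[1]])),
         gls = ls$global, gcs = cs$global, grs = rs$global,
         cov_ls = ls$cov, cov_cs = cs$cov, cov_rs = rs$cov)
}

build_linear_predictors <- function(participants, biomarkers, config) {
  df <- left_join(participants, biomarkers, by = "participant_id")
  zcol <- function(nm) {
    base <- sub("_z$", "", nm)
    if (!base %in% names(df))
      abort(paste0("invalid configuration: unknown hazard covariate `",
                   nm, "`"))
    as.numeric(scale(df[[base]]))
  }
  col <- function(nm) {
    if (grepl("_z$", nm)) return(zcol(nm))
    if (!nm %in% names(df))
      abort(paste0("invalid configuration: unknown hazard covariate `",
                   nm, "`"))
    as.numeric(df[[nm]])
  }
  lp <- sapply(sim_endpoints(), function(ep) {
    betas <- config$log_hazard_ratios[[ep]]
    if (is.null(betas) || length(betas) == 0) return(rep(0, nrow(df)))
    rowSums(sapply(names(betas), function(nm) betas[[nm]] * col(nm)))
  })
  rownames(lp) <- df$participant_id
  lp
}

prevalent_flags <- function(participants) {
  arr <- participants$af | participants$va
  cbind(composite_cv = participants$prev_mi | participants$prev_hf | arr,
        mi = participants$prev_mi,
        hf = participants$prev_hf,
        arrhythmia = arr,
        death = rep(FALSE, nrow(participants)))
}

#' Simulate proportional-hazards outcomes from linear predictors
#'
#' Event times are drawn from a Weibull baseline scaled by `exp(lp)` via
#' inverse-transform sampling; censoring is administrative at
#' `admin_censor_time` combined with, for a configurable fraction of
#' participants, an independent Uniform(0, cutoff) dropout time. Death
#' censors the non-fatal endpoints. Consumes the current RNG state.
#'
#' @param linear_predictors Numeric matrix, participants x endpoints (columns
#'   named with the endpoints; missing endpoints get linear predictor 0).
#' @param config A [sim_config()].
#' @param prevalent Optional logical matrix (participants x endpoints) of
#'   prevalent-disease flags; defaults to all `FALSE`.
#' @return Tibble: participant_id, endpoint, time, event, prevalent.
#' @export
simulate_outcomes <- function(linear_predictors, config, prevalent = NULL) {
  n <- nrow(linear_predictors)
  if (any(!is.finite(linear_predictors)))
    abort("non-finite linear predictor")
  dimnames(linear_predictors) <- list(NULL, colnames(linear_predictors))
  if (is.null(prevalent))
    prevalent <- matrix(FALSE, n, length(sim_endpoints()),
                        dimnames = list(NULL, sim_endpoints()))
  admin <- config$admin_censor_time
  dropout <- runif(n) < config$dropout_prob
  censor_time <- ifelse(dropout, runif(n, 0, admin), admin)

  latent <- sapply(sim_endpoints(), function(ep) {
    bh <- config$baseline_hazard[[ep]]
    lp <- if (ep %in% colnames(linear_predictors))
      linear_predictors[, ep] else rep(0, n)
    bh$scale * (-log(runif(n)))^(1 / bh$shape) * exp(-lp / bh$shape)
  })

  bind_rows(lapply(sim_endpoints(), function(ep) {
    cens <- if (ep == "death") censor_time
            else pmin(censor_time, latent[, "death"])
    t_obs <- pmin(latent[, ep], cens)
    tibble(participant_id = seq_len(n), endpoint = ep,
           time = pmax(t_obs, 1e-8),
           event = latent[, ep] <= cens,
           prevalent = prevalent[, ep])
  }))
}

#' Inject measurement artifacts into a strain table
#'
#' Corrupts a clean long-format strain table at the configured rates:
#' removes all strain rows of randomly emptied participants, drops
#' individual segments, flips value signs (producing the "non-sensical"
#' raw output the QC sign rule targets), and substitutes extreme values
#' placed strictly beyond the cohort's Q3 + 3 IQR fence on absolute values
#' (per direction). Every corrupted cell is recorded so QC recall and
#' precision are computable. Consumes the current RNG state.
#'
#' @param strain Long tibble: participant_id, direction, segment, value.
#' @param artifact_rates List with `sign_flip`, `extreme_outlier`,
#'   `segment_dropout`, `empty_participant` (fractions).
#' @return List: `strain` (corrupted tibble) and `ledger` (tibble with
#'   participant_id, direction, segment, type, original_value, new_value;
#'   dropped cells have `new_value = NA`).
#' @export
inject_artifacts <- function(strain, artifact_rates) {
  r <- artifact_rates
  ledger <- tibble(participant_id = integer(), direction = character(),
                   segment = integer(), type = character(),
                   original_value = numeric(), new_value = numeric())
  if (all(unlist(r) == 0)) return(list(strain = strain, ledger = ledger))

  ids <- unique(strain$participant_id)
  emptied <- ids[runif(length(ids)) < r$empty_participant]
  if (length(emptied)) {
    gone <- strain %>% filter(.data$participant_id %in% emptied)
    ledger <- bind_rows(ledger, gone %>%
      mutate(type = "empty_participant", original_value = .data$value,
             new_value = NA_real_) %>%
      select("participant_id", "direction", "segment", "type",
             "original_value", "new_value"))
    strain <- strain %>% filter(!.data$participant_id %in% emptied)
  }

  dropped <- runif(nrow(strain)) < r$segment_dropout
  if (any(dropped)) {
    gone <- strain[dropped, ]
    ledger <- bind_rows(ledger, gone %>%
      mutate(type = "segment_dropout", original_value = .data$value,
             new_value = NA_real_) %>%
      select("participant_id", "direction", "segment", "type",
             "original_value", "new_value"))
    strain <- strain[!dropped, ]
  }

  # fences from the (still clean-valued) cohort, per direction
  fence_hi <- strain %>%
    group_by(.data$direction) %>%
    summarise(q1 = quantile(abs(.data$value), 0.25, names = FALSE),
              q3 = quantile(abs(.data$value), 0.75, names = FALSE),
              .groups = "drop") %>%
    mutate(iqr = .data$q3 - .data$q1)

  u <- runif(nrow(strain))
  flip <- u < r$sign_flip
  outl <- !flip & u >= r$sign_flip & u < r$sign_flip + r$extreme_outlier

  if (any(flip)) {
    orig <- strain$value[flip]
    strain$value[flip] <- -orig
    ledger <- bind_rows(ledger,
      tibble(participant_id = strain$participant_id[flip],
             direction = strain$direction[flip],
             segment = strain$segment[flip],
             type = "sign_flip", original_value = orig,
             new_value = -orig))
  }
  if (any(outl)) {
    orig <- strain$value[outl]
    fh <- fence_hi[match(strain$direction[outl], fence_hi$direction), ]
    # magnitude strictly beyond Q3 + 3 IQR, correct sign retained
    mag <- fh$q3 + (4 + runif(sum(outl)) * 3) * pmax(fh$iqr, 1)
    newv <- direction_sign(strain$direction[outl]) * mag
    strain$value[outl] <- newv
    ledger <- bind_rows(ledger,
      tibble(participant_id = strain$participant_id[outl],
             direction = strain$direction[outl],
             segment = strain$segment[outl],
             type = "extreme_outlier", original_value = orig,
             new_value = newv))
  }
  list(strain = strain, ledger = ledger)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
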