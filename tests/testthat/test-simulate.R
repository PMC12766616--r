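test_that("identical configurations reproduce the cohort bit-identically", {
  cfg <- sim_config(n_participants = 100, seed = 7,
                    artifact_rates = list(sign_flip = 0.01,
                                          extreme_outlier = 0.01,
                                          segment_dropout = 0.02,
                                          empty_participant = 0.01))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$strain, b$strain)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$ledger, b$ledger)
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(lesion_prevalence = 1.5), "lesion_prevalence")
  expect_error(sim_config(lesion_n_segments = 17), "lesion_n_segments")
  expect_error(sim_config(admin_censor_time = 0), "admin_censor_time")
  expect_error(sim_config(artifact_rates = list(sign_flip = -0.1,
                                                extreme_outlier = 0,
                                                segment_dropout = 0,
                                                empty_participant = 0)),
               "sign_flip")
  expect_error(sim_config(direction_means = c(longitudinal = -1,
                                              circumferential = 18,
                                              radial = 30)),
               "direction_means")
})

test_that("zero lesion prevalence yields a purely healthy strain model", {
  co <- simulate_cohort(sim_config(n_participants = 300, seed = 2,
                                   lesion_prevalence = 0))
  expect_false(any(co$participants$lesioned))
  b <- co$true_biomarkers
  # healthy CoV concentrates near the calibration anchors
  expect_equal(median(b$cov_cs), 0.16, tolerance = 0.1)
  expect_equal(median(b$cov_ls), 0.33, tolerance = 0.1)
})

test_that("zero segment noise makes all 16 segments equal per direction", {
  eff <- tibble::tibble(participant_id = 1:5,
                        effect_longitudinal = rnorm(5),
                        effect_circumferential = rnorm(5),
                        effect_radial = rnorm(5))
  cfg <- sim_config(between_segment_sd = c(longitudinal = 0,
                                           circumferential = 0,
                                           radial = 0),
                    lesion_prevalence = 0)
  strain <- simulate_segmental_strain(eff, cfg)
  spread <- strain |>
    dplyr::group_by(participant_id, direction) |>
    dplyr::summarise(rng = diff(range(value)), .groups = "drop")
  expect_true(all(spread$rng == 0))
  # raw sign convention
  expect_true(all(strain$value[strain$direction == "radial"] > 0))
  expect_true(all(strain$value[strain$direction != "radial"] < 0))
})

test_that("attenuation factor 1 reproduces the unlesioned strain exactly", {
  eff <- tibble::tibble(participant_id = 1:20,
                        effect_longitudinal = 0, effect_circumferential = 0,
                        effect_radial = 0, lesioned = TRUE)
  masks <- matrix(FALSE, 20, 16); masks[, 1:4] <- TRUE
  cfg1 <- sim_config(seed = 3, lesion_attenuation = 1)
  cfg2 <- sim_config(seed = 3, lesion_attenuation = 0.5)
  set.seed(99)
  s1 <- simulate_segmental_strain(eff, cfg1, masks = masks,
                                  ls_coupled = rep(TRUE, 20))
  set.seed(99)
  s2 <- simulate_segmental_strain(eff, cfg2, masks = masks,
                                  ls_coupled = rep(TRUE, 20))
  set.seed(99)
  s0 <- simulate_segmental_strain(eff |> dplyr::mutate(lesioned = FALSE),
                                  cfg1, masks = matrix(FALSE, 20, 16),
                                  ls_coupled = rep(FALSE, 20))
  expect_equal(s1$value, s0$value)
  expect_false(isTRUE(all.equal(s2$value, s0$value)))
})

test_that("a 4-of-16 half-magnitude lesion gives the closed-form CoV", {
  # noise-free set {12 x m, 4 x m/2}: CoV computable by hand
  eff <- tibble::tibble(participant_id = 1L, effect_longitudinal = 0,
                        effect_circumferential = 0, effect_radial = 0,
                        lesioned = TRUE)
  cfg <- sim_config(between_segment_sd = c(longitudinal = 0,
                                           circumferential = 0,
                                           radial = 0),
                    lesion_attenuation = 0.5)
  masks <- matrix(FALSE, 1, 16); masks[1, c(2, 3, 8, 9)] <- TRUE
  strain <- simulate_segmental_strain(eff, cfg, masks = masks,
                                      ls_coupled = TRUE)
  m <- cfg$direction_means[["circumferential"]]
  vals <- c(rep(m, 12), rep(m / 2, 12 / 3))
  expected <- sd(vals) / mean(vals)
  got <- strain |>
    dplyr::filter(direction == "circumferential") |>
    dplyr::pull(value)
  expect_equal(strain_cov(got), expected, tolerance = 1e-12)
})

test_that("lesion masks are contiguous on the segment adjacency graph", {
  adj <- aha_segment_adjacency()
  # adjacency is symmetric and within 1..16
  for (s in 1:16) {
    for (nb in adj[[as.character(s)]]) {
      expect_true(nb >= 1 && nb <= 16)
      expect_true(s %in% adj[[as.character(nb)]])
    }
  }
  set.seed(42)
  for (k in c(1, 4, 9, 16)) {
    mask <- grow_lesion_mask(k, adj)
    expect_equal(sum(mask), k)
    # connectivity: BFS from the first selected segment reaches all
    sel <- which(mask)
    reached <- sel[1]
    repeat {
      nxt <- unique(unlist(adj[as.character(reached)]))
      nxt <- intersect(nxt, sel)
      if (all(nxt %in% reached)) break
      reached <- union(reached, nxt)
    }
    expect_setequal(reached, sel)
  }
})

test_that("artifact injection at rate zero is the identity", {
  co <- simulate_cohort(sim_config(n_participants = 50, seed = 4))
  out <- inject_artifacts(co$strain,
                          list(sign_flip = 0, extreme_outlier = 0,
                               segment_dropout = 0, empty_participant = 0))
  expect_identical(out$strain, co$strain)
  expect_equal(nrow(out$ledger), 0)
})

test_that("saturated sign flipping inverts every value and records it", {
  co <- simulate_cohort(sim_config(n_participants = 30, seed = 4))
  out <- inject_artifacts(co$strain,
                          list(sign_flip = 1, extreme_outlier = 0,
                               segment_dropout = 0, empty_participant = 0))
  expect_equal(out$strain$value, -co$strain$value)
  expect_equal(nrow(out$ledger), nrow(co$strain))
  expect_true(all(out$ledger$type == "sign_flip"))
})

test_that("injection counts stay within binomial 99% bounds", {
  rates <- list(sign_flip = 0.01, extreme_outlier = 0.01,
                segment_dropout = 0.05, empty_participant = 0.005)
  co <- simulate_cohort(sim_config(n_participants = 5000, seed = 12,
                                   artifact_rates = rates))
  led <- co$ledger
  counts <- table(led$type)
  n_cells <- 5000 * 48
  bounds <- function(n, p) {
    qbinom(c(0.005, 0.995), n, p)
  }
  b_empty <- bounds(5000, rates$empty_participant)
  n_empty <- length(unique(led$participant_id[led$type ==
                                                "empty_participant"]))
  expect_gte(n_empty, b_empty[1]); expect_lte(n_empty, b_empty[2])

  cells_after_empty <- n_cells - 48 * n_empty
  b_drop <- bounds(cells_after_empty, rates$segment_dropout)
  expect_gte(counts[["segment_dropout"]], b_drop[1])
  expect_lte(counts[["segment_dropout"]], b_drop[2])

  cells_left <- cells_after_empty - counts[["segment_dropout"]]
  for (tp in c("sign_flip", "extreme_outlier")) {
    b <- bounds(cells_left, 0.01)
    expect_gte(counts[[tp]], b[1] * 0.9)
    expect_lte(counts[[tp]], b[2] * 1.1)
  }
})

test_that("null-hazard exponential outcomes match the analytic median", {
  cfg <- sim_config(n_participants = 20000, seed = 9,
                    log_hazard_ratios = list(),
                    baseline_hazard = list(
                      composite_cv = list(shape = 1, scale = 10),
                      mi = list(shape = 1, scale = 10),
                      hf = list(shape = 1, scale = 10),
                      arrhythmia = list(shape = 1, scale = 10),
                      death = list(shape = 1, scale = 1e9)),
                    admin_censor_time = 1e9, dropout_prob = 0)
  set.seed(1)
  lp <- matrix(0, 20000, 5,
               dimnames = list(NULL, strainhet:::sim_endpoints()))
  oc <- simulate_outcomes(lp, cfg)
  hf <- oc[oc$endpoint == "hf", ]
  # rate 1/10 per year -> median ln(2) * 10
  expect_equal(median(hf$time), log(2) * 10, tolerance = 0.05 * log(2) * 10)
  expect_true(all(oc$time > 0))
  expect_error(simulate_outcomes(lp * NA, cfg), "non-finite")
})

test_that("lower attenuation monotonically raises CoV and lowers GCS", {
  covs <- numeric(0); gcss <- numeric(0)
  for (att in c(0.8, 0.6, 0.4)) {
    co <- simulate_cohort(sim_config(n_participants = 800, seed = 21,
                                     lesion_prevalence = 1,
                                     lesion_attenuation = att))
    covs <- c(covs, mean(co$true_biomarkers$cov_cs))
    gcss <- c(gcss, mean(co$true_biomarkers$gcs))
  }
  expect_true(all(diff(covs) > 0))
  expect_true(all(diff(gcss) < 0))
})

test_that("lesioned participants show higher CoV_CS and lower GCS", {
  co <- simulate_cohort(sim_config(n_participants = 2000, seed = 31,
                                   lesion_prevalence = 0.5,
                                   lesion_attenuation = 0.5))
  b <- dplyr::left_join(co$true_biomarkers,
                        co$participants[, c("participant_id", "lesioned")],
                        by = "participant_id")
  expect_gt(mean(b$cov_cs[b$lesioned]), mean(b$cov_cs[!b$lesioned]))
  expect_lt(mean(b$gcs[b$lesioned]), mean(b$gcs[!b$lesioned]))
})
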