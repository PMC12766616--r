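test_that("healthy reference selection applies the full exclusion list", {
  co <- simulate_cohort(sim_config(n_participants = 400, seed = 14))
  p <- co$participants
  healthy <- select_healthy_reference(p)
  # no retained participant carries any exclusion flag
  for (f in healthy_exclusion_flags())
    expect_false(any(healthy[[f]]))
  # hypertension alone excludes
  one <- p[1, ]
  one[healthy_exclusion_flags()] <- FALSE
  one$bmi <- 24
  two <- one; two$hypertension <- TRUE
  expect_equal(nrow(select_healthy_reference(rbind(one, one))), 2)
  got <- select_healthy_reference(rbind(one, two))
  expect_equal(nrow(got), 1)
  # all-flags-false cohort is returned whole
  clean <- p
  clean[healthy_exclusion_flags()] <- FALSE
  expect_equal(nrow(select_healthy_reference(clean)), nrow(p))
  # empty result errors
  allbad <- p
  allbad$hypertension <- TRUE
  expect_error(select_healthy_reference(allbad), "larger cohort")
})

test_that("reference ranges are mean +/- 2 SD with exact arithmetic", {
  v <- c(16.4, 18.4, 20.4)  # mean 18.4, sd 2
  r <- compute_reference_range(v, "gls")
  expect_equal(r$mean, 18.4)
  expect_equal(r$sd, 2)
  expect_equal(r$lower, 14.4)
  expect_equal(r$upper, 22.4)
  expect_warning(compute_reference_range(rep(5, 4)), "degenerate")
  expect_error(compute_reference_range(1), ">= 2")
  # translation/scale equivariance
  r2 <- compute_reference_range(3 * v + 1)
  expect_equal(r2$lower, 3 * r$lower + 1)
  expect_equal(r2$upper, 3 * r$upper + 1)
})

test_that("regional abnormality needs an outlying segment AND preserved global", {
  lo <- rep(10, 16); hi <- rep(30, 16)
  grange <- c(15, 25)
  inside <- rep(20, 16)
  expect_false(flag_regional_abnormality(inside, lo, hi, 20, grange))
  one_out <- inside; one_out[5] <- 8
  expect_true(flag_regional_abnormality(one_out, lo, hi, 20, grange))
  # global outside its range -> FALSE regardless of segments
  expect_false(flag_regional_abnormality(one_out, lo, hi, 14, grange))
  expect_true(is.na(flag_regional_abnormality(one_out, lo, hi, NA, grange)))
  # monotone: widening segmental ranges never turns FALSE into TRUE
  set.seed(3)
  for (i in 1:25) {
    sv <- runif(16, 5, 35)
    f_narrow <- flag_regional_abnormality(sv, lo, hi, 20, grange)
    f_wide <- flag_regional_abnormality(sv, lo - 3, hi + 3, 20, grange)
    expect_true(f_narrow || !f_wide)
  }
})

test_that("cohort regional flags agree with the scalar rule", {
  co <- simulate_cohort(sim_config(n_participants = 300, seed = 16,
                                   lesion_prevalence = 0.3,
                                   lesion_attenuation = 0.5))
  qc <- apply_qc(co$strain, roster = co$participants$participant_id)
  joined <- dplyr::inner_join(co$participants, qc$biomarkers,
                              "participant_id")
  healthy <- select_healthy_reference(joined)
  ranges <- reference_range_table(
    healthy, qc$strain[qc$strain$participant_id %in%
                         healthy$participant_id, ])
  flags <- regional_abnormality_flags(qc$strain, qc$biomarkers, ranges)
  # spot-check a sample of participants against flag_regional_abnormality
  seg_cs <- ranges[!is.na(ranges$segment) &
                     ranges$direction == "circumferential", ]
  seg_cs <- seg_cs[order(seg_cs$segment), ]
  g_cs <- ranges[ranges$metric == "gcs", ]
  for (pid in flags$participant_id[seq(1, 300, by = 23)]) {
    cells <- qc$strain[qc$strain$participant_id == pid &
                         qc$strain$direction == "circumferential" &
                         qc$strain$valid, ]
    expected <- flag_regional_abnormality(
      abs(cells$value), seg_cs$lower[cells$segment],
      seg_cs$upper[cells$segment],
      qc$biomarkers$gcs[qc$biomarkers$participant_id == pid],
      c(g_cs$lower, g_cs$upper))
    expect_identical(flags$regional_cs[flags$participant_id == pid],
                     expected)
  }
  # lesions inflate the regional-abnormality rate
  with_lesion <- dplyr::inner_join(
    flags, co$participants[, c("participant_id", "lesioned")],
    "participant_id")
  expect_gt(mean(with_lesion$regional_cs[with_lesion$lesioned],
                 na.rm = TRUE),
            mean(with_lesion$regional_cs[!with_lesion$lesioned],
                 na.rm = TRUE))
})

test_that("Mann-Whitney matches rank enumeration on small samples", {
  r <- group_compare(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$u, 0)
  expect_equal(r$method, "exact")
  # identical multiset split across groups -> p = 1
  sym <- group_compare(c(5, 7, 5, 7), c("a", "a", "b", "b"))
  expect_equal(sym$p, 1)
  # complementarity U + U' = n1 * n2
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(11)
    g <- c(rep("a", 5), rep("b", 6))
    u1 <- group_compare(x, g)$u
    u2 <- group_compare(x, ifelse(g == "a", "b", "a"))$u
    expect_equal(u1 + u2, 5 * 6)
  }
  expect_error(group_compare(1:3, rep("a", 3)), "2 groups")
})

test_that("Spearman correlation is rank-based and transform-invariant", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(correlate(x, sqrt(x)), 1)
  expect_equal(correlate(x, -x^3), -1)
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(correlate(a, b), correlate(exp(a), b), tolerance = 1e-12)
  # tied-data toy equals the direct rank-formula computation
  xt <- c(1, 2, 2, 3); yt <- c(4, 4, 5, 6)
  expect_equal(correlate(xt, yt),
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_true(is.na(correlate(rep(1, 5), 1:5)))
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("tertile split balances distinct values and handles ties", {
  t9 <- tertile_split(1:9)
  expect_equal(as.character(t9),
               rep(c("T1", "T2", "T3"), each = 3))
  expect_error(tertile_split(rep(2, 10)), "degenerate")
  set.seed(6)
  for (i in 1:10) {
    v <- rnorm(30 + i)
    tt <- table(tertile_split(v))
    expect_lte(max(tt) - min(tt), 1)
  }
  # missing propagates
  tm <- tertile_split(c(1:9, NA))
  expect_true(is.na(tm[10]))
})
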