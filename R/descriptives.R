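#' Select the healthy reference subset of a cohort
#'
#' Retains participants free of prevalent cardiometabolic risk factors and
#' cardiovascular disease: no dyslipidemia, obesity, hypertension, diabetes,
#' CKD, active smoking, CAD or previous MI, cerebrovascular disease, PVD,
#' AF, aortic stenosis, mitral valve disease, cardiomyopathy or HF.
#'
#' @param participants Tibble of covariates with the logical exclusion flags
#'   (as produced by [simulate_cohort()] or [read_cohort_tables()]).
#' @param exclusion_flags Character vector of flag columns that disqualify a
#'   participant; defaults to the standard list.
#' @return The healthy subset (tibble).
#' @export
select_healthy_reference <- function(participants,
                                     exclusion_flags = healthy_exclusion_flags()) {
  missing_cols <- setdiff(exclusion_flags, names(participants))
  if (length(missing_cols))
    abort(paste0("missing covariate columns: ",
                 paste(missing_cols, collapse = ", ")))
  any_flag <- Reduce(`|`, lapply(exclusion_flags,
                                 function(f) participants[[f]]))
  healthy <- participants[!any_flag, , drop = FALSE]
  if (nrow(healthy) == 0)
    abort("no healthy reference participants; use a larger cohort")
  healthy
}

#' @rdname select_healthy_reference
#' @export
healthy_exclusion_flags <- function() {
  c("dyslipidemia", "obesity", "hypertension", "diabetes", "ckd", "smoker",
    "cad", "prev_mi", "cerebrovascular", "pvd", "af", "aortic_stenosis",
    "mitral_disease", "acm", "dcm", "hcm", "prev_hf")
}

#' Reference range for a metric (mean +/- 2 SD)
#'
#' @param values Numeric vector of healthy-reference values (>= 2
#'   non-missing).
#' @param metric Optional metric name carried into the output.
#' @return One-row tibble: metric, n, mean, sd, lower, upper.
#' @export
#' @examples
#' compute_reference_range(rnorm(100, 18.4, 2), "gls")
compute_reference_range <- function(values, metric = NA_character_) {
  v <- values[is.finite(values)]
  if (length(v) < 2) abort("reference range needs >= 2 healthy values")
  m <- mean(v); s <- sd(v)
  if (s == 0) warn(paste0("degenerate reference range for `", metric,
                          "`: zero spread"))
  tibble(metric = metric, n = length(v), mean = m, sd = s,
         lower = m - 2 * s, upper = m + 2 * s)
}

#' Reference-range table for global strain, strain CoV and every segment
#'
#' Computes mean +/- 2 SD ranges in the healthy reference subset for the six
#' derived biomarkers and for the absolute strain of each of the 16 segments
#' in each direction (48 segmental ranges), the structure the
#' regional-abnormality rule consumes.
#'
#' @param biomarkers Biomarker tibble ([compute_biomarkers()]) restricted to
#'   healthy participants.
#' @param strain Long strain tibble (with `valid` column after QC) restricted
#'   to the same participants.
#' @return Tibble: metric, direction, segment (NA for global metrics), n,
#'   mean, sd, lower, upper.
#' @export
reference_range_table <- function(biomarkers, strain) {
  glob <- bind_rows(lapply(c("gls", "gcs", "grs",
                             "cov_ls", "cov_cs", "cov_rs"), function(m)
    compute_reference_range(biomarkers[[m]], m))) %>%
    mutate(direction = rep(.directions, 2), segment = NA_integer_)
  if (!"valid" %in% names(strain)) strain$valid <- is.finite(strain$value)
  seg <- strain %>%
    filter(.data$valid) %>%
    group_by(.data$direction, .data$segment) %>%
    summarise(rng = list(compute_reference_range(abs(.data$value))),
              .groups = "drop") %>%
    tidyr::unnest("rng") %>%
    mutate(metric = paste0("segment_", .data$segment))
  bind_rows(glob, seg) %>%
    select("metric", "direction", "segment", "n", "mean", "sd",
           "lower", "upper")
}

#' Regional strain abnormality flag
#'
#' A participant-direction is regionally abnormal when at least one valid
#' segment lies outside its per-segment reference range while the global
#' strain of that direction remains inside the global range ("preserved
#' overall global strain").
#'
#' @param segment_values Numeric vector of absolute segmental strain.
#' @param segment_lower,segment_upper Per-segment reference limits aligned
#'   with `segment_values`.
#' @param global_value Absolute global strain for the direction.
#' @param global_range Numeric `c(lower, upper)` for the global metric.
#' @return `TRUE`/`FALSE`, or `NA` when the global value is missing.
#' @export
flag_regional_abnormality <- function(segment_values, segment_lower,
                                      segment_upper, global_value,
                                      global_range) {
  if (!is.finite(global_value)) return(NA)
  global_ok <- global_value >= global_range[[1]] &&
    global_value <= global_range[[2]]
  if (!global_ok) return(FALSE)
  ok <- is.finite(segment_values)
  any(segment_values[ok] < segment_lower[ok] |
        segment_values[ok] > segment_upper[ok])
}

#' Regional abnormality flags for a whole cohort
#'
#' Applies [flag_regional_abnormality()] per participant and direction
#' against a reference-range table.
#'
#' @param strain QC'd long strain tibble (with `valid`).
#' @param biomarkers Biomarker tibble for the same participants.
#' @param ranges Output of [reference_range_table()] (computed on the healthy
#'   subset).
#' @return Tibble: participant_id, regional_ls, regional_cs, regional_rs.
#' @export
regional_abnormality_flags <- function(strain, biomarkers, ranges) {
  if (!"valid" %in% names(strain)) strain$valid <- is.finite(strain$value)
  suffix <- c(longitudinal = "ls", circumferential = "cs", radial = "rs")
  seg_rng <- ranges %>%
    filter(!is.na(.data$segment)) %>%
    select("direction", "segment", seg_lower = "lower", seg_upper = "upper")
  any_out <- strain %>%
    filter(.data$valid) %>%
    left_join(seg_rng, by = c("direction", "segment")) %>%
    group_by(.data$participant_id, .data$direction) %>%
    summarise(any_outside = any(abs(.data$value) < .data$seg_lower |
                                  abs(.data$value) > .data$seg_upper),
              .groups = "drop")
  out <- biomarkers %>% select("participant_id")
  for (d in .directions) {
    s <- suffix[[d]]
    grange <- ranges %>% filter(.data$metric == paste0("g", s))
    ao <- any_out %>% filter(.data$direction == d)
    outside <- ao$any_outside[match(biomarkers$participant_id,
                                    ao$participant_id)]
    outside[is.na(outside)] <- FALSE
    gv <- biomarkers[[paste0("g", s)]]
    global_in <- gv >= grange$lower & gv <= grange$upper
    flag <- ifelse(is.na(gv), NA, ifelse(!global_in, FALSE, outside))
    out[[paste0("regional_", s)]] <- flag
  }
  out
}

#' Mann-Whitney U comparison of a biomarker between two groups
#'
#' Two-sided Mann-Whitney U test: exact by enumeration of all label
#' assignments when the combined sample size is at most `exact_max`
#' (handles ties exactly), tie-corrected normal approximation otherwise.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector aligned with `values`.
#' @param exact_max Combined-n threshold for the exact test (default 12).
#' @return One-row tibble: u (first group), p, method, n1, n2.
#' @export
#' @examples
#' group_compare(c(1, 2, 3, 4), c("a", "a", "b", "b"))
group_compare <- function(values, group, exact_max = 12) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  if (nlevels(group) != 2) abort("group_compare needs exactly 2 groups")
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0 || n2 == 0) abort("group_compare: a group is empty")
  u_stat <- function(x, ix) {
    r <- rank(x)
    sum(r[ix]) - length(ix) * (length(ix) + 1) / 2
  }
  pooled <- c(g1, g2)
  u <- u_stat(pooled, seq_len(n1))
  n <- n1 + n2
  if (n <= exact_max) {
    combs <- combn(n, n1)
    us <- apply(combs, 2, function(ix) u_stat(pooled, ix))
    center <- n1 * n2 / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (u - n1 * n2 / 2) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  tibble(u = u, p = min(p, 1), method = method, n1 = n1, n2 = n2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @param x,y Numeric vectors (>= 3 complete pairs).
#' @return Spearman's rho, or `NA` when either rank vector is constant.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("correlate needs >= 3 paired values")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Tertile assignment
#'
#' Cuts at the 33.3% and 66.7% quantiles of the supplied values; ties at a
#' cut go to the lower tertile. Labels are ordered T1 < T2 < T3 by biomarker
#' value.
#'
#' @param values Numeric vector (>= 3 non-missing, non-degenerate).
#' @return Ordered factor with levels T1, T2, T3 (NA propagates).
#' @export
#' @examples
#' tertile_split(1:9)
tertile_split <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3) abort("tertile_split needs >= 3 non-missing values")
  cuts <- quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (cuts[1] == cuts[2] || length(unique(v)) < 3)
    abort("tertile_split: degenerate spread")
  lab <- rep(NA_character_, length(values))
  ok <- is.finite(values)
  lab[ok] <- ifelse(values[ok] <= cuts[1], "T1",
                    ifelse(values[ok] <= cuts[2], "T2", "T3"))
  factor(lab, levels = c("T1", "T2", "T3"), ordered = TRUE)
}
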