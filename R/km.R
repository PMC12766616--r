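#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group with cumulative hazard displayed as
#' `-log(S(t))`.
#'
#' @param time,event Follow-up and event indicator.
#' @param group Grouping vector (single group when omitted).
#' @return Tibble: group, time, n_risk, n_event, n_censor, survival, cumhaz.
#' @export
km_estimate <- function(time, event, group = NULL) {
  event <- as.numeric(event)
  if (sum(event) == 0) abort("all observations censored in all groups")
  if (is.null(group)) group <- rep("all", length(time))
  df <- tibble(time = time, event = event, group = as.character(group))
  bind_rows(lapply(split(df, df$group), function(d) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    tibble(group = d$group[1], time = sf$time, n_risk = sf$n.risk,
           n_event = sf$n.event, n_censor = sf$n.censor,
           survival = sf$surv, cumhaz = -log(pmax(sf$surv, 1e-300)))
  }))
}

#' Logrank test for trend over ordered groups
#'
#' Score test with equally spaced ordered group scores: the statistic sums
#' score-weighted observed-minus-expected event counts over the distinct
#' event times, with variance from the hypergeometric model; 1 degree of
#' freedom. With two groups it reduces to the standard two-sample logrank
#' test, and it is invariant to affine recoding of the scores.
#'
#' @param time,event Follow-up and event indicator.
#' @param group Ordered factor (or vector coercible to one) of >= 2 groups.
#' @param scores Numeric scores per group level (default 1, 2, ...).
#' @return One-row tibble: chisq, df, p.value, n_groups, n_events.
#' @export
logrank_trend <- function(time, event, group, scores = NULL) {
  event <- as.numeric(event)
  group <- factor(group)
  keep <- !is.na(group) & is.finite(time)
  time <- time[keep]; event <- event[keep]; group <- droplevels(group[keep])
  k <- nlevels(group)
  if (k < 2) abort("logrank trend needs >= 2 groups")
  if (is.null(scores)) scores <- seq_len(k)
  s <- scores[as.integer(group)]
  u <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    if (n <= 1) next
    s_risk <- s[at_risk]
    s_bar <- mean(s_risk)
    u <- u + sum(s[event == 1 & time == t]) - d * s_bar
    v <- v + d * (n - d) / (n - 1) * (mean(s_risk^2) - s_bar^2)
  }
  chisq <- if (v > 0) u^2 / v else 0
  tibble(chisq = chisq, df = 1,
         p.value = pchisq(chisq, 1, lower.tail = FALSE),
         n_groups = k, n_events = sum(event))
}

#' Stratified tertile Kaplan-Meier panels
#'
#' For each strain biomarker and endpoint, splits participants into
#' within-stratum tertiles (reduced LVEF < 50% vs preserved LVEF >= 50%),
#' estimates the KM cumulative hazard per tertile and tests for an ordered
#' trend across tertiles.
#'
#' @param data Participant-level tibble with `lvef` and the biomarker
#'   columns (e.g. covariates joined with [compute_biomarkers()] output).
#' @param outcomes Long outcome tibble.
#' @param biomarkers Biomarker columns to panel (default the six strain
#'   markers).
#' @param endpoints Endpoints to panel (default all five).
#' @param tertile_scope `"stratum"` (default: tertiles computed within each
#'   LVEF stratum) or `"cohort"`.
#' @return List of tibbles `curves` (per-panel KM curves) and `trend`
#'   (per-panel logrank trend chisq and p). Panels with fewer than 3
#'   distinct biomarker values in a stratum are skipped with a warning.
#' @export
stratified_tertile_km <- function(data, outcomes,
                                  biomarkers = strain_markers,
                                  endpoints = sim_endpoints(),
                                  tertile_scope = c("stratum", "cohort")) {
  tertile_scope <- match.arg(tertile_scope)
  data <- data %>% mutate(lvef_stratum = ifelse(.data$lvef < 50,
                                                "reduced", "preserved"))
  curves <- list(); trends <- list()
  for (bm in biomarkers) {
    if (tertile_scope == "cohort") {
      data$.tertile <- tertile_split(data[[bm]])
    }
    for (stratum in c("reduced", "preserved")) {
      sub <- data %>% filter(.data$lvef_stratum == stratum)
      if (tertile_scope == "stratum") {
        if (length(unique(sub[[bm]][is.finite(sub[[bm]])])) < 3) {
          warn(paste0("skipping panel ", bm, " / ", stratum,
                      ": < 3 distinct values"))
          next
        }
        sub$.tertile <- tertile_split(sub[[bm]])
      }
      for (ep in endpoints) {
        oc <- outcomes %>%
          filter(.data$endpoint == ep, !.data$prevalent) %>%
          dplyr::inner_join(sub %>%
                              select("participant_id", ".tertile"),
                            by = "participant_id") %>%
          filter(!is.na(.data$.tertile))
        if (nrow(oc) == 0 || sum(oc$event) == 0) next
        km <- km_estimate(oc$time, oc$event, oc$.tertile) %>%
          mutate(biomarker = bm, endpoint = ep, lvef_stratum = stratum)
        tr <- logrank_trend(oc$time, oc$event, oc$.tertile) %>%
          mutate(biomarker = bm, endpoint = ep, lvef_stratum = stratum)
        curves[[length(curves) + 1]] <- km
        trends[[length(trends) + 1]] <- tr
      }
    }
  }
  list(curves = bind_rows(curves), trend = bind_rows(trends))
}
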