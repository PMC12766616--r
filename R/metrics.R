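# product-limit estimator of the censoring survival G, with left-continuous
# evaluation G(t-); at tied times events are taken to precede censorings
censoring_survival <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]; c_s <- 1 - event[ord]
  ut <- unique(t_s)
  counts <- as.vector(table(factor(t_s, levels = ut)))
  n_at_risk <- length(t_s) - c(0, cumsum(counts)[-length(counts)])
  d_c <- as.vector(rowsum(c_s, factor(t_s, levels = ut)))
  surv <- cumprod(1 - d_c / n_at_risk)
  function(t, left = TRUE) {
    ix <- findInterval(t, ut, left.open = left)
    out <- rep(1, length(t))
    out[ix > 0] <- surv[ix[ix > 0]]
    out
  }
}

#' Uno's censoring-robust concordance index
#'
#' IPCW-weighted fraction of concordant comparable pairs, truncated at the
#' horizon `tau`: for each event at time T_i < tau, every subject still
#' under observation beyond T_i is a comparator, the pair is weighted by the
#' inverse squared censoring survival at T_i (left-continuous Kaplan-Meier
#' of the censoring distribution), and tied risk scores count 1/2. With no
#' censoring this reduces exactly to Harrell's C.
#'
#' @param risk Numeric risk scores (higher = higher predicted hazard).
#' @param time,event Follow-up time and event indicator (0/1 or logical).
#' @param tau Truncation horizon; default 95th percentile of observed
#'   follow-up.
#' @return Concordance in \[0, 1\].
#' @export
uno_c_index <- function(risk, time, event, tau = NULL) {
  event <- as.numeric(event)
  stopifnot(length(risk) == length(time), length(time) == length(event))
  if (is.null(tau)) tau <- quantile(time, 0.95, names = FALSE)
  G <- censoring_survival(time, event)
  ev <- which(event == 1 & time < tau)
  num <- 0; den <- 0
  for (i in ev) {
    g <- G(time[i])
    if (g <= 0) next
    w <- 1 / g^2
    cmp <- time > time[i]
    if (!any(cmp)) next
    num <- num + w * (sum(risk[i] > risk[cmp]) +
                        0.5 * sum(risk[i] == risk[cmp]))
    den <- den + w * sum(cmp)
  }
  if (den == 0) abort("no comparable pairs before `tau`")
  num / den
}

#' Bootstrap comparison of Uno C between nested models
#'
#' Computes the C-index difference of two fitted Cox models on the shared
#' data, and a p-value from an unpaired t-test comparing the two bootstrap
#' C-index distributions (B participant-level resamples, both models refit
#' per resample). A paired percentile-bootstrap p-value on the per-resample
#' differences is also reported; the unpaired t-test is anticonservative for
#' overlapping resamples, which is why both are returned.
#'
#' @param fit_full,fit_reduced [fit_cox()] results on identical rows.
#' @param B Number of bootstrap resamples (default 200; below 50 warns).
#' @param seed Integer seed for the resampling.
#' @param tau Truncation horizon passed to [uno_c_index()].
#' @return One-row tibble: c_full, c_reduced, delta_c, p_unpaired_t,
#'   p_paired_percentile, tau, B, n_failed.
#' @export
compare_c_index <- function(fit_full, fit_reduced, B = 200, seed = 1,
                            tau = NULL) {
  stopifnot(inherits(fit_full, "strain_cox"),
            inherits(fit_reduced, "strain_cox"))
  if (nrow(fit_full$data) != nrow(fit_reduced$data))
    abort("models must be fitted on identical rows")
  if (B > 0 && B < 50)
    warn("B < 50 bootstrap resamples: comparison is unstable")
  df <- fit_full$data
  if (is.null(tau)) tau <- quantile(df$time, 0.95, names = FALSE)
  c_of <- function(fit, data) {
    lp <- as.numeric(predict(fit$fit, newdata = data, type = "lp"))
    uno_c_index(lp, data$time, data$event, tau = tau)
  }
  c_full <- unname(c_of(fit_full, df))
  c_reduced <- unname(c_of(fit_reduced, df))

  if (B == 0) {
    return(tibble(c_full = c_full, c_reduced = c_reduced,
                  delta_c = c_full - c_reduced,
                  p_unpaired_t = NA_real_, p_paired_percentile = NA_real_,
                  tau = tau, B = 0L, n_failed = 0L))
  }
  set.seed(seed)
  boots <- matrix(NA_real_, B, 2)
  n_failed <- 0L
  for (b in seq_len(B)) {
    ix <- sample.int(nrow(df), replace = TRUE)
    res <- try({
      d <- df[ix, ]
      f1 <- survival::coxph(stats::formula(fit_full$fit), data = d,
                            ties = fit_full$ties)
      f0 <- survival::coxph(stats::formula(fit_reduced$fit), data = d,
                            ties = fit_reduced$ties)
      c(uno_c_index(as.numeric(predict(f1, type = "lp")), d$time, d$event,
                    tau = tau),
        uno_c_index(as.numeric(predict(f0, type = "lp")), d$time, d$event,
                    tau = tau))
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L
    else boots[b, ] <- res
  }
  ok <- stats::complete.cases(boots)
  d_boot <- boots[ok, 1] - boots[ok, 2]
  p_t <- if (all(d_boot == 0)) 1 else
    stats::t.test(boots[ok, 1], boots[ok, 2], paired = FALSE)$p.value
  p_paired <- 2 * min(mean(d_boot <= 0), mean(d_boot >= 0))
  tibble(c_full = c_full, c_reduced = c_reduced,
         delta_c = c_full - c_reduced,
         p_unpaired_t = p_t,
         p_paired_percentile = min(1, p_paired),
         tau = tau, B = B, n_failed = n_failed)
}

# IPCW weights for event status at a horizon: events before the horizon get
# 1/G(T-), horizon survivors 1/G(horizon), earlier-censored subjects 0
ipcw_status_weights <- function(time, event, horizon) {
  G <- censoring_survival(time, event)
  is_event <- time <= horizon & event == 1
  is_survivor <- time > horizon
  w <- numeric(length(time))
  w[is_event] <- 1 / G(time[is_event])
  g_h <- G(horizon, left = FALSE)
  if (g_h <= 0) abort("censoring survival is zero at the horizon")
  w[is_survivor] <- 1 / g_h
  list(w = w, is_event = is_event, is_survivor = is_survivor)
}

#' Continuous net reclassification improvement NRI(>0)
#'
#' Net proportion of events re-ranked upward plus non-events re-ranked
#' downward by the new risk score relative to the old one, with event
#' status at the horizon IPCW-adjusted for censoring. Reported in percent
#' (saturation bound +200%) with a percentile bootstrap interval.
#'
#' @param risk_old,risk_new Risk scores on the same subjects at the horizon.
#' @param time,event Follow-up and event indicator.
#' @param horizon Status horizon (years).
#' @param B Bootstrap resamples for the interval (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param conf_level Interval coverage (default 0.95).
#' @return One-row tibble: nri_pct, event_component_pct,
#'   nonevent_component_pct, conf.low, conf.high.
#' @export
continuous_nri <- function(risk_old, risk_new, time, event, horizon,
                           B = 200, seed = 1, conf_level = 0.95) {
  stopifnot(length(risk_old) == length(risk_new))
  event <- as.numeric(event)
  point <- function(ro, rn, tm, ev) {
    wts <- ipcw_status_weights(tm, ev, horizon)
    if (sum(wts$is_event) == 0) abort("no events by the horizon")
    up <- rn > ro; down <- rn < ro
    we <- wts$w * wts$is_event
    wn <- wts$w * wts$is_survivor
    ev_comp <- (sum(we[up]) - sum(we[down])) / sum(we)
    ne_comp <- (sum(wn[down]) - sum(wn[up])) / sum(wn)
    c(ev_comp, ne_comp)
  }
  pt <- point(risk_old, risk_new, time, event)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    set.seed(seed)
    reps <- replicate(B, {
      ix <- sample.int(length(time), replace = TRUE)
      out <- try(sum(point(risk_old[ix], risk_new[ix], time[ix],
                           event[ix])), silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out
    })
    alpha <- (1 - conf_level) / 2
    ci <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  }
  tibble(nri_pct = 100 * sum(pt),
         event_component_pct = 100 * pt[1],
         nonevent_component_pct = 100 * pt[2],
         conf.low = 100 * ci[1], conf.high = 100 * ci[2])
}

#' IPCW Brier score at a horizon
#'
#' Mean squared difference between the predicted event probability by the
#' horizon and the observed status, with inverse-probability-of-censoring
#' weights (events weighted by 1/G(T-), horizon survivors by 1/G(horizon));
#' lower is better.
#'
#' @param risk Predicted event probabilities in \[0, 1\].
#' @param time,event Follow-up and event indicator.
#' @param horizon Horizon (default 5 years).
#' @return Brier score in \[0, 1\].
#' @export
brier_score <- function(risk, time, event, horizon = 5) {
  if (any(risk < 0 | risk > 1)) abort("`risk` must lie in [0, 1]")
  event <- as.numeric(event)
  wts <- ipcw_status_weights(time, event, horizon)
  err <- numeric(length(time))
  err[wts$is_event] <- (1 - risk[wts$is_event])^2
  err[wts$is_survivor] <- risk[wts$is_survivor]^2
  sum(wts$w * err) / length(time)
}

#' Predicted event probability at a horizon from a Cox fit
#'
#' Baseline cumulative hazard (matching the fit's tie handling) combined
#' with the centered linear predictor: `1 - exp(-H0(horizon) * exp(lp))`.
#'
#' @param x A [fit_cox()] result.
#' @param horizon Horizon (years).
#' @param newdata Optional data (defaults to the fitting data).
#' @return Numeric vector of event probabilities.
#' @export
predicted_risk <- function(x, horizon = 5, newdata = NULL) {
  stopifnot(inherits(x, "strain_cox"))
  if (is.null(newdata)) newdata <- x$data
  bh <- survival::basehaz(x$fit, centered = TRUE)
  ix <- findInterval(horizon, bh$time)
  h0 <- if (ix == 0) 0 else bh$hazard[ix]
  lp <- as.numeric(predict(x$fit, newdata = newdata, type = "lp"))
  1 - exp(-h0 * exp(lp))
}

#' Likelihood-ratio test and AIC difference for nested Cox models
#'
#' @param fit_full,fit_reduced Nested [fit_cox()] results on the same rows.
#' @return One-row tibble: chisq, df, p.value, delta_aic, improvement
#'   (delta AIC < -2 and LRT p < 0.05).
#' @export
lrt_and_aic <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "strain_cox"),
            inherits(fit_reduced, "strain_cox"))
  if (fit_full$fit$n != fit_reduced$fit$n)
    abort("models must be fitted on the same rows")
  k_full <- sum(!is.na(coef(fit_full$fit)))
  k_red <- sum(!is.na(coef(fit_reduced$fit)))
  if (k_full < k_red) abort("`fit_full` must nest `fit_reduced`")
  chisq <- 2 * (fit_full$fit$loglik[2] - fit_reduced$fit$loglik[2])
  df <- k_full - k_red
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  delta_aic <- glance(fit_full)$aic - glance(fit_reduced)$aic
  tibble(chisq = chisq, df = df, p.value = p, delta_aic = delta_aic,
         improvement = delta_aic < -2 & p < 0.05)
}
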