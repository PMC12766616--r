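# independent brute-force oracles used to pin down the estimators;
# these deliberately use naive loop implementations, distinct from the
# package's vectorized code paths

# product-limit censoring survival by explicit looping, left-continuous
oracle_censor_G <- function(time, event, t_eval, left = TRUE) {
  ut <- sort(unique(time))
  g <- 1
  for (u in ut) {
    if ((left && u < t_eval) || (!left && u <= t_eval)) {
      at_risk <- sum(time >= u)
      d_c <- sum(time == u & event == 0)
      g <- g * (1 - d_c / at_risk)
    }
  }
  g
}

# O(n^2) IPCW pair sum for Uno's C
oracle_uno_c <- function(risk, time, event, tau) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    g <- oracle_censor_G(time, event, time[i])
    if (g <= 0) next
    for (j in seq_len(n)) {
      if (time[j] > time[i]) {
        w <- 1 / g^2
        den <- den + w
        if (risk[i] > risk[j]) num <- num + w
        else if (risk[i] == risk[j]) num <- num + 0.5 * w
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# direct-count IPCW continuous NRI (proportion sums, explicit loop)
oracle_nri <- function(risk_old, risk_new, time, event, horizon) {
  n <- length(time)
  we_up <- we_down <- we <- 0
  wn_up <- wn_down <- wn <- 0
  g_h <- oracle_censor_G(time, event, horizon, left = FALSE)
  for (i in seq_len(n)) {
    if (time[i] <= horizon && event[i] == 1) {
      w <- 1 / oracle_censor_G(time, event, time[i])
      we <- we + w
      if (risk_new[i] > risk_old[i]) we_up <- we_up + w
      if (risk_new[i] < risk_old[i]) we_down <- we_down + w
    } else if (time[i] > horizon) {
      w <- 1 / g_h
      wn <- wn + w
      if (risk_new[i] > risk_old[i]) wn_up <- wn_up + w
      if (risk_new[i] < risk_old[i]) wn_down <- wn_down + w
    }
  }
  100 * ((we_up - we_down) / we + (wn_down - wn_up) / wn)
}

# direct IPCW Brier sum
oracle_brier <- function(risk, time, event, horizon) {
  n <- length(time)
  total <- 0
  g_h <- oracle_censor_G(time, event, horizon, left = FALSE)
  for (i in seq_len(n)) {
    if (time[i] <= horizon && event[i] == 1) {
      total <- total + (1 - risk[i])^2 / oracle_censor_G(time, event, time[i])
    } else if (time[i] > horizon) {
      total <- total + risk[i]^2 / g_h
    }
  }
  total / n
}

# exact Mann-Whitney by enumerating all label assignments
oracle_mann_whitney <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1); n <- length(pooled)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  list(u = u_obs,
       p = mean(abs(us - center) >= abs(u_obs - center) - 1e-12))
}

# logrank trend statistic assembled from per-time contingency tables
oracle_logrank_trend <- function(time, event, group, scores) {
  group <- factor(group)
  lv <- levels(group)
  u <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n_g <- sapply(lv, function(g) sum(group == g & time >= t))
    d_g <- sapply(lv, function(g) sum(group == g & time == t & event == 1))
    n <- sum(n_g); d <- sum(d_g)
    if (n <= 1) next
    e_g <- d * n_g / n
    u <- u + sum(scores * (d_g - e_g))
    mean_s <- sum(scores * n_g) / n
    mean_s2 <- sum(scores^2 * n_g) / n
    v <- v + d * (n - d) / (n - 1) * (mean_s2 - mean_s^2)
  }
  chisq <- if (v > 0) u^2 / v else 0
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# random survival instance with ~30% censoring for the oracle comparisons
random_survival_instance <- function(n) {
  time_event <- rexp(n, 0.3)
  time_cens <- rexp(n, 0.13)
  list(time = pmin(time_event, time_cens),
       event = as.numeric(time_event <= time_cens),
       risk = rnorm(n))
}

# small long-format strain table from a named list of 16-vectors
make_strain_long <- function(values_by_direction, participant_id = 1L) {
  dplyr::bind_rows(lapply(names(values_by_direction), function(d) {
    v <- values_by_direction[[d]]
    tibble::tibble(participant_id = participant_id, direction = d,
                   segment = seq_along(v), value = v)
  }))
}
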