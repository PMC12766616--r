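#' Knot placement for a restricted cubic spline
#'
#' Default rule places the 4 knots at the 5th, 25th, 75th and 95th
#' percentiles. A "quartile" rule anchoring the knots at a low-tail point
#' plus the three quartiles (5th percentile, Q1, Q2, Q3) is provided as an
#' alternative, since "4 knots at quartiles" is underdetermined (quartiles
#' give only 3 interior points).
#'
#' @param x Numeric vector.
#' @param rule `"percentile"` (default) or `"quartile"`.
#' @param n_knots Number of knots (default 4).
#' @return Sorted numeric vector of knots.
#' @export
rcs_knots <- function(x, rule = c("percentile", "quartile"), n_knots = 4) {
  rule <- match.arg(rule)
  x <- x[is.finite(x)]
  probs <- if (rule == "percentile") {
    if (n_knots == 4) c(0.05, 0.25, 0.75, 0.95)
    else seq(0.05, 0.95, length.out = n_knots)
  } else {
    c(0.05, 0.25, 0.50, 0.75)
  }
  knots <- quantile(x, probs, names = FALSE, type = 7)
  if (anyDuplicated(knots))
    abort("duplicate knots (degenerate quantiles): use fewer knots")
  sort(knots)
}

#' Restricted cubic spline basis
#'
#' Truncated-power construction with linearity constraints beyond the
#' boundary knots, normalized by the squared knot span (Harrell's
#' parameterization): for k knots the basis has k - 1 columns, the first
#' being x itself. The basis is continuous with continuous first and second
#' derivatives at every knot and exactly linear outside the boundary knots;
#' below the first knot the nonlinear columns are exactly zero.
#'
#' @param x Numeric vector.
#' @param knots Sorted knot vector (from [rcs_knots()]), length >= 3.
#' @return Numeric matrix with `length(knots) - 1` columns named
#'   `rcs1`, `rcs2`, ...
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) abort("at least 3 knots are required")
  if (anyDuplicated(knots)) abort("duplicate knots")
  knots <- sort(knots)
  pos3 <- function(u) pmax(u, 0)^3
  span2 <- (knots[k] - knots[1])^2
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
                       pos3(x - knots[k - 1]) *
                         (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
                       pos3(x - knots[k]) *
                         (knots[k - 1] - knots[j]) /
                         (knots[k] - knots[k - 1])) / span2
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  out
}

#' Likelihood-ratio test for non-linearity of a strain biomarker
#'
#' Compares a Cox model in which the focal biomarker enters through a
#' 4-knot restricted cubic spline against the linear model with the same
#' adjustment set, on identical rows. With 4 knots the spline adds 2
#' nonlinear columns, so the test has 2 degrees of freedom.
#'
#' @param data Analysis tibble from [endpoint_data()].
#' @param spec A [cox_model_spec()] (typically tier 3).
#' @param knot_rule Passed to [rcs_knots()].
#' @param ties Tie handling for the Cox fits.
#' @return One-row tibble: chisq, df, p.value, knots (list-column),
#'   knot_rule.
#' @export
test_nonlinearity <- function(data, spec,
                              knot_rule = c("percentile", "quartile"),
                              ties = "efron") {
  knot_rule <- match.arg(knot_rule)
  focal <- paste0(spec$biomarker, "_z")
  need <- c("time", "event", spec$covariates)
  df <- data[stats::complete.cases(data[, need]), ]
  knots <- rcs_knots(df[[focal]], rule = knot_rule)
  basis <- rcs_basis(df[[focal]], knots)
  for (j in seq_len(ncol(basis))) df[[colnames(basis)[j]]] <- basis[, j]

  others <- setdiff(spec$covariates, focal)
  rhs_lin <- paste(c("rcs1", others), collapse = " + ")
  rhs_rcs <- paste(c(colnames(basis), others), collapse = " + ")
  ctl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit_lin <- survival::coxph(
    as.formula(paste("survival::Surv(time, event) ~", rhs_lin)),
    data = df, ties = ties, control = ctl)
  fit_rcs <- survival::coxph(
    as.formula(paste("survival::Surv(time, event) ~", rhs_rcs)),
    data = df, ties = ties, control = ctl)
  chisq <- 2 * (fit_rcs$loglik[2] - fit_lin$loglik[2])
  df_test <- ncol(basis) - 1
  tibble(chisq = chisq, df = df_test,
         p.value = pchisq(chisq, df_test, lower.tail = FALSE),
         knots = list(knots), knot_rule = knot_rule)
}
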