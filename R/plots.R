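#' Kaplan-Meier cumulative-hazard panel plot
#'
#' Step curves of cumulative hazard by tertile, faceted by LVEF stratum,
#' for one biomarker and endpoint of a [stratified_tertile_km()] result.
#'
#' @param curves The `curves` tibble from [stratified_tertile_km()].
#' @param biomarker,endpoint Panel to draw.
#' @return A ggplot object.
#' @export
plot_km_tertiles <- function(curves, biomarker, endpoint) {
  df <- curves %>%
    filter(.data$biomarker == .env$biomarker,
           .data$endpoint == .env$endpoint)
  if (nrow(df) == 0) abort("no curves for that biomarker/endpoint")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cumhaz,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~lvef_stratum) +
    ggplot2::labs(x = "Years since baseline CMR",
                  y = "Cumulative hazard",
                  colour = "Tertile",
                  title = paste0(toupper(biomarker), " tertiles: ",
                                 endpoint)) +
    ggplot2::theme_minimal()
}

#' Distribution of a strain biomarker by group
#'
#' @param data Participant tibble joined with biomarkers.
#' @param biomarker Biomarker column name.
#' @param group Bare or string column name of a grouping flag.
#' @return A ggplot object.
#' @export
plot_cov_distribution <- function(data, biomarker = "cov_cs",
                                  group = "lesioned") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[biomarker]],
                               fill = factor(.data[[group]]))) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = biomarker, fill = group) +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios for a fitted model
#'
#' @param object A [fit_cox()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot strain_cox
#' @export
autoplot.strain_cox <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
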