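#' Plot database-specific stratum rates
#'
#' Dot plot of incidence rates per 100 000 person-years by age group, one
#' panel per outcome, coloured by sex, with exact-Poisson error bars and a
#' log10 rate axis. Suppressed cells are dropped from the display.
#'
#' @param rates Output of [stratum_rates()].
#' @param outcomes Optional character vector restricting the panels.
#' @return A ggplot object.
#' @export
plot_stratum_rates <- function(rates, outcomes = NULL) {
  d <- filter(rates, !.data$suppressed)
  if (!is.null(outcomes)) d <- filter(d, .data$outcome_id %in% outcomes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_group, y = .data$rate,
                                  colour = .data$sex,
                                  group = interaction(.data$database_id, .data$sex))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5),
                             size = 0.25) +
    ggplot2::facet_wrap(~outcome_id, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age group", y = "Rate per 100 000 person-years",
                  colour = "Sex") +
    ggplot2::theme_minimal()
}

#' Plot pooled rates with prediction intervals
#'
#' The machine-readable analogue of a frequency-classification panel: pooled
#' rate and 95% prediction interval by age group and sex, one panel per
#' outcome, with the CIOMS category boundaries as horizontal reference
#' lines.
#'
#' @param pooled Output of [pool_rates()].
#' @return A ggplot object.
#' @export
plot_pooled_rates <- function(pooled) {
  d <- filter(pooled, !is.na(.data$pooled_rate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_group, y = .data$pooled_rate,
                                  colour = .data$sex, group = .data$sex)) +
    ggplot2::geom_hline(yintercept = c(10, 100, 1000, 10000),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$pi_low,
                                          ymax = .data$pi_high),
                             position = ggplot2::position_dodge(width = 0.4),
                             size = 0.25) +
    ggplot2::facet_wrap(~outcome_id, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age group",
                  y = "Pooled rate per 100 000 person-years (95% PI)",
                  colour = "Sex") +
    ggplot2::theme_minimal()
}

#' Weight plot for a pooled fit
#'
#' @param object A `bg_meta` object.
#' @param ... Unused.
#' @return A ggplot bar chart of normalised random-effects weights.
#' @method autoplot bg_meta
#' @export
autoplot.bg_meta <- function(object, ...) {
  d <- tibble(database_id = object$database_id %||%
                paste0("db", seq_len(object$k)),
              weight = object$weights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$database_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Normalised random-effects weight", y = NULL) +
    ggplot2::theme_minimal()
}
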