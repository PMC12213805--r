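#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_abline
#'   labs facet_wrap theme_minimal annotate
NULL

#' Plot a flow waveform
#'
#' @param object a [flow_waveform()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$flow * 1e6)) +
    geom_line(colour = "#2c7fb8") +
    labs(x = "time [s]", y = "flow [mL/s]",
         title = sprintf("Inlet flow waveform (SV %.1f mL, T %.2f s)",
                         stroke_volume(object), wf_period(object))) +
    theme_minimal()
}

#' Plot a Windkessel pressure waveform
#'
#' @param object a `pressure_waveform` from [simulate_3ewk()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pressure_waveform <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$time, y = pa_to_mmhg(.data$pressure),
             colour = factor(.data$cycle))) +
    geom_line(show.legend = FALSE) +
    labs(x = "time [s]", y = "pressure [mmHg]",
         title = "3-element Windkessel pressure response") +
    theme_minimal()
}

#' Plot a cohort fit (TAWSS-pressure style scatter)
#'
#' @param object a `cohort_fit` from [linear_fit()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 2.5, colour = "#225ea8") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = 2) +
    annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
             label = sprintf("R^2 == %.2f", object$r_squared), parse = TRUE) +
    labs(x = object$predictor, y = object$response) +
    theme_minimal()
}

#' Plot a cohort correlation report
#'
#' Faceted scatter of each fitted predictor against mean PAP with the OLS
#' line and R^2.
#'
#' @param object a `cohort_correlations` from [cohort_correlation_report()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_correlations <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(as_tibble(object),
                  label = sprintf("%s (R^2=%.2f)", .data$predictor,
                                  .data$r_squared)),
    "data"
  )
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(colour = "#225ea8") +
    geom_abline(aes(slope = .data$slope, intercept = .data$intercept),
                linetype = 2) +
    facet_wrap(~label, scales = "free_x") +
    labs(x = "predictor", y = "mean PAP [mmHg]") +
    theme_minimal()
}

#' Plot a TAWSS map along the wall
#'
#' @param object a `tawss_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tawss_map <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$location, y = .data$tawss_pa,
             colour = .data$region)) +
    geom_point() +
    labs(x = "wall element", y = "TAWSS [Pa]", colour = "region") +
    theme_minimal()
}
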