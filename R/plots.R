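# ggplot2 graphics for the main result types.

#' Plot a sensorgram or injection cycle
#'
#' @param object A [sensorgram()] or `spr_cycle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensorgram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$response_RU)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = c(sg_marker(object, "t_start"), sg_marker(object, "t_stop")),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sensorgram
#' @export
autoplot.spr_cycle <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$active), trace = "active"),
    dplyr::mutate(as_tibble(object$reference), trace = "reference")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$response_RU,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a steady-state affinity fit
#'
#' Measured plateau responses against concentration with the constrained
#' 1:1 isotherm overlaid; the dashed lines mark KD and the half-saturation
#' response.
#'
#' @param object A [fit_steady_state()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.steady_state_fit <- function(object, ...) {
  grid <- tibble(conc_M = exp(seq(log(min(object$data$conc_M) / 2),
                                  log(max(object$data$conc_M) * 2),
                                  length.out = 200)))
  grid$req_RU <- grid$conc_M * object$rmax / (grid$conc_M + object$kd) +
    object$offset
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_M * 1e6, y = .data$req_RU)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$kd * 1e6, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("Concentration (" * mu * "M)"),
                  y = expression(R[eq] ~ "(RU)")) +
    ggplot2::theme_minimal()
}

#' Plot a constrained dose-response fit
#'
#' @param object A [fit_ic50()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  lc <- log(object$data$conc_M)
  grid <- tibble(conc_M = exp(seq(min(lc) - log(4), max(lc) + log(4),
                                  length.out = 200)))
  grid$pct_activity <- 100 / (1 + (grid$conc_M / object$ic50)^object$hill)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_M * 1e6, y = .data$pct_activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$ic50 * 1e6, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("Inhibitor (" * mu * "M)"),
                  y = "Activity (%)") +
    ggplot2::theme_minimal()
}

#' Screening overview plot
#'
#' Percent of theoretical Rmax per screened compound with the hit threshold
#' and the superstoichiometric exclusion line; hits highlighted.
#'
#' @param records Screen-record tibble from [screen_compounds()].
#' @param config The [triage_config()] used (for the threshold lines).
#' @return A ggplot object.
#' @export
plot_screen <- function(records, config = triage_config()) {
  df <- dplyr::mutate(records, idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$pct_rmax,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 100 * config$hit_fraction,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 100 * config$superstoich_factor,
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "Compound", y = expression("% of theoretical" ~ R[max]),
                  colour = "Hit") +
    ggplot2::theme_minimal()
}

#' Domain-mapping bar plot
#'
#' Stoichiometry-normalized occupancies across surfaces, one panel per
#' analyte if an `analyte` column is present.
#'
#' @param map Tibble from [domain_map()] (optionally with an `analyte`
#'   column).
#' @return A ggplot object.
#' @export
plot_domain_map <- function(map) {
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$surface, y = .data$occupancy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Normalized occupancy") +
    ggplot2::theme_minimal()
  if ("analyte" %in% names(map)) {
    p <- p + ggplot2::facet_wrap(~analyte)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
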