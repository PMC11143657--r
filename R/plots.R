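# ggplot2 methods for the package's result types.

#' @export
autoplot.step_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 0),
    df[c("time", "estimate")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time since randomization", y = "Probability",
      title = sprintf(
        "%s, arm %s", attr(object, "estimator"), attr(object, "arm")
      )
    )
}

#' Overlay the product-limit risk curves of a dataset
#'
#' Draws one minus Kaplan-Meier against the Aalen-Johansen cumulative
#' incidence for each arm, the visual form of the upward Kaplan-Meier bias
#' under competing events.
#'
#' @inheritParams incidence_proportion
#' @return A ggplot object.
#' @export
plot_risk_curves <- function(data, tau = max_eval_time(data)) {
  df <- purrr::map_dfr(sort(unique(data$arm)), function(a) {
    dplyr::bind_rows(
      dplyr::mutate(
        tibble::as_tibble(risk_curve(one_minus_km(data, a, tau))),
        estimator = "1 - Kaplan-Meier", arm = a
      ),
      dplyr::mutate(
        tibble::as_tibble(risk_curve(aalen_johansen(data, a, tau))[
          , c("time", "estimate", "variance", "n_risk", "d_ae", "d_ce")
        ]),
        estimator = "Aalen-Johansen", arm = a
      )
    )
  })
  df <- dplyr::bind_rows(
    tidyr::expand_grid(
      time = 0, estimate = 0,
      estimator = unique(df$estimator), arm = unique(df$arm)
    ),
    df
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$estimate, colour = .data$estimator
  )) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm)) +
    ggplot2::labs(
      x = "Time since randomization", y = "AE probability", colour = NULL
    )
}

#' @export
autoplot.bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$estimator, y = .data$ratio
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("Ratio to %s (log scale)", attr(object, "reference") %||% "benchmark")
    )
}

#' @export
autoplot.switch_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$comparator, y = .data$gold, fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Comparator category", y = "Gold-standard category", fill = "AEs")
}
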