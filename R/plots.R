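#' Plot a simulated trajectory
#'
#' @param object A [new_trajectory()].
#' @param ... Unused.
#' @return A ggplot: value against time, with the transient burn-in shaded.
#' @export
autoplot.pop_trajectory <- function(object, ...) {
  n_discard <- attr(object, "n_discard")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time step",
      y = if (attr(object, "scale") == "log") "log abundance" else "abundance",
      title = sprintf("%s trajectory", attr(object, "source"))
    )
  if (n_discard > 0) {
    p <- p + ggplot2::annotate("rect",
      xmin = -Inf, xmax = n_discard, ymin = -Inf, ymax = Inf,
      alpha = 0.12, fill = "grey40"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of empirical stationary variance by density-dependence strength
#'
#' One box per `beta` level, faceted by environmental variance; whiskers
#' extend to Q1 - 1.5 IQR and Q3 + 1.5 IQR. Shows the monotone increase of
#' the stationary variance with the strength of density regulation.
#'
#' @param records Output of [run_experiment()].
#' @return A ggplot.
#' @export
plot_stationary_variance <- function(records) {
  d <- dplyr::filter(records, .data$model == "known")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$beta_true), y = .data$v_inf
  )) +
    ggplot2::geom_boxplot(fill = "goldenrod", alpha = 0.7) +
    ggplot2::facet_wrap(~sigma2_true, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression("strength of density dependence" ~ beta),
      y = "empirical stationary variance"
    )
}

#' Boxplots of the density-dependent variance share under fitted models
#'
#' @param records Output of [run_experiment()]; only fitted-model rows are
#'   shown.
#' @return A ggplot with one fill per fitted model.
#' @export
plot_phi_dd <- function(records) {
  d <- dplyr::filter(records, .data$model != "known")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$beta_true), y = .data$phi_dd, fill = .data$model
  )) +
    ggplot2::geom_boxplot(alpha = 0.7, position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~sigma2_true, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(gompertz = "goldenrod", ricker = "steelblue")) +
    ggplot2::labs(
      x = expression("strength of density dependence" ~ beta),
      y = expression("proportion of stationary variance due to density regulation" ~ phi[dd])
    )
}

#' Mean density-dependent share against its theoretical value
#'
#' Across-replicate mean of `phi_dd` with its 2.5-97.5 percentile interval,
#' against `beta`, overlaid with the theoretical squares `beta^2`.
#'
#' @param summary Output of [summarize_experiment()]; rows with
#'   `model == "gompertz"` are used unless only one model is present.
#' @param model Which fitted model's rows to display.
#' @return A ggplot.
#' @export
plot_phi_vs_beta <- function(summary, model = "gompertz") {
  d <- dplyr::filter(summary, .data$model == !!model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_true)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$phi_dd_p2.5, ymax = .data$phi_dd_p97.5),
      width = 0.02, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$phi_dd_mean),
      colour = "blue", size = 2.5
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$phi_dd_theory),
      colour = "darkorange", shape = 18, size = 3
    ) +
    ggplot2::facet_wrap(~sigma2_true, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression(beta),
      y = expression(phi[dd]),
      title = expression("mean" ~ phi[dd] ~ "(blue) vs" ~ beta^2 ~ "(orange)")
    )
}
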