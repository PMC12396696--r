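#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's objects:
#' raw trajectories with group means, filter estimates with particle bands,
#' and time-varying rate functions with credible bands.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gaitadapt-plots
NULL

#' @rdname gaitadapt-plots
#' @method autoplot gait_trials
#' @export
autoplot.gait_trials <- function(object, ...) {
  gm <- group_means(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$step, y = .data$angle)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_line(data = gm,
                       ggplot2::aes(y = .data$y_bar, colour = .data$group),
                       linewidth = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "stride step", y = "knee angle (deg)")
}

#' @rdname gaitadapt-plots
#' @param what `"mean"` or `"variance"` panel for filter estimates.
#' @method autoplot filter_estimate
#' @export
autoplot.filter_estimate <- function(object, what = c("mean", "variance"),
                                     ...) {
  what <- match.arg(what)
  d <- tibble::as_tibble(object)
  if (what == "mean") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$step)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m_lo, ymax = .data$m_hi,
                                        fill = .data$group), alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(y = .data$m_hat,
                                      colour = .data$group)) +
      ggplot2::labs(x = "stride step", y = "estimated mean angle (deg)")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$step)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sigma2_lo,
                                        ymax = .data$sigma2_hi,
                                        fill = .data$group), alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(y = .data$sigma2_hat,
                                      colour = .data$group)) +
      ggplot2::labs(x = "stride step", y = "estimated variance (deg^2)")
  }
}

#' @rdname gaitadapt-plots
#' @param parameter Which rate function to draw: `"A"`, `"B"` or `"f"`.
#' @method autoplot tv_rates
#' @export
autoplot.tv_rates <- function(object, parameter = c("A", "B", "f"), ...) {
  parameter <- match.arg(parameter)
  d <- tibble::as_tibble(object)
  d$.lo <- d[[paste0(parameter, "_lo")]]
  d$.hi <- d[[paste0(parameter, "_hi")]]
  d$.est <- d[[parameter]]
  ylab <- switch(parameter,
                 A = "retention function A(t) (deg/step)",
                 B = "learning-rate function B(t)",
                 f = "fitted mean function (deg)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lo, ymax = .data$.hi,
                                      fill = .data$group), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.est, colour = .data$group)) +
    ggplot2::labs(x = "stride step", y = ylab)
}

#' Box plots of per-participant retention and learning rates
#'
#' @param individual A tibble from [fit_individual_rates()].
#' @return A ggplot object (two facets: retention factor and learning rate).
#' @export
plot_individual_rates <- function(individual) {
  d <- tidyr::pivot_longer(
    dplyr::filter(individual, .data$rank_ok),
    cols = c("A", "B"), names_to = "parameter", values_to = "estimate"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$estimate,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "per-participant estimate")
}
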