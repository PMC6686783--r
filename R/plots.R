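#' Diagnostic plots
#'
#' `autoplot()` methods for the package's result objects, in the plain
#' ggplot2 style of model-diagnostic figures: posterior marginals for a
#' fit, trace plots for chains, GPP series with credible bands for a
#' campaign report, and a diel composite plot.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cosflux-plots
NULL

#' @rdname cosflux-plots
#' @export
autoplot.cos_fit <- function(object, ...) {
  draws <- posterior_draws(object$chains) |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "param")
  ggplot(draws, aes(x = .data$value)) +
    geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    facet_wrap(~param, scales = "free") +
    labs(title = sprintf("Posterior marginals (%s)",
                         toupper(sub("plus", "+", object$model))),
         x = NULL, y = "draws") +
    theme_minimal()
}

#' @rdname cosflux-plots
#' @export
autoplot.posterior_chains <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(object$params), names_to = "param") |>
    ggplot(aes(x = .data$iteration, y = .data$value,
               colour = factor(.data$chain))) +
    geom_line(linewidth = 0.2, alpha = 0.8) +
    geom_vline(xintercept = object$burn, linetype = 2) +
    facet_wrap(~param, scales = "free_y") +
    labs(colour = "chain", y = NULL) +
    theme_minimal()
}

#' @rdname cosflux-plots
#' @export
autoplot.campaign_result <- function(object, ...) {
  s <- object$series
  ggplot(s, aes(x = .data$timestamp)) +
    geom_ribbon(aes(ymin = .data$gpp_lo_fp, ymax = .data$gpp_hi_fp),
                fill = "grey40", alpha = 0.4) +
    geom_ribbon(aes(ymin = .data$gpp_lo_fpplus, ymax = .data$gpp_hi_fpplus),
                fill = "forestgreen", alpha = 0.3) +
    geom_line(aes(y = .data$gpp_fp), colour = "black", linewidth = 0.3) +
    geom_line(aes(y = .data$gpp_fpplus), colour = "forestgreen", linewidth = 0.3) +
    labs(title = sprintf("%s: GPP, FP (black) vs FP+ (green)", object$site),
         x = NULL, y = expression(GPP~(mu*mol~m^-2~s^-1))) +
    theme_minimal()
}

#' Plot a diel composite
#'
#' @param composite Output of [diel_composite()].
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_diel_composite <- function(composite, ylab = "flux") {
  ggplot(composite, aes(x = .data$hour, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "steelblue", alpha = 0.3) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "hour of day (CET)", y = ylab) +
    theme_minimal()
}
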