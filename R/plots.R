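#' Plot a fitted saturation curve over the data
#'
#' Mean rates (with +/- SE bars where replicate variances are available)
#' and the fitted rate law evaluated on a dense substrate grid.
#'
#' @param object a `kin_fit` from [fit_model()].
#' @param n_grid number of points for the fitted curve (default 200).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  d$sem <- ifelse(is.na(d$rate_variance), NA_real_,
                  sqrt(d$rate_variance / d$n_replicates))
  grid <- tibble(s_mM = seq(0, max(d$s_mM), length.out = n_grid))
  grid$rate <- predict(object, newdata = grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s_mM, y = .data$mean_rate)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                   ymax = .data$mean_rate + .data$sem),
      width = 0, na.rm = TRUE, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$rate),
                       colour = "#2166ac") +
    ggplot2::labs(x = "Substrate (mM)", y = "Rate (U/mg)",
                  title = sprintf("Weighted %s fit", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a salt-sensitivity summary
#'
#' Percent decrease of the summarised parameter versus the 0 mM NaCl
#' reference, per enzyme and salt level.
#'
#' @param sensitivity a tibble from [salt_sensitivity_summary()].
#' @return A ggplot object.
#' @export
plot_salt_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = factor(.data$nacl_mM),
                               y = .data$percent_decrease,
                               fill = .data$enzyme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Added NaCl (mM)", y = "Vm decrease (%)",
                  fill = "Enzyme") +
    ggplot2::theme_minimal()
}
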