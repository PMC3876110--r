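# Plotting methods for simulation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recorded trace of a simulation
#'
#' @param object a `ttmyo_sim` with a dense trace.
#' @param vars trace columns to show (faceted); defaults to the membrane
#'   potential and cytosolic Ca2+.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ttmyo_sim <- function(object, vars = c("v", "ca_i"), ...) {
  if (is.null(object$trace)) abort("simulation holds no dense trace")
  df <- tidyr::pivot_longer(object$trace[, c("time", vars)],
                            -"time", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL)
}

#' Plot an end-diastolic per-cycle series
#'
#' @param sim a `ttmyo_sim`.
#' @param var end-diastolic column of the per-cycle table.
#' @return a ggplot object.
#' @export
plot_end_diastolic <- function(sim, var = "k_c_end") {
  df <- end_diastolic_series(sim, var)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_end, .data[[var]])) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "time (s)", y = var)
}

#' Plot the radial t-tubular concentration profile
#'
#' @param state named state vector (e.g. `sim$final_state`).
#' @param ion `"ca"`, `"k"` or `"na"`.
#' @return a ggplot object.
#' @export
plot_tubular_profile <- function(state, ion = "ca") {
  df <- tubular_profile(state)
  ggplot2::ggplot(df, ggplot2::aes(.data$shell, .data[[ion]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "shell (1 = membrane-adjacent)", y = paste0("[", ion, "] (mM)"))
}
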