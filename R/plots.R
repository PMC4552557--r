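#' Kymograph plot of a trajectory
#'
#' Space-time heat map of membrane-bound MinD (`rho_d + rho_de`) along
#' the cell's long axis.
#'
#' @param object a `min_trajectory`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot min_trajectory
#' @export
autoplot.min_trajectory <- function(object, ...) {
  df <- tidy_kymograph(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$z,
                                   fill = .data$membrane_MinD)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MinD (1/um^2)") +
    ggplot2::labs(x = "time (s)", y = "axial position z (um)",
                  title = "Membrane-bound MinD kymograph")
}

tidy_kymograph <- function(tr) {
  stopifnot(inherits(tr, "min_trajectory"))
  tibble::tibble(
    time = rep(tr$times, times = ncol(tr$kymograph)),
    z = rep(tr$geometry$z_centers, each = nrow(tr$kymograph)),
    membrane_MinD = as.vector(tr$kymograph))
}

#' Plot the time-averaged axial profile and its h/w construction
#'
#' @param tr a `min_trajectory`
#' @param ... passed to [performance()]
#' @return a ggplot object
#' @export
plot_performance_profile <- function(tr, ...) {
  perf <- performance(tr, ...)
  prof <- attr(perf, "profile")
  gg <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$z, y = .data$rescaled)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "normalized axial position",
                  y = "membrane MinD / mid-cell value",
                  subtitle = sprintf("h = %.3g, w = %.3g, score = %.3g",
                                     perf$h, perf$w, perf$score))
  if (is.finite(perf$h) && is.finite(perf$w)) {
    gg <- gg + ggplot2::geom_hline(yintercept = 1 + perf$h / 2,
                                   linetype = "dashed", colour = "grey50")
  }
  gg
}

#' Heat map of a parameter-plane scan
#'
#' @param object a `min_scan` tibble from [scan_plane()]
#' @param fill column to map to fill (default `score`)
#' @param ... unused
#' @return a ggplot object
#' @method autoplot min_scan
#' @export
autoplot.min_scan <- function(object, fill = "score", ...) {
  axes <- names(object)[1:2]
  if (axes[2] %in% c("gamma")) {  # line scan: single axis
    return(ggplot2::ggplot(object,
                           ggplot2::aes(x = .data[[axes[1]]],
                                        y = .data[[fill]])) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::scale_x_log10())
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[1]]],
                                       y = .data[[axes[2]]],
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = fill) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
}

#' Tidy time series of a trajectory's dissipation channels
#'
#' @param x a `min_trajectory`
#' @param ... unused
#' @return a long tibble (`time`, `channel`, `value`) of the dissipation
#'   rates and `sigma_atp`
#' @method tidy min_trajectory
#' @export
tidy.min_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$sigma, -"time", names_to = "channel",
                      values_to = "value")
}

#' One-row summary of a trajectory
#'
#' @param x a `min_trajectory`
#' @param ... passed to [detect_oscillation()]
#' @return a one-row tibble: oscillation status, period, score, average
#'   dissipation and flux, and conservation drift
#' @method glance min_trajectory
#' @export
glance.min_trajectory <- function(x, ...) {
  osc <- detect_oscillation(x, ...)
  perf <- performance(x)
  bud <- generics::glance(period_averaged_budget(x, ...))
  tibble::tibble(
    oscillating = osc$oscillating, period = osc$period,
    amplitude = osc$amplitude, score = perf$score,
    sigma_avg = bud$sigma_tot, J_avg = bud$J_avg,
    ln_gamma = bud$ln_gamma,
    MinD_drift = diff(range(x$counts$MinD_total)) / x$params$N_D,
    MinE_drift = diff(range(x$counts$MinE_total)) / x$params$N_E)
}
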