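#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pressure and flow waveforms of a trajectory
#'
#' Aortic root, left-ventricular, and left-atrial pressures in the top
#' panel; aortic root flow (and device flow, when present) in the bottom
#' panel.
#'
#' @param object A `cv_trajectory`.
#' @param cycles Which cycles to show (default the last two).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_trajectory
#' @export
autoplot.cv_trajectory <- function(object, cycles = NULL, ...) {
  n <- attr(object, "n_cycles")
  cycles <- cycles %||% seq(max(1, n - 1), n)
  T_cyc <- 60 / attr(object, "hr")
  dat <- dplyr::filter(object, .data$time >= (min(cycles) - 1) * T_cyc,
                       .data$time <= max(cycles) * T_cyc)
  pres <- tidyr::pivot_longer(
    dplyr::select(dat, "time", "P_ao", "P_LV", "P_LA"),
    -"time", names_to = "signal", values_to = "value"
  )
  flow <- tidyr::pivot_longer(
    dplyr::select(dat, "time", "Q_AV", "Q_dev"),
    -"time", names_to = "signal", values_to = "value"
  )
  pres$panel <- "pressure (mmHg)"
  flow$panel <- "flow (mL/s)"
  ggplot2::ggplot(dplyr::bind_rows(pres, flow),
                  ggplot2::aes(.data$time, .data$value, colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the left-ventricular pressure--volume loop
#'
#' @param traj A `cv_trajectory`.
#' @param cycle Cycle index (default final).
#' @return A ggplot object.
#' @export
plot_pv_loop <- function(traj, cycle = -1) {
  cy <- trajectory_cycle(traj, cycle)
  ggplot2::ggplot(cy, ggplot2::aes(.data$V_LV, .data$P_LV)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "LV volume (mL)", y = "LV pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' One panel per metric against the sweep axis, with the actuator-off
#' baseline as a dashed reference line.
#'
#' @param object A `cv_sweep`.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_sweep
#' @export
autoplot.cv_sweep <- function(object,
                              metrics = c("peak_systolic", "co",
                                          "stroke_work", "ea",
                                          "coronary_flow", "mean_lap"),
                              ...) {
  axis <- if (attr(object, "sweep_mode") == "delay") "delay_ms" else "p_act_psi"
  base <- dplyr::filter(object, .data$baseline)
  pts <- dplyr::filter(object, !.data$baseline, !.data$failed)
  long <- tidyr::pivot_longer(
    dplyr::select(pts, dplyr::all_of(c(axis, metrics))),
    -dplyr::all_of(axis), names_to = "metric", values_to = "value"
  )
  base_long <- tidyr::pivot_longer(
    dplyr::select(base, dplyr::all_of(metrics)),
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[axis]], .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = base_long,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = if (axis == "delay_ms") "actuation delay (ms)"
                  else "actuation pressure (psi)", y = NULL) +
    ggplot2::theme_minimal()
}
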