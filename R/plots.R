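#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kymograph trace
#'
#' Tail, wavefront and PSM-length curves against time, the standard
#' position-versus-time representation of somitogenesis kinematics.
#'
#' @param object a `kymograph_trace` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.kymograph_trace <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(cols = c("tail_um", "psm_um", "front_um"),
                        names_to = "series", values_to = "position_um") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         tail_um = "tail position",
                                         psm_um = "PSM length",
                                         front_um = "wavefront position"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_h, y = .data$position_um,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (h)", y = "position / length (µm)",
                  colour = NULL)
}

#' Plot a somite boundary series
#'
#' Boundary distance from the tail end at each clock tick; under the
#' exponential field the points fall on a line of slope -tau_s * lambda/tau.
#'
#' @param object a `boundary_series` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.boundary_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$x_um)) +
    ggplot2::geom_line(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "somite index n",
                  y = "boundary distance from tail end (µm)")
}

#' Plot delta-Ct points with an optional fitted line
#'
#' @param points delta-Ct tibble from [delta_ct_table()].
#' @param fit optional `wls_fit` to overlay.
#' @param axis `"stage"` or `"time"`.
#' @return A ggplot object.
#' @export
plot_delta_ct <- function(points, fit = NULL, axis = c("stage", "time")) {
  axis <- match.arg(axis)
  xvar <- if (axis == "stage") "stage" else "time_h"
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data[[xvar]], y = .data$delta_ct)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$delta_ct - .data$sd,
                                          ymax = .data$delta_ct + .data$sd),
                             size = 0.3) +
    ggplot2::labs(x = if (axis == "stage") "somite stage" else "time (h)",
                  y = expression(delta * "Ct (cycles)"))
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                                  colour = "firebrick")
  }
  p
}

#' Plot rate observations against temperature with fitted critical laws
#'
#' Each observable's fitted line passes through zero at its critical
#' temperature.
#'
#' @param obs rate observations tibble (`observable`, `temperature_C`,
#'   `rate`, optional `sd`).
#' @param fit optional `scaling_fit` from [fit_critical_law()] to overlay.
#' @return A ggplot object.
#' @export
plot_rate_scaling <- function(obs, fit = NULL) {
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$temperature_C,
                                         y = .data$rate,
                                         colour = .data$observable))
  if ("sd" %in% names(obs) && !all(is.na(obs$sd))) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$rate - .data$sd,
                   ymax = .data$rate + .data$sd), size = 0.3)
  } else {
    p <- p + ggplot2::geom_point()
  }
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      data = fit$estimates,
      ggplot2::aes(slope = .data$slope, intercept = -.data$slope * .data$Tc,
                   colour = .data$observable))
  }
  p + ggplot2::labs(x = "temperature (°C)", y = "rate", colour = NULL)
}
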