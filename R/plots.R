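# ggplot2 views of recordings, segmentations, spectra and cohort indexes.

#' @export
autoplot.imu_recording <- function(object, channels = c("gx", "gy", "gz"),
                                   ...) {
  m <- rec_meta(object)
  tibble::as_tibble(object)[c("t", channels)] |>
    tidyr::pivot_longer(-"t", names_to = "channel") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(
      x = "time [s]", y = "angular velocity [deg/s]",
      title = sprintf("%s | %s | %s | %s", m$subject_id, m$condition,
                      m$task, m$location))
}

#' @export
autoplot.power_spectrum <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"freq", names_to = "axis", names_prefix = "psd_") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$freq, y = .data$value,
                                 colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency [Hz]", y = "PSD [(deg/s)^2/Hz]",
                  title = sprintf("total power = %.3g (deg/s)^2",
                                  attr(object, "total_power")))
}

#' Plot a speed profile with detected movement cycles
#'
#' @param v A `speed_profile`.
#' @param cs The matching `cycle_set`.
#' @return A ggplot object: the speed trace with shaded cycle spans and the
#'   per-cycle 10%-of-peak thresholds.
#' @export
plot_cycles <- function(v, cs) {
  thr <- attr(cs, "threshold_frac") %||% 0.1
  p <- ggplot2::ggplot(tibble::as_tibble(v),
                       ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "speed [deg/s]",
                  title = sprintf("%d detected cycles", nrow(cs)))
  if (nrow(cs)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(cs),
      ggplot2::aes(xmin = .data$start_t, xmax = .data$end_t,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue") +
      ggplot2::geom_segment(
        data = tibble::as_tibble(cs),
        ggplot2::aes(x = .data$start_t, xend = .data$end_t,
                     y = thr * .data$peak_speed,
                     yend = thr * .data$peak_speed),
        inherit.aes = FALSE, colour = "firebrick", linetype = 2)
  }
  p
}

#' Summary plot of cohort index values
#'
#' Mean with standard-error bars per medication state and sensor location,
#' facetted by index (free y scales), mirroring the figure layout used to
#' report the cohort contrasts.
#'
#' @param indices Tidy index tibble from [run_extract()].
#' @param task Restrict to one task (default: all present, extra facet).
#' @return A ggplot object.
#' @export
plot_index_summary <- function(indices, task = NULL) {
  d <- if (is.null(task)) indices else indices[indices$task == task, ]
  d <- d |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("task", "index", "location", "state")))) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(state = factor(.data$state, levels = STATES),
                  location = factor(.data$location,
                                    levels = SENSOR_LOCATIONS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$location, y = .data$mean,
                                  fill = .data$state)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(
      if (is.null(task)) ggplot2::vars(.data$task, .data$index)
      else ggplot2::vars(.data$index),
      scales = "free_y") +
    ggplot2::labs(x = "sensor location", y = "index value (mean ± SE)")
}
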