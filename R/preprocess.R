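# Band-specific zero-phase filtering of the gyroscope channels and
# derivation of scalar speed profiles.

# Frequency bands used by the analysis (Hz)
BANDS <- list(bradykinesia = c(1, 4), tremor = c(4, 8))

# Zero-phase Butterworth filtering with odd-reflection edge padding.
# `filt` is a signal::Arma; padding keeps filtfilt start-up transients out of
# the retained segment.
.filtfilt_padded <- function(x, filt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1L):(pad + n)]
}

.apply_gyro_filter <- function(rec, filt, band_label, order) {
  fs <- attr(rec, "sample_rate")
  n <- nrow(rec)
  min_len <- 3L * (order + 1L)
  if (n < min_len) {
    stop(sprintf("recording too short to filter: %d samples < %d", n, min_len))
  }
  pad <- as.integer(min(n - 1L, round(3 * fs)))
  out <- rec
  for (col in c("gx", "gy", "gz")) {
    out[[col]] <- .filtfilt_padded(rec[[col]], filt, pad)
  }
  attr(out, "band") <- band_label
  out
}

#' High-pass filter gyroscope channels at 1 Hz
#'
#' Removes drift and gross orientation change with a 4th-order Butterworth
#' high-pass applied forward-backward (zero phase), with odd-reflection edge
#' padding. Only the gyroscope channels are filtered.
#'
#' @param rec An `imu_recording`.
#' @param cutoff High-pass cutoff in Hz (default 1).
#' @param order Butterworth order (default 4; effective attenuation is
#'   doubled by the forward-backward pass).
#' @return The recording with filtered gyro channels, `band` attribute set to
#'   `"highpass_1hz"`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' hp <- highpass_1hz(rec)
highpass_1hz <- function(rec, cutoff = 1, order = 4) {
  fs <- attr(rec, "sample_rate")
  stopifnot("sampling rate must exceed 2 Hz" = fs > 2)
  filt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  .apply_gyro_filter(rec, filt, "highpass_1hz", order)
}

#' Band-pass filter gyroscope channels
#'
#' Isolates the symptom band: 1-4 Hz for bradykinesia, 4-8 Hz for tremor.
#' 4th-order Butterworth band-pass (two poles per edge), forward-backward.
#'
#' @param rec An `imu_recording`.
#' @param band `"bradykinesia"` (1-4 Hz) or `"tremor"` (4-8 Hz).
#' @return The recording with band-passed gyro channels; `band` attribute set.
#' @export
bandpass <- function(rec, band = c("bradykinesia", "tremor")) {
  band <- match.arg(band)
  fs <- attr(rec, "sample_rate")
  edges <- BANDS[[band]]
  stopifnot("sampling rate too low for requested band" = fs / 2 > edges[2])
  filt <- signal::butter(2, edges / (fs / 2), type = "pass")
  .apply_gyro_filter(rec, filt, band, 4L)
}

#' Scalar speed profile from a recording
#'
#' Collapses the 3-axis angular velocity into the non-negative scalar speed
#' v(t) that segmentation and the smoothness index consume. Two conventions
#' are supported: `task_axis_abs` takes the absolute angular speed of the
#' task's most informative gyroscope axis (y for finger tapping, x for
#' prono-supination); `gyro_norm` takes the Euclidean norm of all three
#' axes.
#'
#' @param rec An `imu_recording` (raw or filtered).
#' @param mode `"task_axis_abs"` or `"gyro_norm"`.
#' @return A `speed_profile`: tibble with columns `t`, `v` (deg/s, >= 0),
#'   carrying the recording metadata plus `provenance`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' v <- speed_profile(rec, "task_axis_abs")
speed_profile <- function(rec, mode = c("task_axis_abs", "gyro_norm")) {
  mode <- match.arg(mode)
  v <- if (mode == "gyro_norm") {
    sqrt(rec$gx^2 + rec$gy^2 + rec$gz^2)
  } else {
    task <- attr(rec, "task")
    if (is.null(task) || !task %in% TASKS) {
      stop("task_axis_abs mode requires a recording with a known task")
    }
    abs(rec[[paste0("g", task_axis(task))]])
  }
  structure(tibble::tibble(t = rec$t, v = v),
            class = c("speed_profile", class(tibble::tibble())),
            sample_rate = attr(rec, "sample_rate"),
            location = attr(rec, "location"),
            subject_id = attr(rec, "subject_id"),
            condition = attr(rec, "condition"),
            task = attr(rec, "task"),
            band = attr(rec, "band"),
            provenance = mode)
}

#' @export
print.speed_profile <- function(x, ...) {
  cat(sprintf("<speed_profile> %s | band: %s | %d samples\n",
              attr(x, "provenance"), attr(x, "band"), nrow(x)))
  NextMethod()
}
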