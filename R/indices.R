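# The four kinematic indexes: fatigability (slope of per-cycle peak-to-peak
# angular velocity), total spectral power, and smoothness (spectral arc
# length); total time lives with the segmentation.

#' Fatigability: slope of per-cycle peak-to-peak angular velocity
#'
#' Ordinary least squares of the peak-to-peak angular velocity on the task's
#' most relevant gyroscope axis against the progressive cycle number
#' 1..n. The slope quantifies the progressive reduction in movement
#' amplitude (negative = decrement); the intercept estimates the initial
#' amplitude.
#'
#' @param cs A `cycle_set` with peak-to-peak columns from [cycle_ptp()].
#' @param task Task name (selects the axis: y for finger tapping, x for
#'   prono-supination); defaults to the cycle set's own task metadata.
#' @param axis Optionally force a gyroscope axis (`"x"`, `"y"`, `"z"`).
#' @return A `fatigability_fit` with elements `slope` (deg/s per cycle),
#'   `intercept` (deg/s), `r_squared`, `axis`, `n_cycles`.
#' @export
#' @examples
#' cs <- tibble::tibble(cycle = 1:15, ptp_y = 200 - 4 * (0:14))
#' fit <- fatigability(cs, task = "finger_tapping")
#' fit$slope  # -4
fatigability <- function(cs, task = NULL, axis = NULL) {
  if (is.null(task)) task <- attr(cs, "task")
  if (is.null(axis)) {
    if (is.null(task)) stop("either task or axis must be supplied")
    axis <- task_axis(task)
  }
  col <- paste0("ptp_", axis)
  if (!col %in% names(cs)) {
    stop("cycle set lacks peak-to-peak values; run cycle_ptp() first")
  }
  y <- cs[[col]]
  if (length(y) < 2) stop("fatigability slope needs at least 2 cycles")
  x <- seq_along(y)
  fit <- lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
    axis = axis, n_cycles = length(y)
  ), class = "fatigability_fit")
}

#' @export
print.fatigability_fit <- function(x, ...) {
  cat(sprintf(
    "<fatigability_fit> slope m = %.4g deg/s per cycle | q = %.4g | axis %s | n = %d | r2 = %.3f\n",
    x$slope, x$intercept, x$axis, x$n_cycles, x$r_squared))
  invisible(x)
}

#' @export
tidy.fatigability_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "cycle"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.fatigability_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, axis = x$axis,
                 n_cycles = x$n_cycles)
}

# ---- power spectral density ---------------------------------------------

# Welch PSD with Hann window, one-sided density scaling: the trapezoidal
# integral over frequency approximates the signal mean square (Parseval).
.welch_psd <- function(x, fs, segment = 512L, overlap = 0.5) {
  n <- length(x)
  seg <- as.integer(min(segment, n))
  step <- max(1L, as.integer(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))  # Hann
  scale <- fs * sum(w^2)
  acc <- numeric(seg %/% 2 + 1L)
  for (s0 in starts) {
    seg_x <- x[s0:(s0 + seg - 1L)] * w
    X <- fft(seg_x)[seq_len(seg %/% 2 + 1L)]
    acc <- acc + (Mod(X)^2) / scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when seg is even)
  m <- length(psd)
  dbl <- rep(2, m); dbl[1] <- 1
  if (seg %% 2 == 0) dbl[m] <- 1
  list(freq = (seq_len(m) - 1) * fs / seg, psd = psd * dbl,
       segment = seg, n_segments = length(starts), overlap = overlap)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Total power of angular velocity
#'
#' Estimates the power spectral density of the (band-passed) angular
#' velocity and integrates it over frequency. By Parseval's theorem the
#' integral of the PSD equals the signal's mean-square content, so the index
#' summarises the overall intensity of the movement. PSD by Welch's method
#' (Hann window, segments of `min(segment, N)` samples, 50% overlap); a
#' recording shorter than one segment falls back to a single-segment
#' periodogram.
#'
#' @param rec An `imu_recording`, usually band-passed to the 1-4 Hz
#'   bradykinesia band.
#' @param axes `"task"` (default; report the task axis) or `"sum3"` (sum of
#'   the three axes' powers).
#' @param segment Welch segment length in samples (default 512, i.e. 4 s at 128 Hz: 0.25 Hz resolution, fine enough to resolve movement harmonics 1 Hz apart).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `power_spectrum`: tibble with columns `freq`, `psd_x`, `psd_y`,
#'   `psd_z` ((deg/s)^2/Hz) and attributes `total_power` (the index value,
#'   (deg/s)^2), `power_by_axis`, and method metadata.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' ps <- total_power(bandpass(highpass_1hz(rec), "bradykinesia"))
#' attr(ps, "total_power")
total_power <- function(rec, axes = c("task", "sum3"), segment = 512L,
                        overlap = 0.5) {
  axes <- match.arg(axes)
  fs <- attr(rec, "sample_rate")
  spectra <- lapply(c(x = "gx", y = "gy", z = "gz"), function(col) {
    .welch_psd(rec[[col]], fs, segment, overlap)
  })
  freq <- spectra$x$freq
  power_by_axis <- vapply(spectra, function(s) .trapz(s$freq, s$psd),
                          numeric(1))
  task <- attr(rec, "task")
  value <- if (axes == "sum3" || is.null(task) || !task %in% TASKS) {
    sum(power_by_axis)
  } else {
    power_by_axis[[task_axis(task)]]
  }
  structure(tibble::tibble(freq = freq, psd_x = spectra$x$psd,
                           psd_y = spectra$y$psd, psd_z = spectra$z$psd),
            class = c("power_spectrum", class(tibble::tibble())),
            total_power = unname(value), power_by_axis = power_by_axis,
            axes = axes, window = "hann", segment = spectra$x$segment,
            n_segments = spectra$x$n_segments, overlap = overlap,
            sample_rate = fs, task = task,
            location = attr(rec, "location"),
            subject_id = attr(rec, "subject_id"),
            condition = attr(rec, "condition"), band = attr(rec, "band"))
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> total power = %.4g (deg/s)^2 [%s axis policy] | Welch %d-sample %s, %d segment(s)\n",
    attr(x, "total_power"), attr(x, "axes"), attr(x, "segment"),
    attr(x, "window"), attr(x, "n_segments")))
  NextMethod()
}

# ---- spectral arc length -------------------------------------------------

#' Spectral arc length (SPARC) smoothness of a speed profile
#'
#' Computes the negative arc length of the normalised magnitude Fourier
#' spectrum of the speed profile v(t) over the band (0, omega_c]. The
#' spectrum is normalised by its value at zero frequency, making the measure
#' exactly invariant to amplitude scaling; omega_c is the smaller of
#' `omega_c_max` and the highest frequency at which the normalised magnitude
#' still reaches `v_bar` (above it the spectrum stays below the threshold).
#' Smoother movements have simpler spectra and hence less negative values;
#' the result is dimensionless and <= 0.
#'
#' @param v A `speed_profile` or data frame with column `v` (and `t`), or a
#'   numeric vector (then `sample_rate` is required).
#' @param omega_c_max Upper bound for the adaptive cutoff, Hz: 4 for the
#'   bradykinesia tasks, 20 for the passive rigidity movement.
#' @param v_bar Normalised magnitude threshold for the adaptive cutoff
#'   (default 0.10).
#' @param freq_res Maximum spacing of the frequency grid, Hz; the FFT is
#'   zero-padded until the resolution is at least this fine (default 0.05).
#' @param sample_rate Sampling rate in Hz (taken from `v`'s metadata when
#'   available).
#' @return The SPARC value (negative, dimensionless). Errors if the profile
#'   has zero mean magnitude (V(0) = 0).
#' @export
#' @examples
#' fs <- 128
#' t <- seq(0, 1, by = 1 / fs)
#' v <- exp(-((t - 0.5)^2) / (2 * 0.1^2))
#' sparc(v, sample_rate = fs)
sparc <- function(v, omega_c_max = 4, v_bar = 0.10, freq_res = 0.05,
                  sample_rate = NULL) {
  if (is.data.frame(v)) {
    sample_rate <- sample_rate %||% attr(v, "sample_rate") %||%
      (1 / median(diff(v$t)))
    v <- v$v
  }
  stopifnot(
    "omega_c_max must be > 0" = omega_c_max > 0,
    "v_bar must lie in (0, 1)" = v_bar > 0 && v_bar < 1,
    "sample_rate is required" = !is.null(sample_rate),
    "speed profile needs more than one sample" = length(v) > 1
  )
  nfft <- 2^ceiling(log2(max(sample_rate / freq_res, length(v), 2)))
  mag <- Mod(fft(c(v, numeric(nfft - length(v)))))[seq_len(nfft / 2 + 1)]
  if (mag[1] == 0) stop("SPARC undefined: speed profile has zero mean magnitude")
  freq <- (seq_len(nfft / 2 + 1) - 1) * sample_rate / nfft
  vhat <- mag / mag[1]

  above <- which(vhat >= v_bar)
  f_thr <- if (length(above) > 1) freq[max(above)] else freq[2]
  omega_c <- min(omega_c_max, f_thr)
  sel <- which(freq <= omega_c)
  if (length(sel) < 2) sel <- 1:2  # degenerate: first grid interval only
  f_sel <- freq[sel]
  v_sel <- vhat[sel]
  -sum(sqrt((diff(f_sel) / (f_sel[length(f_sel)] - f_sel[1]))^2 +
              diff(v_sel)^2))
}

#' Per-cycle smoothness of a segmented recording
#'
#' Applies [sparc()] to the speed profile restricted to each detected
#' movement cycle and reports the per-cycle values and their mean. For the
#' bradykinesia tasks the cutoff bound is 4 Hz; for the passive rigidity
#' movement 20 Hz. The speed profile should come from the drift-removed (1 Hz
#' high-passed) recording: no band filtering is applied because the arc
#' length's normalised spectrum is inherently low-pass.
#'
#' @param v A `speed_profile` aligned with `cs`.
#' @param cs A `cycle_set` from [detect_cycles()].
#' @param omega_c_max Cutoff bound in Hz; defaults to 4, or 20 when the
#'   profile's task metadata is `"rigidity"`.
#' @inheritParams sparc
#' @return A tibble with columns `cycle` and `sal`, with attribute
#'   `mean_sal` (mean over cycles with a defined value; undefined cycles are
#'   dropped with a warning).
#' @export
smoothness_by_cycle <- function(v, cs, omega_c_max = NULL, v_bar = 0.10,
                                freq_res = 0.05) {
  if (nrow(cs) < 1) stop("smoothness needs at least one detected cycle")
  if (is.null(omega_c_max)) {
    omega_c_max <- if (identical(attr(v, "task"), "rigidity")) 20 else 4
  }
  fs <- attr(v, "sample_rate") %||% (1 / median(diff(v$t)))
  sal <- vapply(seq_len(nrow(cs)), function(i) {
    seg <- v$v[cs$start_idx[i]:(cs$end_idx[i] - 1L)]
    tryCatch(
      sparc(seg, omega_c_max = omega_c_max, v_bar = v_bar,
            freq_res = freq_res, sample_rate = fs),
      error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(sal)) {
    warning(sprintf("%d cycle(s) with undefined SAL excluded from the mean",
                    sum(is.na(sal))), call. = FALSE)
  }
  structure(tibble::tibble(cycle = cs$cycle, sal = sal),
            class = c("smoothness_set", class(tibble::tibble())),
            mean_sal = mean(sal, na.rm = TRUE), omega_c_max = omega_c_max)
}

# ---- per-recording orchestration ----------------------------------------

#' Extract all applicable kinematic indexes from one recording
#'
#' Runs the full per-recording pipeline: drift removal (1 Hz high-pass),
#' cycle segmentation on the drift-removed task-axis speed profile, band-pass
#' to the 1-4 Hz bradykinesia band for the power index, then the remaining
#' indexes. Bradykinesia tasks
#' yield all four indexes (total time, fatigability slope, total power,
#' smoothness); the passive rigidity task is described by smoothness only,
#' computed with a 20 Hz cutoff bound on the high-passed profile.
#'
#' Peak-to-peak amplitudes (and hence fatigability) are measured on the
#' drift-removed rather than band-passed gyro signal, so that harmonics of
#' the movement are not attenuated; smoothness uses the Euclidean-norm speed
#' profile of the same signal.
#'
#' @param rec An `imu_recording`.
#' @param config A configuration list, see [default_config()]; `NULL` uses
#'   the defaults.
#' @return A tibble in long format: one row per index with columns
#'   `subject_id`, `state`, `task`, `location`, `index`, `value`, plus
#'   `n_cycles` detected. Inapplicable indexes are absent.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' extract_indices(rec)
extract_indices <- function(rec, config = NULL) {
  cfg <- if (is.null(config)) default_config() else config
  task <- attr(rec, "task")
  stage <- "preprocessing"
  res <- tryCatch({
    hp <- highpass_1hz(rec, cutoff = cfg$filters$highpass_hz,
                       order = cfg$filters$order)
    if (task == "rigidity") {
      stage <- "segmentation"
      v_seg <- speed_profile(hp, cfg$segmentation$profile)
      cs <- suppressWarnings(detect_cycles(
        v_seg, threshold_frac = cfg$segmentation$threshold_frac,
        min_gap = cfg$segmentation$min_gap,
        min_duration = cfg$segmentation$min_duration))
      if (nrow(cs) < 1) stop("no movement cycles detected")
      stage <- "smoothness"
      v_smooth <- speed_profile(hp, cfg$sparc$profile)
      sm <- suppressWarnings(smoothness_by_cycle(
        v_smooth, cs, omega_c_max = cfg$sparc$omega_c_max_rigidity,
        v_bar = cfg$sparc$v_bar, freq_res = cfg$sparc$freq_res))
      tibble::tibble(index = "smoothness", value = attr(sm, "mean_sal"),
                     n_cycles = nrow(cs))
    } else {
      bp <- bandpass(hp, "bradykinesia")
      stage <- "segmentation"
      v_seg <- speed_profile(hp, cfg$segmentation$profile)
      cs <- suppressWarnings(detect_cycles(
        v_seg, threshold_frac = cfg$segmentation$threshold_frac,
        min_gap = cfg$segmentation$min_gap,
        min_duration = cfg$segmentation$min_duration))
      if (nrow(cs) < 2) stop("fewer than two movement cycles detected")
      stage <- "indexes"
      cs <- cycle_ptp(hp, cs)
      fat <- fatigability(cs, task = task)
      ps <- total_power(bp, axes = cfg$power$axes,
                        segment = cfg$power$segment,
                        overlap = cfg$power$overlap)
      v_smooth <- speed_profile(hp, cfg$sparc$profile)
      sm <- suppressWarnings(smoothness_by_cycle(
        v_smooth, cs, omega_c_max = cfg$sparc$omega_c_max,
        v_bar = cfg$sparc$v_bar, freq_res = cfg$sparc$freq_res))
      tibble::tibble(
        index = c("total_time", "fatigability", "total_power", "smoothness"),
        value = c(total_time(cs), fat$slope, attr(ps, "total_power"),
                  attr(sm, "mean_sal")),
        n_cycles = nrow(cs))
    }
  }, error = function(e) {
    stop(sprintf("index extraction failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  tibble::tibble(
    subject_id = attr(rec, "subject_id") %||% NA_character_,
    state = attr(rec, "condition") %||% NA_character_,
    task = task, location = attr(rec, "location") %||% NA_character_,
    res)
}
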