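# Movement-cycle detection from a speed profile with a 10%-of-peak
# threshold, total task time, and per-cycle peak-to-peak angular velocity.

#' Detect movement cycles in a speed profile
#'
#' Two-pass procedure. Pass 1: provisional bursts are the runs of samples
#' where v exceeds `threshold_frac` times the global peak; bursts separated
#' by less than `min_gap` seconds are merged (a tap's opening and closing
#' phases dip through zero speed mid-cycle), and bursts shorter than
#' `min_duration` are discarded. Pass 2: each burst's boundaries are moved to
#' the nearest crossings of `threshold_frac` times that burst's own peak,
#' which realises the per-cycle threshold; expansion is limited at the speed
#' minimum between neighbouring bursts so cycles never overlap. Threshold
#' crossings are taken at the first sample at or above the threshold (no
#' sub-sample interpolation).
#'
#' @param v A `speed_profile` (non-negative), or a data frame with columns
#'   `t` and `v`.
#' @param threshold_frac Fraction of the peak used as boundary threshold,
#'   in (0, 1); default 0.10.
#' @param min_gap Bursts closer than this (seconds) are merged; default 0.15.
#' @param min_duration Bursts shorter than this (seconds) are dropped;
#'   default 0.1.
#' @param expected_count Expected number of cycles (from the task); a
#'   mismatch raises a warning, never an error. `NULL` disables the check.
#' @return A `cycle_set`: tibble with one row per cycle (`cycle`, `start_t`,
#'   `end_t`, `start_idx`, `end_idx`, `peak_speed`; indices are 1-based with
#'   half-open `[start_idx, end_idx)` sample windows) and attributes `t_a`
#'   (start of first cycle), `t_b` (end of last cycle), `expected_count`.
#'   An all-zero profile yields an empty cycle set.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' v <- speed_profile(highpass_1hz(rec))
#' cs <- detect_cycles(v)
#' nrow(cs)
detect_cycles <- function(v, threshold_frac = 0.10, min_gap = 0.15,
                          min_duration = 0.1, expected_count = NULL) {
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("threshold_frac must lie in (0, 1)")
  }
  stopifnot(all(v$v >= 0))
  if (is.null(expected_count) && !is.null(attr(v, "task")) &&
      isTRUE(attr(v, "task") %in% TASKS)) {
    expected_count <- expected_cycles(attr(v, "task"))
  }
  speed <- v$v
  tvec <- v$t
  n <- length(speed)
  fs <- attr(v, "sample_rate") %||% (1 / median(diff(tvec)))

  peak <- max(speed)
  if (peak <= 0) {
    return(.new_cycle_set(tibble::tibble(
      cycle = integer(), start_t = numeric(), end_t = numeric(),
      start_idx = integer(), end_idx = integer(), peak_speed = numeric()),
      v, expected_count, threshold_frac))
  }

  # pass 1: provisional bursts above the global threshold
  above <- speed >= threshold_frac * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bursts <- cbind(starts[r$values], ends[r$values])
  if (nrow(bursts) > 1) {
    merged <- list(bursts[1, ])
    for (i in seq(2, nrow(bursts))) {
      last <- merged[[length(merged)]]
      gap <- (bursts[i, 1] - last[2] - 1L) / fs
      if (gap < min_gap) {
        merged[[length(merged)]] <- c(last[1], bursts[i, 2])
      } else {
        merged <- c(merged, list(bursts[i, ]))
      }
    }
    bursts <- do.call(rbind, merged)
  }
  keep <- (bursts[, 2] - bursts[, 1] + 1L) / fs >= min_duration
  bursts <- bursts[keep, , drop = FALSE]

  # pass 2: refine boundaries against each burst's own 10%-of-peak level
  nb <- nrow(bursts)
  out <- vector("list", nb)
  prev_end <- 0L
  for (b in seq_len(nb)) {
    i0 <- bursts[b, 1]; i1 <- bursts[b, 2]
    local_peak <- max(speed[i0:i1])
    thr <- threshold_frac * local_peak
    # expansion limits: the speed minimum in the inter-burst valleys
    left_lim <- if (b == 1) 1L else {
      lo <- bursts[b - 1L, 2]
      lo + which.min(speed[lo:i0]) - 1L
    }
    right_lim <- if (b == nb) n else {
      hi <- bursts[b + 1L, 1]
      i1 + which.min(speed[i1:hi]) - 1L
    }
    s <- i0
    while (s > left_lim && speed[s - 1L] >= thr) s <- s - 1L
    while (s < i1 && speed[s] < thr) s <- s + 1L
    e <- i1
    while (e < right_lim && speed[e + 1L] >= thr) e <- e + 1L
    while (e > s && speed[e] < thr) e <- e - 1L
    s <- max(s, prev_end + 1L)
    prev_end <- e
    out[[b]] <- c(s, e)
  }
  bounds <- do.call(rbind, out)
  end_idx <- pmin(bounds[, 2] + 1L, n)  # half-open [start, end)
  cycles <- tibble::tibble(
    cycle = seq_len(nb),
    start_t = tvec[bounds[, 1]],
    end_t = tvec[end_idx],
    start_idx = as.integer(bounds[, 1]),
    end_idx = as.integer(end_idx),
    peak_speed = vapply(seq_len(nb), function(b) {
      max(speed[bounds[b, 1]:bounds[b, 2]])
    }, numeric(1))
  )
  if (!is.null(expected_count) && nrow(cycles) != expected_count) {
    warning(sprintf("detected %d cycles but expected %d",
                    nrow(cycles), expected_count), call. = FALSE)
  }
  .new_cycle_set(cycles, v, expected_count, threshold_frac)
}

.new_cycle_set <- function(cycles, v, expected_count, threshold_frac) {
  structure(cycles,
            class = c("cycle_set", class(tibble::tibble())),
            t_a = if (nrow(cycles)) cycles$start_t[1] else NA_real_,
            t_b = if (nrow(cycles)) cycles$end_t[nrow(cycles)] else NA_real_,
            expected_count = expected_count,
            threshold_frac = threshold_frac,
            sample_rate = attr(v, "sample_rate"),
            location = attr(v, "location"),
            subject_id = attr(v, "subject_id"),
            condition = attr(v, "condition"),
            task = attr(v, "task"),
            band = attr(v, "band"))
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles | t_a = %.3f s | t_b = %.3f s\n",
              nrow(x), attr(x, "t_a"), attr(x, "t_b")))
  NextMethod()
}

#' Total task time
#'
#' Difference between the end time of the last movement cycle and the
#' beginning of the first: the total time needed to complete the task.
#'
#' @param cs A `cycle_set` with at least one cycle.
#' @return Total time in seconds.
#' @export
#' @examples
#' cs <- tibble::tibble(cycle = 1, start_t = 0.5, end_t = 10.2,
#'                      start_idx = 1L, end_idx = 2L, peak_speed = 1)
#' total_time(cs)  # 9.7
total_time <- function(cs) {
  if (nrow(cs) < 1) stop("total time is undefined for an empty cycle set")
  t_a <- attr(cs, "t_a") %||% cs$start_t[1]
  t_b <- attr(cs, "t_b") %||% cs$end_t[nrow(cs)]
  t_b - t_a
}

#' Per-cycle peak-to-peak angular velocity
#'
#' For every detected cycle and every gyroscope axis, the difference between
#' the maximum and minimum angular velocity within the cycle's half-open
#' sample window. Feeds the fatigability regression.
#'
#' @param rec An `imu_recording` aligned with `cs` (same time grid); the
#'   drift-removed (1 Hz high-passed) recording is the usual input.
#' @param cs A `cycle_set` from [detect_cycles()].
#' @return `cs` with columns `ptp_x`, `ptp_y`, `ptp_z` (deg/s) added.
#' @export
cycle_ptp <- function(rec, cs) {
  if (nrow(cs) && max(cs$end_idx) - 1L > nrow(rec)) {
    stop("cycle indices out of range for this recording")
  }
  ptp <- function(col) {
    vapply(seq_len(nrow(cs)), function(i) {
      w <- rec[[col]][cs$start_idx[i]:(cs$end_idx[i] - 1L)]
      max(w) - min(w)
    }, numeric(1))
  }
  cs$ptp_x <- ptp("gx")
  cs$ptp_y <- ptp("gy")
  cs$ptp_z <- ptp("gz")
  cs
}
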