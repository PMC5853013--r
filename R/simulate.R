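# Synthetic-movement generator: quasi-periodic angular-velocity bursts with
# amplitude decay, arrhythmicity, submovement fragmentation, tremor and noise.

#' Simulation parameters for one synthetic recording
#'
#' Bundles and validates the knobs of the synthetic-movement generator. The
#' defaults describe a repetitive upper-limb task performed at the pace and
#' repetition count the UPDRS part III items prescribe: 15 cycles for the
#' bradykinesia tasks (finger tapping, prono-supination), 10 slow passive
#' cycles for the elbow rigidity task.
#'
#' @param task Task to simulate: `"finger_tapping"`, `"pronosupination"` or
#'   `"rigidity"`.
#' @param n_cycles Number of movement cycles (default 15; 10 for rigidity).
#' @param base_rate Cycle repetition rate in Hz (default 2 for tapping, 1.5
#'   for prono-supination, 0.5 for the passive rigidity movement).
#' @param base_amplitude Peak angular speed of the first cycle, deg/s.
#' @param decay_per_cycle Change of peak amplitude per cycle, deg/s (<= 0 for
#'   Parkinsonian decrement). Amplitude is floored at 5% of
#'   `base_amplitude`; reaching the floor before the last cycle is recorded
#'   as a metadata warning, not an error.
#' @param rate_jitter_cv Coefficient of variation of inter-cycle intervals
#'   (arrhythmicity); 0 gives a strictly periodic signal.
#' @param n_submovements Submovements per cycle (1 = smooth). A fragmented
#'   cycle is simulated as repeated partial open-close attempts separated by
#'   hesitations, which also prolong the cycle. For the rigidity task this
#'   is reused as the cogwheel severity: `n_submovements - 1` scales the
#'   depth of 7.5 Hz velocity notches instead.
#' @param submovement_interval Minimum seconds between successive submovement
#'   attempts (stretched to 0.45 of the base period at slow rates so
#'   attempts never overlap destructively).
#' @param tremor_amplitude Amplitude of an additive tremor sinusoid, deg/s.
#' @param tremor_freq Tremor frequency in Hz, within 4-8 Hz.
#' @param noise_sd Standard deviation of additive white sensor noise on each
#'   gyroscope axis, deg/s.
#' @param sample_rate Sampling rate in Hz. Must exceed twice
#'   `max(tremor_freq, 20)`.
#' @param lead_in,lead_out Seconds of rest padding before/after the task.
#' @param notch_freq Cogwheel notch frequency in Hz (rigidity only).
#' @param seed Integer seed; identical seed and parameters give identical
#'   samples.
#'
#' @return A `sim_params` list.
#' @export
#' @examples
#' p <- sim_params("finger_tapping", base_amplitude = 100, decay_per_cycle = -2)
#' rec <- simulate_recording(p)
sim_params <- function(task = c("finger_tapping", "pronosupination", "rigidity"),
                       n_cycles = NULL,
                       base_rate = NULL,
                       base_amplitude = 200,
                       decay_per_cycle = 0,
                       rate_jitter_cv = 0,
                       n_submovements = 1,
                       submovement_interval = 0.25,
                       tremor_amplitude = 0,
                       tremor_freq = 6,
                       noise_sd = 0,
                       sample_rate = 128,
                       lead_in = 0.5,
                       lead_out = 0.5,
                       notch_freq = 7.5,
                       seed = NULL) {
  task <- match.arg(task)
  if (is.null(n_cycles)) n_cycles <- expected_cycles(task)
  if (is.null(base_rate)) {
    base_rate <- switch(task, finger_tapping = 2, pronosupination = 1.5,
                        rigidity = 0.5)
  }
  stopifnot(
    "n_cycles must be >= 1" = n_cycles >= 1,
    "base_amplitude must be > 0" = base_amplitude > 0,
    "rate_jitter_cv must be >= 0" = rate_jitter_cv >= 0,
    "n_submovements must be >= 1" = n_submovements >= 1,
    "base_rate must be > 0" = base_rate > 0,
    "tremor_freq must lie in [4, 8] Hz" =
      tremor_freq >= 4 && tremor_freq <= 8,
    "sample_rate must exceed twice max(tremor_freq, 20 Hz)" =
      sample_rate > 2 * max(tremor_freq, 20),
    "noise_sd must be >= 0" = noise_sd >= 0,
    "lead_in/lead_out must be >= 0" = lead_in >= 0 && lead_out >= 0
  )
  structure(list(
    task = task, n_cycles = as.integer(n_cycles), base_rate = base_rate,
    base_amplitude = base_amplitude, decay_per_cycle = decay_per_cycle,
    rate_jitter_cv = rate_jitter_cv,
    n_submovements = as.integer(n_submovements),
    submovement_interval = submovement_interval,
    tremor_amplitude = tremor_amplitude, tremor_freq = tremor_freq,
    noise_sd = noise_sd, sample_rate = sample_rate,
    lead_in = lead_in, lead_out = lead_out, notch_freq = notch_freq,
    seed = seed
  ), class = "sim_params")
}

# Unit Gaussian pulse evaluated on the time grid, support limited to +-6 sigma
.add_pulse <- function(x, t, center, sigma, sign = 1) {
  fs_idx <- which(t >= center - 6 * sigma & t <= center + 6 * sigma)
  if (length(fs_idx)) {
    x[fs_idx] <- x[fs_idx] +
      sign * exp(-((t[fs_idx] - center)^2) / (2 * sigma^2))
  }
  x
}

# Build the deterministic task-axis angular velocity for one recording.
# Returns list(omega, t, cycle_peaks, floored_at).
.build_task_axis <- function(p) {
  n <- p$n_cycles
  T0 <- 1 / p$base_rate
  rigid <- p$task == "rigidity"
  # For rigidity n_submovements encodes cogwheel severity, not fragmentation
  n_sub <- if (rigid) 1L else p$n_submovements

  # Waveform geometry. The passive rigidity movement repeats slowly (0.5 Hz)
  # but its velocity pulses are brisker relative to the period, keeping
  # their spectral content above the 1 Hz drift high-pass.
  gap_frac <- if (rigid) 0.15 else 0.2
  sigma0 <- if (rigid) T0 / 30 else T0 / 20
  sigma <- sigma0
  # Fragmentation = repeated partial open-close attempts: hesitations both
  # prolong the cycle and keep the velocity zero-mean at the pair timescale
  # (so drift removal does not distort the rest periods). The interval
  # stretches at slow rates so successive attempts never cancel.
  itv <- max(p$submovement_interval, 0.45 * T0)
  pw <- (n_sub - 1) * itv

  jit <- if (p$rate_jitter_cv > 0) {
    pmax(0.3, 1 + rnorm(n, 0, p$rate_jitter_cv))
  } else {
    rep(1, n)
  }
  periods <- (T0 + pw) * jit
  starts <- p$lead_in + c(0, cumsum(periods[-n]))
  duration <- p$lead_in + sum(periods) + p$lead_out
  t <- seq(0, duration, by = 1 / p$sample_rate)
  floor_amp <- 0.05 * p$base_amplitude
  amps <- p$base_amplitude + (seq_len(n) - 1) * p$decay_per_cycle
  floored_at <- if (any(amps < floor_amp)) min(which(amps < floor_amp)) else NA_integer_
  amps <- pmax(amps, floor_amp)

  omega <- numeric(length(t))
  for (k in seq_len(n)) {
    open_centers <- starts[k] + 0.3 * T0 + (seq_len(n_sub) - 1) * itv
    close_centers <- open_centers + gap_frac * T0
    w <- numeric(length(t))
    for (oc in open_centers) w <- .add_pulse(w, t, oc, sigma, +1)
    for (cc in close_centers) w <- .add_pulse(w, t, cc, sigma, -1)
    win <- which(t >= starts[k] & t < starts[k] + periods[k] + 2 * sigma)
    peak <- max(abs(w[win]))
    omega <- omega + w * (amps[k] / peak)
  }

  if (rigid && p$n_submovements > 1) {
    # cogwheel: amplitude-modulated velocity notches
    depth <- min(0.2 * (p$n_submovements - 1), 0.9)
    omega <- omega * (1 - depth * 0.5 * (1 - cos(2 * pi * p$notch_freq * t)))
  }
  list(omega = omega, t = t, cycle_peaks = amps, floored_at = floored_at,
       starts = starts, periods = periods)
}

#' Simulate one synthetic IMU recording
#'
#' Generates a 6-axis inertial recording (3-axis gyroscope in deg/s, 3-axis
#' accelerometer carried as noise) for one subject, task, sensor location and
#' medication state. Each movement cycle is a symmetric open-close burst of
#' angular velocity on the task axis (y for finger tapping, x for
#' prono-supination and rigidity), built from Gaussian velocity pulses; cycle
#' k peaks at `base_amplitude + (k-1) * decay_per_cycle` exactly, so the
#' per-cycle peak-to-peak sequence is `2 *` that amplitude. Ten percent of
#' the task-axis signal leaks into the other two gyroscope axes so that
#' most-relevant-axis selection is testable.
#'
#' @param params A [sim_params()] object.
#' @param location Sensor location label stored in the metadata.
#' @param subject_id,condition Identification metadata (condition is the
#'   medication state `"OFF"`, `"ON"` or `"HS"`).
#' @return An `imu_recording`: a tibble with columns `t, gx, gy, gz, ax, ay,
#'   az` and metadata attributes (`sample_rate`, `location`, `subject_id`,
#'   `condition`, `task`, `units`, `sim_warnings`). Deterministic given
#'   `params$seed`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_params("finger_tapping", seed = 1))
#' head(rec)
simulate_recording <- function(params,
                               location = "index",
                               subject_id = "S01",
                               condition = c("OFF", "ON", "HS")) {
  stopifnot(inherits(params, "sim_params"))
  condition <- match.arg(condition)
  location <- match.arg(location, SENSOR_LOCATIONS)
  if (!is.null(params$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(params$seed)
  }

  built <- .build_task_axis(params)
  t <- built$t
  n <- length(t)
  s <- built$omega
  if (params$tremor_amplitude > 0) {
    s <- s + params$tremor_amplitude * sin(2 * pi * params$tremor_freq * t)
  }

  axis <- task_axis(params$task)
  gyro <- list(x = 0.10 * s, y = 0.10 * s, z = 0.10 * s)
  gyro[[axis]] <- s
  # z never carries the task; keep a weaker leakage there for asymmetry
  if (axis != "z") gyro$z <- 0.05 * s

  if (params$noise_sd > 0) {
    gyro <- lapply(gyro, function(g) g + rnorm(n, 0, params$noise_sd))
    accel <- replicate(3, rnorm(n, 0, 0.02), simplify = FALSE)
  } else {
    accel <- replicate(3, numeric(n), simplify = FALSE)
  }

  warnings <- character()
  if (!is.na(built$floored_at) && built$floored_at < params$n_cycles) {
    warnings <- c(warnings, sprintf(
      "amplitude floor (5%% of base) reached at cycle %d of %d",
      built$floored_at, params$n_cycles))
  }

  new_imu_recording(
    tibble::tibble(t = t, gx = gyro$x, gy = gyro$y, gz = gyro$z,
                   ax = accel[[1]], ay = accel[[2]], az = accel[[3]]),
    sample_rate = params$sample_rate, location = location,
    subject_id = subject_id, condition = condition, task = params$task,
    sim_warnings = warnings, params = params
  )
}

#' Simulate a passive elbow rigidity recording
#'
#' Slow (default 0.5 Hz) passive flexion-extension cycles with superimposed
#' cogwheel velocity notches: the task-axis velocity is amplitude-modulated
#' at `notch_freq` (default 7.5 Hz) with a depth that scales with the
#' severity encoded in `n_submovements` (1 = no notches).
#'
#' @inheritParams simulate_recording
#' @return An `imu_recording`; see [simulate_recording()].
#' @export
#' @examples
#' rec <- simulate_rigidity(sim_params("rigidity", n_submovements = 5, seed = 2))
simulate_rigidity <- function(params, location = "wrist",
                              subject_id = "S01",
                              condition = c("OFF", "ON", "HS")) {
  stopifnot(inherits(params, "sim_params"))
  if (params$task != "rigidity") {
    stop("params$task must be 'rigidity' for simulate_rigidity()")
  }
  simulate_recording(params, location = location, subject_id = subject_id,
                     condition = match.arg(condition))
}

# ---- recording container -------------------------------------------------

new_imu_recording <- function(df, sample_rate, location, subject_id,
                              condition, task, sim_warnings = character(),
                              params = NULL) {
  structure(df,
            class = c("imu_recording", class(tibble::tibble()))
            , sample_rate = sample_rate, location = location,
            subject_id = subject_id, condition = condition, task = task,
            units = list(gyro = "deg/s", accel = "m/s^2", t = "s"),
            band = "raw", sim_warnings = sim_warnings, sim_params = params)
}

#' Metadata of a recording or derived object
#'
#' @param x An `imu_recording`, `speed_profile` or `cycle_set`.
#' @return A named list with `sample_rate`, `location`, `subject_id`,
#'   `condition`, `task` and `band` (which frequency band the signal is in).
#' @export
rec_meta <- function(x) {
  list(sample_rate = attr(x, "sample_rate"), location = attr(x, "location"),
       subject_id = attr(x, "subject_id"), condition = attr(x, "condition"),
       task = attr(x, "task"), band = attr(x, "band"))
}

#' @export
print.imu_recording <- function(x, ...) {
  m <- rec_meta(x)
  cat(sprintf(
    "<imu_recording> %s | %s | %s | %s | %.0f Hz | %.1f s | band: %s\n",
    m$subject_id, m$condition, m$task, m$location, m$sample_rate,
    max(x$t), m$band))
  NextMethod()
}

# ---- cohort generator ----------------------------------------------------

#' Default per-group generator settings
#'
#' Group-level means and spreads of the simulation parameters for the three
#' cohorts. The waveform-level OFF/ON contrast is a modelling choice (no
#' quantitative waveform description exists for the clinical groups): OFF is
#' simulated with low amplitude, strong per-cycle decay, three submovements
#' per phase, marked arrhythmicity and a small 5 Hz tremor; ON is
#' intermediate; healthy subjects are high-amplitude, smooth and regular.
#'
#' @return A named list (`OFF`, `ON`, `HS`) of parameter means/sds.
#' @export
default_group_params <- function() {
  list(
    OFF = list(base_amplitude = 100, amplitude_sd = 15,
               decay_per_cycle = -3, decay_sd = 0.7,
               base_rate = 1.5, rate_sd = 0.15,
               rate_jitter_cv = 0.15, n_submovements = 3,
               tremor_amplitude = 3, rigidity_severity = 5),
    ON = list(base_amplitude = 260, amplitude_sd = 30,
              decay_per_cycle = -1.5, decay_sd = 0.5,
              base_rate = 2.0, rate_sd = 0.2,
              rate_jitter_cv = 0.08, n_submovements = 2,
              tremor_amplitude = 1, rigidity_severity = 3),
    HS = list(base_amplitude = 320, amplitude_sd = 30,
              decay_per_cycle = -0.5, decay_sd = 0.3,
              base_rate = 2.5, rate_sd = 0.2,
              rate_jitter_cv = 0.03, n_submovements = 1,
              tremor_amplitude = 0, rigidity_severity = 1)
  )
}

#' Cohort simulation specification
#'
#' Describes a simulated study: how many Parkinson's disease patients (each
#' recorded in both OFF and ON states) and healthy subjects, which tasks and
#' sensor locations, per-group generator parameter distributions, and
#' per-location amplitude scaling (distal sensors see the largest angular
#' velocities).
#'
#' @param n_pd Number of PD subjects (each contributes OFF and ON).
#' @param n_hs Number of healthy subjects.
#' @param tasks Character vector of tasks to emit.
#' @param locations Sensor locations to emit.
#' @param location_scaling Named multiplicative amplitude factors (> 0).
#' @param group_params Per-group parameter list, see [default_group_params()].
#' @param subject_amp_cv Lognormal sd of a per-subject amplitude factor
#'   shared across states (induces the within-subject pairing).
#' @param noise_sd Sensor noise sd, deg/s.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_pd = 12, n_hs = 13,
                        tasks = c("finger_tapping", "pronosupination"),
                        locations = SENSOR_LOCATIONS,
                        location_scaling = c(index = 1, thumb = 0.8,
                                             metacarpus = 0.55, wrist = 0.4,
                                             arm = 0.2),
                        group_params = default_group_params(),
                        subject_amp_cv = 0.1,
                        noise_sd = 0.5, sample_rate = 128, seed = 1L) {
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  locations <- match.arg(locations, SENSOR_LOCATIONS, several.ok = TRUE)
  stopifnot(
    "groups must be non-empty" = n_pd >= 1 && n_hs >= 1,
    "location scaling factors must be > 0" =
      all(location_scaling[locations] > 0),
    "all emitted locations need a scaling factor" =
      all(locations %in% names(location_scaling))
  )
  structure(list(
    n_pd = as.integer(n_pd), n_hs = as.integer(n_hs), tasks = tasks,
    locations = locations, location_scaling = location_scaling,
    group_params = group_params, subject_amp_cv = subject_amp_cv,
    noise_sd = noise_sd, sample_rate = sample_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a full cohort of recordings
#'
#' Emits one recording per subject x state x task x sensor location, plus the
#' ground-truth generator parameters of every recording for recovery tests.
#' PD subjects appear in both OFF and ON states (sharing a subject-level
#' amplitude factor); healthy subjects once.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per recording: identifiers (`subject_id`,
#'   `group`, `state`, `task`, `location`), the true per-recording generator
#'   parameters, and a `recording` list-column of `imu_recording` objects.
#'   Drop the `recording` column to obtain the ground-truth table.
#' @export
#' @examples
#' spec <- cohort_spec(n_pd = 2, n_hs = 2, tasks = "finger_tapping",
#'                     locations = c("index", "wrist"), seed = 7)
#' cohort <- simulate_cohort(spec)
#' nrow(cohort)  # (2 PD x 2 states + 2 HS) x 2 locations = 12
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  subjects <- dplyr::bind_rows(
    tibble::tibble(subject_id = sprintf("P%02d", seq_len(spec$n_pd)),
                   group = "PD"),
    tibble::tibble(subject_id = sprintf("H%02d", seq_len(spec$n_hs)),
                   group = "HS")
  )
  subjects$amp_factor <- exp(rnorm(nrow(subjects), 0, spec$subject_amp_cv))

  design <- subjects |>
    dplyr::mutate(state = purrr::map(.data$group, function(g) {
      if (g == "PD") c("OFF", "ON") else "HS"
    })) |>
    tidyr::unnest("state") |>
    tidyr::crossing(task = spec$tasks, location = spec$locations)

  gp <- spec$group_params
  n_rec <- nrow(design)
  draws <- purrr::map(seq_len(n_rec), function(i) {
    row <- design[i, ]
    g <- gp[[row$state]]
    rigid <- row$task == "rigidity"
    amp <- max(10, g$base_amplitude * row$amp_factor +
                 rnorm(1, 0, g$amplitude_sd))
    sc <- spec$location_scaling[[row$location]]
    # decay and tremor scale with the location amplitude factor so the
    # relative decrement and tremor-to-movement ratio are location-invariant
    list(
      base_amplitude = amp * sc,
      decay_per_cycle = if (rigid) 0 else
        sc * min(0, rnorm(1, g$decay_per_cycle, g$decay_sd)),
      base_rate = if (rigid) 0.5 else
        max(0.8, rnorm(1, g$base_rate, g$rate_sd)),
      rate_jitter_cv = g$rate_jitter_cv,
      n_submovements = if (rigid) g$rigidity_severity else g$n_submovements,
      tremor_amplitude = if (rigid) 0 else sc * g$tremor_amplitude
    )
  })
  truth <- dplyr::bind_cols(design, dplyr::bind_rows(lapply(draws, tibble::as_tibble)))
  truth$rec_seed <- sample.int(.Machine$integer.max - 1L, n_rec)

  truth$recording <- purrr::map(seq_len(n_rec), function(i) {
    row <- truth[i, ]
    p <- sim_params(
      task = row$task,
      base_rate = row$base_rate,
      base_amplitude = row$base_amplitude,
      decay_per_cycle = row$decay_per_cycle,
      rate_jitter_cv = row$rate_jitter_cv,
      n_submovements = row$n_submovements,
      tremor_amplitude = row$tremor_amplitude,
      noise_sd = spec$noise_sd,
      sample_rate = spec$sample_rate,
      seed = row$rec_seed
    )
    simulate_recording(p, location = row$location,
                       subject_id = row$subject_id, condition = row$state)
  })
  truth
}
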