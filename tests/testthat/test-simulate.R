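# Synthetic-movement generator: determinism, closed-form amplitude
# structure, fragmentation phenomenology, cohort assembly.

test_that("identical seed and parameters give identical samples", {
  p <- sim_params("finger_tapping", rate_jitter_cv = 0.1, noise_sd = 1,
                  tremor_amplitude = 5, seed = 99)
  r1 <- simulate_recording(p)
  r2 <- simulate_recording(p)
  expect_identical(r1$gy, r2$gy)
  expect_identical(r1$gx, r2$gx)
  pr <- sim_params("rigidity", n_submovements = 4, noise_sd = 0.5, seed = 7)
  expect_identical(simulate_rigidity(pr)$gx, simulate_rigidity(pr)$gx)
})

test_that("noiseless periodic recordings segment into exactly n_cycles", {
  for (task in c("finger_tapping", "pronosupination")) {
    p <- sim_params(task, seed = 1)
    v <- speed_profile(highpass_1hz(simulate_recording(p)), "task_axis_abs")
    expect_identical(nrow(detect_cycles(v)), 15L)
  }
})

test_that("per-cycle peak-to-peak follows base_amplitude + (k-1) decay", {
  p <- sim_params("finger_tapping", base_amplitude = 100,
                  decay_per_cycle = -2, seed = 1)
  rec <- simulate_recording(p)
  v <- speed_profile(rec, "task_axis_abs")
  cs <- cycle_ptp(rec, detect_cycles(v))
  # symmetric open-close burst: peak-to-peak = 2 x peak amplitude
  expect_equal(cs$ptp_y, 2 * (100 - 2 * (0:14)), tolerance = 5e-3)
  expect_equal(diff(cs$ptp_y), rep(-4, 14), tolerance = 5e-3)
  # off-axis leakage carries 10% of the task axis
  expect_equal(cs$ptp_x, 0.1 * cs$ptp_y, tolerance = 1e-10)
})

test_that("amplitude floor is a metadata warning, not an error", {
  p <- sim_params("finger_tapping", base_amplitude = 100,
                  decay_per_cycle = -10, seed = 1)
  rec <- simulate_recording(p)
  expect_true(any(grepl("floor", attr(rec, "sim_warnings"))))
  v <- speed_profile(rec, "task_axis_abs")
  floor_amps <- cycle_ptp(rec, suppressWarnings(detect_cycles(v)))
  expect_true(all(floor_amps$ptp_y > 0))
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params("finger_tapping", n_cycles = 0), "n_cycles")
  expect_error(sim_params("finger_tapping", base_amplitude = -5),
               "base_amplitude")
  expect_error(sim_params("finger_tapping", sample_rate = 30), "sample_rate")
  expect_error(sim_params("jumping"))
  expect_error(simulate_rigidity(sim_params("finger_tapping")), "rigidity")
})

test_that("fragmentation makes per-movement smoothness strictly more negative", {
  sal_mean <- vapply(c(1, 3), function(ns) {
    p <- sim_params("finger_tapping", n_submovements = ns, seed = 1)
    hp <- highpass_1hz(simulate_recording(p))
    cs <- detect_cycles(speed_profile(hp, "task_axis_abs"))
    vn <- speed_profile(hp, "gyro_norm")
    fs <- attr(vn, "sample_rate")
    # oracle-computed per-cycle SAL, averaged
    mean(vapply(seq_len(nrow(cs)), function(i) {
      sparc_oracle(vn$v[cs$start_idx[i]:(cs$end_idx[i] - 1L)], fs)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(sal_mean[2], sal_mean[1])
})

test_that("cogwheel severity degrades rigidity smoothness relative to the smooth reference", {
  ref <- {
    t <- seq(0, 2, by = 1 / FS)
    sparc(exp(-((t - 1)^2) / (2 * 0.15^2)), omega_c_max = 20,
          sample_rate = FS)
  }
  sal <- vapply(c(0, 2, 5), function(sev) {
    p <- sim_params("rigidity", n_submovements = sev + 1, seed = 2)
    hp <- highpass_1hz(simulate_rigidity(p))
    cs <- detect_cycles(speed_profile(hp, "task_axis_abs"))
    vn <- speed_profile(hp, "gyro_norm")
    attr(smoothness_by_cycle(vn, cs, omega_c_max = 20), "mean_sal")
  }, numeric(1))
  expect_identical(which.min(abs(sal - ref)), 1L)
  expect_lt(sal[3], sal[2])  # deeper cogwheel, more negative
})

test_that("a single noiseless rigidity cycle yields exactly one detected cycle", {
  p <- sim_params("rigidity", n_cycles = 1, seed = 1)
  v <- speed_profile(highpass_1hz(simulate_rigidity(p)), "task_axis_abs")
  expect_identical(nrow(suppressWarnings(detect_cycles(v))), 1L)
})

test_that("simulate_cohort emits subject x state x location recordings with reproducible truth", {
  spec <- cohort_spec(n_pd = 12, n_hs = 13, tasks = "finger_tapping",
                      seed = 5)
  co <- simulate_cohort(spec)
  expect_identical(nrow(co), 185L)  # (12 x 2 states + 13) x 5 locations
  co2 <- simulate_cohort(spec)
  expect_identical(dplyr::select(co, -"recording"),
                   dplyr::select(co2, -"recording"))
  expect_identical(co$recording[[37]]$gy, co2$recording[[37]]$gy)
  expect_error(simulate_cohort(cohort_spec(n_pd = 0)), "non-empty")
})

test_that("pipeline fatigability recovers the generator's decay ground truth", {
  gp <- default_group_params()
  gp$OFF$decay_per_cycle <- -3; gp$OFF$decay_sd <- 0.5
  gp$ON$decay_per_cycle <- -1; gp$ON$decay_sd <- 0.5
  spec <- cohort_spec(n_pd = 12, n_hs = 2, tasks = "finger_tapping",
                      locations = c("index", "wrist"), group_params = gp,
                      seed = 17)
  co <- simulate_cohort(spec)
  co <- co[co$group == "PD", ]
  idx <- dplyr::bind_rows(lapply(co$recording, extract_indices))
  fat <- idx[idx$index == "fatigability", ]
  m <- dplyr::inner_join(
    fat, co[c("subject_id", "state", "location", "decay_per_cycle")],
    by = c("subject_id", "state", "location"))
  # recovered slope tracks 2 x true decay (ptp = 2 x peak)
  expect_gt(cor(m$value, 2 * m$decay_per_cycle)^2, 0.8)
})
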