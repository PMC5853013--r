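# The four kinematic indexes: fatigability OLS, Welch total power (Parseval),
# SPARC smoothness, and the per-recording orchestration.

make_cs_ptp <- function(ptp_y) {
  tibble::tibble(cycle = seq_along(ptp_y), ptp_y = ptp_y)
}

test_that("fatigability is exact on constant and linear series", {
  fit0 <- fatigability(make_cs_ptp(rep(10, 4)), task = "finger_tapping")
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 10, tolerance = 1e-12)

  fit <- fatigability(make_cs_ptp(100 - 2 * (1:15)), task = "finger_tapping")
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$intercept, 100, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(fatigability(make_cs_ptp(5), task = "finger_tapping"),
               "2 cycles")
  expect_error(fatigability(tibble::tibble(cycle = 1:3),
                            task = "finger_tapping"), "peak-to-peak")
})

test_that("fatigability equals the normal-equations oracle on random series", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(15, 50, 12)
    fit <- fatigability(make_cs_ptp(y), task = "finger_tapping")
    o <- ols_oracle(y)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  }
  # broom-style accessors
  fit <- fatigability(make_cs_ptp(c(10, 8, 12, 6, 14)),
                      task = "finger_tapping")
  o <- ols_oracle(c(10, 8, 12, 6, 14))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "cycle"], o$slope, tolerance = 1e-10)
  expect_equal(glance(fit)$n_cycles, 5L)
})

test_that("total power satisfies Parseval on sines and is additive", {
  t <- seq(0, 30, by = 1 / FS)
  expect_equal(attr(total_power(make_recording(numeric(length(t)))),
                    "total_power"), 0)
  p1 <- attr(total_power(make_recording(sin(2 * pi * 2 * t))), "total_power")
  expect_equal(p1, 0.5, tolerance = 0.02)
  p2 <- attr(total_power(make_recording(
    sin(2 * pi * 2 * t) + 2 * sin(2 * pi * 3 * t))), "total_power")
  expect_equal(p2, 2.5, tolerance = 0.02)

  # Parseval on a band-limited stochastic signal
  set.seed(8)
  x <- bandpass(make_recording(rnorm(length(t), 0, 3)), "bradykinesia")
  ps <- total_power(x)
  expect_equal(attr(ps, "total_power"), mean(x$gy^2), tolerance = 0.02)
})

test_that("short recordings fall back to a single-segment periodogram", {
  t <- seq(0, 1, by = 1 / FS)  # shorter than one 512-sample segment
  ps <- total_power(make_recording(sin(2 * pi * 4 * t)))
  expect_identical(attr(ps, "n_segments"), 1L)
  expect_equal(attr(ps, "total_power"), 0.5, tolerance = 0.03)
})

test_that("total power is strictly increasing in movement amplitude", {
  pw <- vapply(c(50, 100, 200), function(a) {
    p <- sim_params("finger_tapping", base_amplitude = a, seed = 4)
    rec <- bandpass(highpass_1hz(simulate_recording(p)), "bradykinesia")
    attr(total_power(rec), "total_power")
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("sparc is exactly amplitude-scale invariant and matches the DFT oracle", {
  t <- seq(0, 1, by = 1 / FS)
  v <- exp(-((t - 0.5)^2) / (2 * 0.1^2))
  s <- sparc(v, omega_c_max = 20, sample_rate = FS)
  expect_equal(s, sparc(273.1 * v, omega_c_max = 20, sample_rate = FS),
               tolerance = 1e-12)
  expect_lt(abs(s - sparc_oracle(v, FS, omega_c_max = 20)), 1e-8)

  # default bradykinesia cutoff
  expect_lt(abs(sparc(v, sample_rate = FS) - sparc_oracle(v, FS)), 1e-8)
  expect_lt(s, 0)
  expect_error(sparc(numeric(100), sample_rate = FS), "zero mean")
})

test_that("adding a second submovement pulse strictly decreases sparc", {
  t <- seq(0, 2, by = 1 / FS)
  one <- exp(-((t - 0.8)^2) / (2 * 0.1^2))
  two <- one + exp(-((t - 1.05)^2) / (2 * 0.1^2))
  expect_lt(sparc(two, sample_rate = FS), sparc(one, sample_rate = FS))
  expect_lt(sparc_oracle(two, FS), sparc_oracle(one, FS))
})

test_that("sparc is invariant under time dilation with a rescaled cutoff", {
  t1 <- seq(0, 1.2, by = 1 / FS)
  t2 <- seq(0, 2.4, by = 1 / FS)
  v1 <- exp(-((t1 - 0.6)^2) / (2 * 0.05^2))
  v2 <- exp(-((t2 - 1.2)^2) / (2 * 0.1^2))  # v1 dilated by 2
  s1 <- sparc(v1, omega_c_max = 20, sample_rate = FS, freq_res = 0.005)
  s2 <- sparc(v2, omega_c_max = 10, sample_rate = FS, freq_res = 0.005)
  expect_lt(abs(s1 - s2), 1e-6)
})

test_that("per-cycle smoothness averages identical cycles consistently", {
  # ten byte-identical speed bursts: the per-cycle SAL values must agree
  v <- half_sine_profile(rep(80, 10))
  cs <- detect_cycles(v)
  sm <- smoothness_by_cycle(v, cs, omega_c_max = 4)
  expect_identical(nrow(sm), 10L)
  expect_lt(max(sm$sal) - min(sm$sal), 1e-9)
  expect_equal(attr(sm, "mean_sal"), mean(sm$sal))

  one <- smoothness_by_cycle(v, cs[1, ], omega_c_max = 4)
  expect_equal(attr(one, "mean_sal"), one$sal[1])
})

test_that("ON-like tapping is smoother than OFF-like fragmented tapping", {
  on <- extract_indices(simulate_recording(
    sim_params("finger_tapping", n_submovements = 1, seed = 5)))
  off <- extract_indices(simulate_recording(
    sim_params("finger_tapping", n_submovements = 3, seed = 5)))
  expect_gt(on$value[on$index == "smoothness"],
            off$value[off$index == "smoothness"])
})

test_that("extract_indices yields all four indexes for bradykinesia, smoothness only for rigidity", {
  idx <- extract_indices(simulate_recording(
    sim_params("finger_tapping", seed = 3)))
  expect_setequal(idx$index,
                  c("total_time", "fatigability", "total_power", "smoothness"))
  expect_true(all(is.finite(idx$value)))
  expect_gt(idx$value[idx$index == "total_time"], 0)
  expect_lt(idx$value[idx$index == "smoothness"], 0)
  expect_gt(idx$value[idx$index == "total_power"], 0)

  rig <- extract_indices(simulate_rigidity(
    sim_params("rigidity", n_submovements = 3, seed = 3)))
  expect_identical(rig$index, "smoothness")

  # stage-named structured failure
  short <- make_recording(rnorm(12))
  expect_error(extract_indices(short), "preprocessing")
})
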