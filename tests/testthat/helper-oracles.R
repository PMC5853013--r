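# Independent oracles and fixture builders shared across the test files.
# Each oracle is deliberately written from first principles (direct DFT,
# normal equations, hand sums-of-squares) so it stays independent of the
# implementation path it checks.

FS <- 128

make_recording <- function(gy, fs = FS, task = "finger_tapping",
                           gx = NULL, gz = NULL,
                           location = "index", subject = "S01",
                           condition = "OFF") {
  n <- length(gy)
  t <- (seq_len(n) - 1) / fs
  zero <- numeric(n)
  bradykin:::new_imu_recording(
    tibble::tibble(t = t, gx = gx %||% zero, gy = gy, gz = gz %||% zero,
                   ax = zero, ay = zero, az = zero),
    sample_rate = fs, location = location, subject_id = subject,
    condition = condition, task = task)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# well-separated half-sine speed bursts with known amplitudes
half_sine_profile <- function(amps, fs = FS, burst = 0.3, gap = 0.5) {
  v <- numeric(round(fs * gap))
  for (a in amps) {
    tt <- seq(0, burst, by = 1 / fs)
    v <- c(v, a * sin(pi * tt / burst), numeric(round(fs * gap)))
  }
  t <- (seq_along(v) - 1) / fs
  structure(tibble::tibble(t = t, v = v), sample_rate = fs)
}

# SPARC oracle: explicit DFT sums on the zero-padded profile, the same
# adaptive cutoff rule, and an explicit-loop arc length.
sparc_oracle <- function(v, fs, omega_c_max = 4, v_bar = 0.10,
                         freq_res = 0.05) {
  nfft <- 2^ceiling(log2(max(fs / freq_res, length(v), 2)))
  x <- c(v, numeric(nfft - length(v)))
  m <- nfft / 2 + 1
  mag <- numeric(m)
  j <- seq_along(x) - 1
  for (k in seq_len(m)) {
    ph <- -2 * pi * (k - 1) * j / nfft
    mag[k] <- Mod(sum(x * complex(real = cos(ph), imaginary = sin(ph))))
  }
  freq <- (seq_len(m) - 1) * fs / nfft
  vhat <- mag / mag[1]
  above <- which(vhat >= v_bar)
  f_thr <- if (length(above) > 1) freq[max(above)] else freq[2]
  omega_c <- min(omega_c_max, f_thr)
  sel <- which(freq <= omega_c)
  if (length(sel) < 2) sel <- 1:2
  arc <- 0
  for (i in seq(2, length(sel))) {
    df <- (freq[sel[i]] - freq[sel[i - 1]]) /
      (freq[sel[length(sel)]] - freq[sel[1]])
    dv <- vhat[sel[i]] - vhat[sel[i - 1]]
    arc <- arc + sqrt(df^2 + dv^2)
  }
  -arc
}

# OLS slope/intercept by explicit normal equations
ols_oracle <- function(y) {
  x <- seq_along(y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Two-way fully-within-subject ANOVA by hand sums of squares.
# d: subject, a, b, value (one observation per cell).
rm_anova_oracle <- function(d) {
  G <- mean(d$value)
  subjects <- unique(d$subject); A <- unique(d$a); B <- unique(d$b)
  ns <- length(subjects); na <- length(A); nb <- length(B)
  m_s <- tapply(d$value, d$subject, mean)
  m_a <- tapply(d$value, d$a, mean)
  m_b <- tapply(d$value, d$b, mean)
  m_ab <- tapply(d$value, list(d$a, d$b), mean)
  m_as <- tapply(d$value, list(d$a, d$subject), mean)
  m_bs <- tapply(d$value, list(d$b, d$subject), mean)
  ss_a <- ns * nb * sum((m_a - G)^2)
  ss_b <- ns * na * sum((m_b - G)^2)
  ss_s <- na * nb * sum((m_s - G)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + G)^2)
  ss_as <- nb * sum((m_as - outer(m_a, rep(1, ns)) -
                       outer(rep(1, na), m_s) + G)^2)
  ss_bs <- na * sum((m_bs - outer(m_b, rep(1, ns)) -
                       outer(rep(1, nb), m_s) + G)^2)
  ss_tot <- sum((d$value - G)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  f_a <- (ss_a / (na - 1)) / (ss_as / ((na - 1) * (ns - 1)))
  f_b <- (ss_b / (nb - 1)) / (ss_bs / ((nb - 1) * (ns - 1)))
  f_ab <- (ss_ab / ((na - 1) * (nb - 1))) /
    (ss_abs / ((na - 1) * (nb - 1) * (ns - 1)))
  list(F_a = f_a, F_b = f_b, F_ab = f_ab)
}

# Mixed-design ANOVA by hand: group (between), b (within), one obs per cell.
# d: subject, group, b, value; balanced within subject.
mixed_anova_oracle <- function(d) {
  G <- mean(d$value)
  nb <- length(unique(d$b))
  groups <- unique(d$group)
  subj_mean <- aggregate(value ~ subject + group, d, mean)
  group_mean <- tapply(d$value, d$group, mean)
  b_mean <- tapply(d$value, d$b, mean)
  gb_mean <- tapply(d$value, list(d$group, d$b), mean)
  n_per_group <- table(subj_mean$group)[as.character(groups)]
  N <- nrow(subj_mean)
  ss_g <- nb * sum(n_per_group * (group_mean[as.character(groups)] - G)^2)
  ss_subj_within <- nb * sum((subj_mean$value -
                                group_mean[as.character(subj_mean$group)])^2)
  ss_b <- N * sum((b_mean - G)^2)
  ss_gb <- sum(vapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    nb_g <- n_per_group[as.character(g)]
    sum(nb_g * (gb_mean[as.character(g), ] - group_mean[as.character(g)] -
                  b_mean + G)^2)
  }, numeric(1)))
  ss_tot <- sum((d$value - G)^2)
  ss_between_subj <- nb * sum((subj_mean$value - G)^2)
  ss_err_within <- ss_tot - ss_between_subj - ss_b - ss_gb
  g <- length(groups)
  f_g <- (ss_g / (g - 1)) / (ss_subj_within / (N - g))
  f_b <- (ss_b / (nb - 1)) / (ss_err_within / ((N - g) * (nb - 1)))
  f_gb <- (ss_gb / ((g - 1) * (nb - 1))) / (ss_err_within / ((N - g) * (nb - 1)))
  list(F_group = f_g, F_b = f_b, F_gb = f_gb)
}

# Long-format null cohort tables for calibration runs
null_rm_table <- function(n_sub = 12, locations = bradykin:::SENSOR_LOCATIONS) {
  d <- expand.grid(subject_id = sprintf("P%02d", seq_len(n_sub)),
                   state = c("OFF", "ON"), location = locations,
                   stringsAsFactors = FALSE)
  d$index <- "v"
  d$value <- rnorm(nrow(d))
  d
}

null_mixed_table <- function(n_pd = 12, n_hs = 13,
                             locations = bradykin:::SENSOR_LOCATIONS) {
  d <- expand.grid(subject_id = c(sprintf("P%02d", seq_len(n_pd)),
                                  sprintf("H%02d", seq_len(n_hs))),
                   location = locations, stringsAsFactors = FALSE)
  d$state <- ifelse(grepl("^P", d$subject_id), "OFF", "HS")
  d$index <- "v"
  d$value <- rnorm(nrow(d))
  d
}
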