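# Cohort statistics: Bonferroni threshold, normality screen, repeated-
# measures and mixed ANOVA against hand sums-of-squares oracles, t-tests,
# post hoc layer, UPDRS correlation.

test_that("bonferroni threshold is alpha over the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "n_comparisons")
})

test_that("shapiro screen matches an independent reference implementation", {
  # fixture drawn once with set.seed(42), rnorm(12, 10, 2); the expected W/p
  # were computed independently with scipy.stats.shapiro on these literals
  x <- c(12.741917, 8.870604, 10.726257, 11.265725, 10.808537, 9.787751,
         13.023044, 9.810682, 14.036847, 9.874572, 12.609739, 14.573291)
  d <- tibble::tibble(index = "v", task = "finger_tapping", state = "OFF",
                      location = "index", value = x)
  out <- shapiro_screen(d)
  expect_equal(out$W, 0.9396798987416637, tolerance = 1e-6)
  expect_equal(out$p_value, 0.49393623320989477, tolerance = 1e-6)
  expect_false(out$untestable)

  # heavy-tailed fixture (lognormal draw, set.seed(7)) must be flagged
  y <- c(15.559892, 0.237847, 0.434677, 0.609722, 0.311983, 0.320865,
         2.454117, 0.869057, 1.201042, 13.845686, 1.534775, 26.052198)
  d2 <- d; d2$value <- y
  expect_lt(shapiro_screen(d2)$p_value, 0.05)

  # constant and tiny cells are untestable, not errors
  d3 <- dplyr::bind_rows(
    dplyr::mutate(d, value = 7, location = "arm"),
    dplyr::mutate(d[1:2, ], location = "thumb"))
  out3 <- shapiro_screen(d3)
  expect_true(all(out3$untestable))
})

test_that("repeated-measures ANOVA matches the hand sums-of-squares oracle", {
  # 4 subjects x 2 states x 2 locations, values fixed by hand
  vals <- c(10, 12, 9, 14, 11, 13, 12, 15,   # OFF: index then wrist
            8, 9, 7, 10, 9, 11, 8, 12)       # ON: index then wrist
  d <- expand.grid(subject_id = paste0("P", 1:4),
                   location = c("index", "wrist"), state = c("OFF", "ON"),
                   stringsAsFactors = FALSE)
  d$index <- "v"; d$value <- vals
  res <- rm_anova_state_by_location(d, "v")
  o <- rm_anova_oracle(data.frame(subject = d$subject_id, a = d$state,
                                  b = d$location, value = d$value))
  expect_equal(res$statistic[res$term == "state"], o$F_a, tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "location"], o$F_b,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "state:location"], o$F_ab,
               tolerance = 1e-8)
  expect_identical(attr(res, "design"), "rm2way")

  # location-shift invariance
  d2 <- d; d2$value <- d$value + 123.4
  res2 <- rm_anova_state_by_location(d2, "v")
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-8)
  expect_equal(res2$p.value, res$p.value, tolerance = 1e-8)

  # positive rescaling invariance
  d3 <- d; d3$value <- d$value * 17
  expect_equal(rm_anova_state_by_location(d3, "v")$statistic,
               res$statistic, tolerance = 1e-8)

  expect_error(rm_anova_state_by_location(d[d$subject_id %in% paste0("P", 1:2), ], "v"),
               "3 complete subjects")
})

test_that("mixed-design ANOVA matches the oracle and detects no effect on duplicated groups", {
  set.seed(21)
  d <- expand.grid(subject_id = c(paste0("P", 1:5), paste0("H", 1:6)),
                   location = c("index", "thumb", "wrist"),
                   stringsAsFactors = FALSE)
  d$state <- ifelse(grepl("^P", d$subject_id), "OFF", "HS")
  d$index <- "v"
  d$value <- rnorm(nrow(d), mean = ifelse(d$state == "OFF", 5, 3))
  res <- mixed_anova_group_by_location(d, "v")
  o <- mixed_anova_oracle(data.frame(subject = d$subject_id, group = d$state,
                                     b = d$location, value = d$value))
  expect_equal(res$statistic[res$term == "group"], o$F_group,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "location"], o$F_b,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$term == "group:location"], o$F_gb,
               tolerance = 1e-8)
  expect_identical(unique(res$df_error),
                   c(9, 18))  # (N - g), (N - g)(b - 1)

  # one group duplicated as the other: between-group F ~ 0, p ~ 1
  base <- expand.grid(subject_id = paste0("S", 1:6),
                      location = c("index", "wrist"),
                      stringsAsFactors = FALSE)
  base$value <- rnorm(nrow(base))
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, subject_id = paste0("P", subject_id), state = "OFF"),
    dplyr::mutate(base, subject_id = paste0("H", subject_id), state = "HS"))
  dup$index <- "v"
  res_dup <- mixed_anova_group_by_location(dup, "v")
  expect_lt(res_dup$statistic[res_dup$term == "group"], 1e-10)
  expect_gt(res_dup$p.value[res_dup$term == "group"], 1 - 1e-6)

  small <- d[d$subject_id %in% c("P1", "P2", "H1", "H2", "H3"), ]
  expect_error(mixed_anova_group_by_location(small, "v"), "3 complete")
})

test_that("t-test wrappers handle degenerate cases and match the pooled-variance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t(x, x)$statistic, 0)
  expect_equal(paired_t(x, x)$p.value, 1)
  res <- paired_t(x, x + 1)  # constant nonzero difference
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))

  a <- c(5.1, 4.9, 5.0, 5.2); b <- c(6.0, 6.2, 5.9, 6.1)
  res2 <- independent_t(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res2$statistic, t_hand, tolerance = 1e-8)
  expect_equal(res2$p.value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-8)
  expect_true(independent_t(rep(1, 3), rep(1, 4))$degenerate)
})

test_that("post hoc layer flags only the location carrying the injected effect", {
  set.seed(31)
  locs <- c("index", "thumb", "metacarpus", "wrist", "arm")
  d <- expand.grid(subject_id = sprintf("P%02d", 1:12),
                   state = c("OFF", "ON"), location = locs,
                   stringsAsFactors = FALSE)
  d$index <- "v"
  d$value <- rnorm(nrow(d)) +
    ifelse(d$location == "index" & d$state == "OFF", 4, 0)
  ph <- posthoc_by_location(d, "v", comparison = c("OFF", "ON"))
  expect_equal(unique(ph$threshold), 0.01)  # alpha / 5 locations
  expect_identical(ph$location[ph$significant], "index")
})

test_that("post hoc family-wise error under the null stays controlled", {
  set.seed(1)
  fam <- 0
  for (r in 1:300) {
    d <- null_rm_table()
    ph <- posthoc_by_location(d, "v", comparison = c("OFF", "ON"))
    fam <- fam + any(ph$significant)
  }
  expect_lte(fam / 300, 0.08)  # Bonferroni bound ~0.049 + MC slack
})

test_that("r-squared against UPDRS scores follows the covariance formula", {
  expect_equal(r_squared_vs_updrs(c(1, 2, 3, 4), c(0, 1, 2, 3))$r_squared, 1)
  flagged <- r_squared_vs_updrs(c(1, 2, 3, 4), c(2, 2, 2, 2))
  expect_true(is.na(flagged$r_squared))
  expect_true(attr(flagged, "degenerate"))

  set.seed(9)
  sc <- sample(0:4, 12, replace = TRUE)
  val <- 0.7 * sc + rnorm(12, 0, 0.5)
  got <- r_squared_vs_updrs(val, sc)$r_squared
  hand <- (sum((val - mean(val)) * (sc - mean(sc))))^2 /
    (sum((val - mean(val))^2) * sum((sc - mean(sc))^2))
  expect_equal(got, hand, tolerance = 1e-10)
})

test_that("bundled UPDRS tables carry the printed clinical ratings", {
  u <- updrs_scores()
  expect_identical(nrow(u), 112L)  # 14 subjects x (2+2 brady, 4 rigidity)
  expect_true(all(u$score %in% 0:4))
  expect_identical(
    u$score[u$subject_id == "S06" & u$task == "pronosupination" &
              u$state == "OFF"], 4L)
  expect_identical(
    u$score[u$subject_id == "S09" & u$task == "rigidity" &
              u$side == "right" & u$state == "ON"], 0L)
  info <- patient_info()
  expect_identical(nrow(info), 14L)
  expect_equal(info$updrs3_off_total[info$subject_id == "S06"], 65)
})
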