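# Cohort-level statistics: normality screening, repeated-measures and
# mixed-design ANOVA over state and sensor location, Bonferroni-corrected
# post hoc t-tests, and R-squared correlation with UPDRS clinical scores.

#' Bonferroni-corrected significance threshold
#'
#' alpha divided by the number of comparisons; with alpha = 0.05 over the
#' five sensor locations this gives the 0.01 post hoc threshold.
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The per-comparison threshold alpha / n_comparisons.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 5)  # 0.01
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  alpha / n_comparisons
}

#' Shapiro-Wilk normality screen per analysis cell
#'
#' Runs the Shapiro-Wilk test on every (index, task, state, location) cell
#' of a long-format cohort table. Cells with fewer than 3 values or zero
#' variance are marked untestable. The screen is a report only: no automatic
#' branching to non-parametric tests is performed.
#'
#' @param data Long-format tibble with columns `state`, `location`, `task`,
#'   `index`, `value` (see [extract_indices()]).
#' @return A tibble with one row per cell: `n`, `W`, `p_value`, `untestable`.
#' @export
shapiro_screen <- function(data) {
  data |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("index", "task", "state", "location")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      W = if (dplyr::n() >= 3 && sd(.data$value) > 0)
        unname(shapiro.test(.data$value)$statistic) else NA_real_,
      p_value = if (dplyr::n() >= 3 && sd(.data$value) > 0)
        shapiro.test(.data$value)$p.value else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(untestable = is.na(.data$W))
}

# Extract (df, F, p) rows for named effects from a summary.aovlist; each
# effect is paired with the residual df of its own error stratum.
.aov_effects <- function(fit, effects) {
  rows <- list()
  for (stratum in summary(fit)) {
    s <- stratum[[1]]
    terms <- trimws(rownames(s))
    if (!"F value" %in% colnames(s)) next
    df_err <- s[["Df"]][terms == "Residuals"]
    if (!length(df_err)) df_err <- NA_real_
    for (j in which(terms %in% effects)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = terms[j], df = s[["Df"]][j], df_error = df_err[1],
        statistic = s[["F value"]][j], p.value = s[["Pr(>F)"]][j])
    }
  }
  out <- dplyr::bind_rows(rows)
  out[match(effects, out$term), , drop = FALSE]
}

.complete_subjects <- function(d, within) {
  expected <- prod(vapply(within, function(f) length(unique(d[[f]])), 1L))
  counts <- d |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == expected)
  dropped <- setdiff(unique(d$subject_id), counts$subject_id)
  if (length(dropped)) {
    message(sprintf("dropping %d subject(s) with incomplete cells: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  d[d$subject_id %in% counts$subject_id, , drop = FALSE]
}

#' Two-way repeated-measures ANOVA: state x sensor location
#'
#' Both factors within-subject: every PD subject contributes the index value
#' in both medication states at every sensor location. Univariate
#' repeated-measures decomposition via `aov()` with subject error strata;
#' each effect is tested against its own subject-interaction error term.
#' Degrees of freedom are reported uncorrected (no sphericity correction).
#'
#' @param data Long-format cohort tibble with columns `subject_id`, `state`,
#'   `location`, `index`, `value`.
#' @param index Which index to analyse (e.g. `"total_power"`); `NULL` if
#'   `data` is already a single index.
#' @param states The two within-subject states to compare (default OFF/ON).
#' @return A `kin_anova` object: tibble of effects (`term`, `df`,
#'   `df_error`, `statistic`, `p.value`) with design metadata attributes.
#'   Subjects with missing cells are dropped listwise (with a message);
#'   fewer than 3 complete subjects is an error.
#' @export
rm_anova_state_by_location <- function(data, index = NULL,
                                       states = c("OFF", "ON")) {
  d <- if (!is.null(index)) data[data$index == index, ] else data
  d <- d[d$state %in% states, ]
  d <- .complete_subjects(d, c("state", "location"))
  n_sub <- length(unique(d$subject_id))
  if (n_sub < 3) stop("repeated-measures ANOVA needs >= 3 complete subjects")
  d$subject_id <- factor(d$subject_id)
  d$state <- factor(d$state, levels = states)
  d$location <- factor(d$location)
  fit <- aov(value ~ state * location +
               Error(subject_id / (state * location)), data = d)
  eff <- .aov_effects(fit, c("state", "location", "state:location"))
  structure(eff, class = c("kin_anova", class(tibble::tibble())),
            design = "rm2way", index = index, n_subjects = n_sub,
            factors = c(within = "state x location"),
            correction = "none (uncorrected df)")
}

#' Mixed-design ANOVA: group (between) x sensor location (within)
#'
#' Compares a PD medication state against the healthy group: group is a
#' between-subject factor, sensor location a within-subject factor. Each
#' subject must contribute all locations; incomplete subjects are dropped
#' listwise.
#'
#' @inheritParams rm_anova_state_by_location
#' @param groups Length-2 character: the states defining the two groups,
#'   e.g. `c("OFF", "HS")` or `c("ON", "HS")`.
#' @return A `kin_anova` object with effects `group`, `location`,
#'   `group:location`. Groups with fewer than 3 subjects are an error.
#' @export
mixed_anova_group_by_location <- function(data, index = NULL,
                                          groups = c("OFF", "HS")) {
  stopifnot(length(groups) == 2)
  d <- if (!is.null(index)) data[data$index == index, ] else data
  d <- d[d$state %in% groups, ]
  d$group <- d$state
  d <- .complete_subjects(d, "location")
  sizes <- table(unique(d[c("subject_id", "group")])$group)
  if (length(sizes) < 2 || any(sizes < 3)) {
    stop("each group needs >= 3 complete subjects")
  }
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group, levels = groups)
  d$location <- factor(d$location)
  fit <- aov(value ~ group * location + Error(subject_id / location),
             data = d)
  eff <- .aov_effects(fit, c("group", "location", "group:location"))
  structure(eff, class = c("kin_anova", class(tibble::tibble())),
            design = "mixed", index = index,
            n_subjects = length(unique(d$subject_id)),
            factors = c(between = "group", within = "location"),
            correction = "none (uncorrected df)")
}

#' @export
print.kin_anova <- function(x, ...) {
  cat(sprintf("<kin_anova> %s design%s | %d subjects\n", attr(x, "design"),
              if (!is.null(attr(x, "index")))
                paste0(" | index: ", attr(x, "index")) else "",
              attr(x, "n_subjects")))
  NextMethod()
}

#' @export
tidy.kin_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.kin_anova <- function(x, ...) {
  tibble::tibble(design = attr(x, "design"),
                 index = attr(x, "index") %||% NA_character_,
                 n_subjects = attr(x, "n_subjects"),
                 correction = attr(x, "correction"))
}

#' Paired t-test (thin wrapper with degenerate-case flagging)
#'
#' @param x,y Paired observation vectors of equal length >= 2.
#' @return Tibble with `statistic`, `df`, `p.value`, `degenerate` (TRUE when
#'   the differences have zero variance, in which case the test statistics
#'   are NA).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x - y) == 0) {
    if (all(x == y)) {
      # identical vectors: no difference at all, t = 0 by continuity
      return(tibble::tibble(statistic = 0, df = length(x) - 1,
                            p.value = 1, degenerate = FALSE))
    }
    return(tibble::tibble(statistic = NA_real_, df = length(x) - 1,
                          p.value = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 degenerate = FALSE)
}

#' Independent-samples t-test (pooled variance by default)
#'
#' @param x,y Observation vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student test when `TRUE` (default);
#'   Welch otherwise.
#' @return Tibble with `statistic`, `df`, `p.value`, `degenerate`.
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    return(tibble::tibble(statistic = NA_real_,
                          df = length(x) + length(y) - 2,
                          p.value = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 degenerate = FALSE)
}

#' Per-location post hoc tests against the Bonferroni threshold
#'
#' After a significant state (or group) x location interaction, compares the
#' two states at every sensor location: paired t-tests for the within-subject
#' OFF/ON contrast, independent t-tests against the healthy group. Raw
#' p-values are compared against `bonferroni_threshold(alpha, n_locations)`.
#'
#' @inheritParams rm_anova_state_by_location
#' @param comparison Length-2 character, e.g. `c("OFF", "ON")` (paired) or
#'   `c("OFF", "HS")` (independent).
#' @param alpha Family-wise level before correction (default 0.05).
#' @param var_equal Passed to [independent_t()].
#' @return Tibble with one row per location: `estimate` (mean difference),
#'   `statistic`, `df`, `p.value`, `threshold`, `significant`.
#' @export
posthoc_by_location <- function(data, index = NULL,
                                comparison = c("OFF", "ON"), alpha = 0.05,
                                var_equal = TRUE) {
  stopifnot(length(comparison) == 2)
  d <- if (!is.null(index)) data[data$index == index, ] else data
  d <- d[d$state %in% comparison, ]
  paired <- !"HS" %in% comparison
  locations <- unique(d$location)
  thr <- bonferroni_threshold(alpha, length(locations))
  rows <- purrr::map(locations, function(loc) {
    dl <- d[d$location == loc, ]
    if (paired) {
      wide <- tidyr::pivot_wider(
        dl[c("subject_id", "state", "value")],
        names_from = "state", values_from = "value")
      wide <- wide[stats::complete.cases(wide), ]
      res <- paired_t(wide[[comparison[1]]], wide[[comparison[2]]])
      est <- mean(wide[[comparison[1]]] - wide[[comparison[2]]])
    } else {
      x <- dl$value[dl$state == comparison[1]]
      y <- dl$value[dl$state == comparison[2]]
      res <- independent_t(x, y, var_equal = var_equal)
      est <- mean(x) - mean(y)
    }
    dplyr::bind_cols(tibble::tibble(location = loc, estimate = est), res)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(threshold = thr,
                  significant = !is.na(.data$p.value) & .data$p.value < thr)
}

#' R-squared correlation between an index and UPDRS scores
#'
#' Squared Pearson correlation between per-subject kinematic index values
#' and the integer UPDRS item scores (0-4) assigned by the clinical rater.
#'
#' @param index_values Numeric vector of index values.
#' @param updrs_scores Integer vector of UPDRS item scores, same length.
#' @return A list with `r_squared` and `n`; `r_squared` is `NA` (flagged via
#'   attribute `degenerate`) when either vector has zero variance.
#' @export
#' @examples
#' r_squared_vs_updrs(c(1, 2, 3, 4), c(0, 1, 2, 3))$r_squared  # 1
r_squared_vs_updrs <- function(index_values, updrs_scores) {
  stopifnot(length(index_values) == length(updrs_scores),
            length(index_values) >= 3)
  ok <- stats::complete.cases(index_values, updrs_scores)
  x <- index_values[ok]; y <- updrs_scores[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    out <- list(r_squared = NA_real_, n = length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- list(r_squared = cor(x, y)^2, n = length(x))
  attr(out, "degenerate") <- FALSE
  out
}
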