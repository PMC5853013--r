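# End-to-end workflow: simulate a cohort to disk, extract indexes from a
# directory of recordings, and run the cohort statistics.

#' Simulate a cohort and write it to disk
#'
#' Writes one CSV + JSON-sidecar recording per subject x state x task x
#' location, a `ground_truth.csv` with the true generator parameters, and a
#' `manifest.csv` listing every file with its MD5 checksum.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", out_dir))
  }
  cohort <- simulate_cohort(spec)
  files <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    fn <- sprintf("%s_%s_%s_%s.csv", row$subject_id, row$state, row$task,
                  row$location)
    write_recording(row$recording[[1]], file.path(out_dir, fn))
    fn
  }, character(1))
  truth <- dplyr::select(cohort, -"recording")
  readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"))
  manifest <- tibble::tibble(
    file = files,
    subject_id = cohort$subject_id, state = cohort$state,
    task = cohort$task, location = cohort$location,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Extract kinematic indexes from a directory of recordings
#'
#' Applies [extract_indices()] to every recording file found in `in_dir`
#' (CSV files with a `.csv.json` sidecar). Unreadable or failing files are
#' skipped with a logged message; the run continues.
#'
#' @param in_dir Directory of recording files.
#' @param out Optional CSV path for the tidy index table.
#' @param config Configuration list, see [default_config()].
#' @return Tidy index tibble: one row per recording x index.
#' @export
run_extract <- function(in_dir, out = NULL, config = NULL) {
  all_csv <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- all_csv[file.exists(paste0(all_csv, ".json"))]
  if (!length(files)) stop(sprintf("no recordings found in '%s'", in_dir))
  rows <- purrr::map(files, function(f) {
    tryCatch(extract_indices(read_recording(f), config = config),
             error = function(e) {
               message(sprintf("skipping %s: %s", basename(f),
                               conditionMessage(e)))
               NULL
             })
  })
  res <- dplyr::bind_rows(rows)
  if (!is.null(out)) readr::write_csv(res, out)
  res
}

#' Run the cohort statistical layer
#'
#' For every bradykinesia task and index in the table: the OFF/ON two-way
#' repeated-measures ANOVA, the OFF-vs-healthy and ON-vs-healthy
#' mixed-design ANOVAs, and per-location Bonferroni-corrected post hoc
#' t-tests for each comparison. Total time is additionally compared with a
#' paired t-test (OFF vs ON) and independent t-tests (each state vs
#' healthy), after averaging over sensor locations within subject. When a
#' UPDRS table is supplied, per-location R-squared correlations between each
#' index and the matching item score are reported.
#'
#' @param indices Tidy index tibble from [run_extract()] (or a CSV path).
#' @param updrs Optional UPDRS score table as from [updrs_scores()];
#'   subject ids must match the index table (unmatched ids are an error).
#' @param config Configuration list.
#' @param out_dir Optional directory: writes `anova.csv`, `posthoc.csv`,
#'   `total_time_tests.csv`, `updrs_r_squared.csv` and a text `report.txt`
#'   star matrix (rows: effects per comparison; columns: indexes;
#'   `*` p < 0.05, `**` p < 0.01).
#' @return A list of tibbles (`anova`, `posthoc`, `total_time_tests`,
#'   `updrs_r_squared`), class `kin_stats_report`.
#' @export
run_stats <- function(indices, updrs = NULL, config = NULL,
                      out_dir = NULL) {
  cfg <- if (is.null(config)) default_config() else config
  if (is.character(indices)) {
    indices <- readr::read_csv(indices, show_col_types = FALSE)
  }
  if (!nrow(indices)) stop("empty index table")
  alpha <- cfg$stats$alpha

  comparisons <- list(c("OFF", "ON"), c("OFF", "HS"), c("ON", "HS"))
  tasks <- intersect(c("finger_tapping", "pronosupination", "rigidity"),
                     unique(indices$task))
  anova_rows <- list(); posthoc_rows <- list()
  for (tk in tasks) {
    d_task <- indices[indices$task == tk, ]
    for (ix in unique(d_task$index)) {
      for (cmp in comparisons) {
        if (!all(cmp %in% d_task$state)) next
        res <- tryCatch({
          if ("HS" %in% cmp) {
            mixed_anova_group_by_location(d_task, ix, groups = cmp)
          } else {
            rm_anova_state_by_location(d_task, ix, states = cmp)
          }
        }, error = function(e) NULL)
        if (is.null(res)) next
        lab <- paste(cmp, collapse = "/")
        anova_rows[[length(anova_rows) + 1L]] <- dplyr::mutate(
          tidy(res), task = tk, index = ix, comparison = lab,
          design = attr(res, "design"), .before = 1)
        ph <- tryCatch(
          posthoc_by_location(d_task, ix, comparison = cmp, alpha = alpha,
                              var_equal = cfg$stats$var_equal),
          error = function(e) NULL)
        if (!is.null(ph)) {
          posthoc_rows[[length(posthoc_rows) + 1L]] <- dplyr::mutate(
            ph, task = tk, index = ix, comparison = lab, .before = 1)
        }
      }
    }
  }

  # total time: subject-level t-tests (average over sensor locations)
  tt_rows <- list()
  tt <- indices[indices$index == "total_time", ]
  if (nrow(tt)) {
    tt_subj <- tt |>
      dplyr::group_by(.data$task, .data$subject_id, .data$state) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    for (tk in unique(tt_subj$task)) {
      dt <- tt_subj[tt_subj$task == tk, ]
      for (cmp in comparisons) {
        if (!all(cmp %in% dt$state)) next
        res <- if ("HS" %in% cmp) {
          independent_t(dt$value[dt$state == cmp[1]],
                        dt$value[dt$state == cmp[2]],
                        var_equal = cfg$stats$var_equal)
        } else {
          wide <- tidyr::pivot_wider(dt[dt$state %in% cmp, ],
                                     names_from = "state",
                                     values_from = "value")
          wide <- wide[stats::complete.cases(wide), ]
          paired_t(wide[[cmp[1]]], wide[[cmp[2]]])
        }
        tt_rows[[length(tt_rows) + 1L]] <- dplyr::mutate(
          res, task = tk, comparison = paste(cmp, collapse = "/"),
          .before = 1)
      }
    }
  }

  # UPDRS correlations
  cor_rows <- list()
  if (!is.null(updrs)) {
    pd_ids <- unique(indices$subject_id[indices$state != "HS"])
    unmatched <- setdiff(pd_ids, unique(updrs$subject_id))
    if (length(unmatched)) {
      stop(sprintf("subject ids missing from the UPDRS table: %s",
                   paste(unmatched, collapse = ", ")))
    }
    joined <- dplyr::inner_join(
      indices[indices$state %in% c("OFF", "ON"), ],
      updrs[c("subject_id", "task", "state", "score")],
      by = c("subject_id", "task", "state"),
      relationship = "many-to-many")
    cor_rows <- joined |>
      dplyr::group_by(.data$task, .data$index, .data$location, .data$state) |>
      dplyr::summarise(
        r_squared = if (dplyr::n() >= 3 && sd(.data$value) > 0 &&
                          sd(.data$score) > 0)
          cor(.data$value, .data$score)^2 else NA_real_,
        n = dplyr::n(), .groups = "drop")
  }

  out <- structure(list(
    anova = dplyr::bind_rows(anova_rows),
    posthoc = dplyr::bind_rows(posthoc_rows),
    total_time_tests = dplyr::bind_rows(tt_rows),
    updrs_r_squared = if (length(cor_rows)) cor_rows else tibble::tibble()
  ), class = "kin_stats_report", alpha = alpha)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out$anova, file.path(out_dir, "anova.csv"))
    readr::write_csv(out$posthoc, file.path(out_dir, "posthoc.csv"))
    readr::write_csv(out$total_time_tests,
                     file.path(out_dir, "total_time_tests.csv"))
    readr::write_csv(out$updrs_r_squared,
                     file.path(out_dir, "updrs_r_squared.csv"))
    writeLines(format_star_matrix(out), file.path(out_dir, "report.txt"))
  }
  out
}

#' Star-matrix summary of the ANOVA layer
#'
#' Text rendering of the per-task results: one row per effect and
#' comparison, one column per kinematic index; `*` marks p < 0.05 and `**`
#' p < 0.01.
#'
#' @param report A `kin_stats_report` from [run_stats()].
#' @return Character vector of report lines.
#' @export
format_star_matrix <- function(report) {
  a <- report$anova
  if (!nrow(a)) return("no ANOVA results")
  star <- function(p) ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                                                  ifelse(p < 0.05, "*", "")))
  lines <- character()
  for (tk in unique(a$task)) {
    at <- a[a$task == tk, ]
    idx <- unique(at$index)
    lines <- c(lines, sprintf("== %s ==", tk),
               paste0(formatC("effect", width = 38, flag = "-"),
                      paste(formatC(idx, width = 14), collapse = "")))
    for (cmp in unique(at$comparison)) {
      for (term in unique(at$term)) {
        row <- at[at$comparison == cmp & at$term == term, ]
        cells <- vapply(idx, function(ix) {
          p <- row$p.value[row$index == ix]
          if (length(p)) star(p[1]) else ""
        }, character(1))
        lines <- c(lines, paste0(
          formatC(sprintf("%s [%s]", term, cmp), width = 38, flag = "-"),
          paste(formatC(cells, width = 14), collapse = "")))
      }
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.kin_stats_report <- function(x, ...) {
  cat(format_star_matrix(x), sep = "\n")
  invisible(x)
}
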