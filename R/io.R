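# Recording file format (CSV + JSON sidecar), run configuration, and the
# bundled UPDRS clinical rating tables.

#' Default run configuration
#'
#' All analysis constants in one place. Defaults follow the analysis
#' protocol: 1 Hz high-pass, 1-4 Hz bradykinesia band, 10%-of-peak cycle
#' threshold, SPARC cutoff bound 4 Hz (20 Hz for the passive rigidity
#' movement) with a 10% magnitude threshold, Welch PSD with 512-sample Hann
#' segments at 50% overlap.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    filters = list(highpass_hz = 1, order = 4),
    segmentation = list(threshold_frac = 0.10, min_gap = 0.15,
                        min_duration = 0.1, profile = "task_axis_abs"),
    sparc = list(omega_c_max = 4, omega_c_max_rigidity = 20, v_bar = 0.10,
                 freq_res = 0.05, profile = "gyro_norm"),
    power = list(axes = "task", segment = 512L, overlap = 0.5),
    stats = list(alpha = 0.05, var_equal = TRUE)
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected (naming the offending key); missing keys fall
#' back to [default_config()].
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (section in names(user)) {
    if (!section %in% names(base)) {
      stop(sprintf("unknown configuration section '%s' in %s", section, path))
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(base[[section]])) {
        stop(sprintf("unknown configuration key '%s$%s' in %s",
                     section, key, path))
      }
    }
    base[[section]] <- modifyList(base[[section]], user[[section]])
  }
  base
}

#' Write a recording as CSV plus JSON sidecar
#'
#' The data file holds columns `t,gx,gy,gz,ax,ay,az` (seconds, deg/s,
#' m/s^2); the sidecar (`<path>.json`) holds sample rate, units, location,
#' subject, condition, task and provenance, so a recording round-trips
#' losslessly through [read_recording()].
#'
#' @param rec An `imu_recording`.
#' @param path CSV path to write (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec)[c("t", "gx", "gy", "gz",
                                            "ax", "ay", "az")], path)
  meta <- c(rec_meta(rec)[c("sample_rate", "location", "subject_id",
                            "condition", "task")],
            list(units = attr(rec, "units"),
                 n_samples = nrow(rec),
                 sim_warnings = as.list(attr(rec, "sim_warnings") %||%
                                          character())))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (expects `<path>.json` sidecar alongside).
#' @return An `imu_recording`.
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop(sprintf("missing sidecar %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$units)) stop(sprintf("sidecar %s lacks mandatory units", sidecar))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s lacks required columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!is.null(meta$n_samples) && nrow(df) != meta$n_samples) {
    stop(sprintf("%s: row count %d inconsistent with sidecar (%d)",
                 path, nrow(df), meta$n_samples))
  }
  new_imu_recording(df[need], sample_rate = as.numeric(meta$sample_rate),
                    location = meta$location, subject_id = meta$subject_id,
                    condition = meta$condition, task = meta$task,
                    sim_warnings = unlist(meta$sim_warnings) %||% character())
}

#' Bundled UPDRS part III clinical ratings
#'
#' Item scores (0-4) assigned by a movement-disorders expert to each of the
#' 14 PD subjects in both medication states: item 23 (finger tapping) and
#' item 25 (prono-supination) for the bradykinesia tasks, item 22 for right
#' and left elbow rigidity.
#'
#' @return A long tibble: `subject_id`, `task`, `item`, `side`, `state`,
#'   `score`.
#' @export
#' @examples
#' updrs_scores() |> head()
updrs_scores <- function() {
  path <- system.file("extdata", "updrs_item_scores.csv",
                      package = "bradykin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, col_types = "ccicci")
}

#' Bundled PD patient characteristics
#'
#' Disease duration, gender, dominant hand, most affected side, levodopa
#' equivalent daily dose and total UPDRS part III motor score (OFF state)
#' for the 14 PD subjects.
#'
#' @return A tibble, one row per subject.
#' @export
patient_info <- function() {
  path <- system.file("extdata", "patient_characteristics.csv",
                      package = "bradykin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
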