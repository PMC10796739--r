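#' Write one session to CSV with a label sidecar
#'
#' The signal file has header `t,ax,ay,az` (seconds, m/s^2); the sidecar has
#' one row per labelled segment, `start_s,end_s,task_type,role`.
#'
#' @param session A session tibble from [simulate_session()].
#' @param path Signal CSV path.
#' @param labels_path Sidecar CSV path.
#' @param fs Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path, labels_path, fs = 100) {
  readr::write_csv(session[, c("t", "ax", "ay", "az")], path)
  key <- paste(session$task_type, session$role, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1))
  parts <- strsplit(r$values, "\r", fixed = TRUE)
  readr::write_csv(tibble(
    start_s = starts / fs, end_s = ends / fs,
    task_type = map_chr(parts, 1), role = map_chr(parts, 2)
  ), labels_path)
  invisible(path)
}

#' Read a session written by [write_session_csv()]
#'
#' @param path Signal CSV path.
#' @param labels_path Sidecar CSV path.
#' @param fs Sampling rate in Hz.
#' @return A session tibble `t, ax, ay, az, task_type, role`.
#' @export
read_session_csv <- function(path, labels_path, fs = 100) {
  sig <- readr::read_csv(path, show_col_types = FALSE)
  lab <- readr::read_csv(labels_path, show_col_types = FALSE)
  n <- nrow(sig)
  task_type <- character(n)
  role <- character(n)
  for (i in seq_len(nrow(lab))) {
    idx <- (as.integer(round(lab$start_s[i] * fs)) + 1L):
      as.integer(round(lab$end_s[i] * fs))
    idx <- idx[idx >= 1 & idx <= n]
    task_type[idx] <- lab$task_type[i]
    role[idx] <- lab$role[i]
  }
  bind_cols(sig, tibble(task_type = task_type, role = role))
}

#' Write a cohort manifest as JSON
#'
#' @param cohort A [make_cohort()] tibble.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(cohort, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read an evaluation report as JSON
#'
#' The report lists the per-split metrics, their means, the per-task
#' accuracy table and the seeds used, and round-trips through
#' [read_loso_report()].
#'
#' @param loso A [run_loso()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_loso_report <- function(loso, path) {
  jsonlite::write_json(
    list(seed = loso$seed, fs = loso$fs,
         split_metrics = loso$split_metrics,
         mean_metrics = loso$mean_metrics,
         per_task = loso$per_task),
    path, dataframe = "rows", digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_loso_report
#' @export
read_loso_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$split_metrics <- as_tibble(rep$split_metrics)
  rep$mean_metrics <- as_tibble(rep$mean_metrics)
  rep$per_task <- as_tibble(rep$per_task)
  rep
}

#' Write all pipeline reports to a directory
#'
#' Emits `cohort.json`, `loso_report.json`, `group_stats.csv` (sorted by
#' absolute effect size) and `downstream_report.json`.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_manifest(pipeline$cohort, file.path(dir, "cohort.json"))
  write_loso_report(pipeline$loso, file.path(dir, "loso_report.json"))
  readr::write_csv(pipeline$group_stats, file.path(dir, "group_stats.csv"))
  jsonlite::write_json(
    list(
      classification = list(
        gdm_periods = glance(pipeline$clf_gdm),
        entire_recording = glance(pipeline$clf_entire)
      ),
      regression = list(
        gdm_periods = glance(pipeline$reg_gdm),
        entire_recording = glance(pipeline$reg_entire)
      )
    ),
    file.path(dir, "downstream_report.json"),
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Packaged reference group-summary table
#'
#' Published per-feature group summary statistics (means and SDs for 20
#' stroke survivors and 10 controls, with the printed Cohen's d) from a
#' wrist-accelerometer stroke study, used as a worked example for
#' [cohens_d_summary()] and by the acceptance checks.
#'
#' @return A tibble `feature, stroke_mean, stroke_sd, control_mean,
#'   control_sd, printed_d, n_stroke, n_control`.
#' @export
reference_group_stats <- function() {
  path <- system.file("extdata", "gdm_group_stats_reference.csv",
                      package = "gdmwear")
  readr::read_csv(path, show_col_types = FALSE)
}
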