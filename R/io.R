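#' Read a long-format adherence cohort
#'
#' Expects a CSV with header `patient_id,day,hours` (or `seconds`, or a
#' generic `value` column interpreted through `unit`). Device exports in
#' seconds are converted to hours. Days a patient has no record for within
#' `1..n_days` are intermittent days and are filled in as zero hours, so
#' every patient ends up with a complete daily grid.
#'
#' @param path CSV file path.
#' @param unit `"hours"` or `"seconds"` for the value column.
#' @param n_days length of the daily grid to complete (default 90).
#' @return a cohort tibble (`patient_id`, `day`, `hours`) sorted by patient
#'   and day.
#' @export
read_cohort <- function(path, unit = c("hours", "seconds"), n_days = 90) {
  unit <- match.arg(unit)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"patient_id" %in% names(raw) || !"day" %in% names(raw)) {
    stop("cohort CSV must have columns `patient_id` and `day`", call. = FALSE)
  }
  vcol <- intersect(c("hours", "seconds", "value"), names(raw))
  if (length(vcol) == 0) {
    stop("cohort CSV must have a `hours`, `seconds` or `value` column", call. = FALSE)
  }
  vcol <- vcol[1]
  if (vcol == "seconds") unit <- "seconds"
  value <- raw[[vcol]]
  day <- raw$day
  bad_day <- which(!is.finite(day) | day != as.integer(day) | day < 1)
  if (length(bad_day)) {
    stop("non-integer or out-of-range `day` at row(s): ",
         paste(head(bad_day, 5), collapse = ", "), call. = FALSE)
  }
  bad_val <- which(!is.finite(value) | value < 0)
  if (length(bad_val)) {
    stop("negative or missing usage value at row(s): ",
         paste(head(bad_val, 5), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(data.frame(raw$patient_id, day)))
  if (length(dup)) {
    stop(sprintf("duplicate (patient, day) pair at row %d: patient %s, day %d",
                 dup[1], raw$patient_id[dup[1]], day[dup[1]]), call. = FALSE)
  }
  hours <- if (unit == "seconds") value / 3600 else value
  obs <- tibble::tibble(patient_id = as.character(raw$patient_id),
                        day = as.integer(day), hours = hours)
  # complete the daily grid: missing days are non-attempts (zero hours)
  out <- tidyr::complete(obs,
                         patient_id = unique(obs$patient_id),
                         day = seq_len(max(n_days, max(obs$day))),
                         fill = list(hours = 0))
  dplyr::arrange(out, .data$patient_id, .data$day)
}

#' Write a cohort to long CSV
#'
#' @param data a cohort tibble (`patient_id`, `day`, `hours`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data[, c("patient_id", "day", "hours")], path, progress = FALSE)
  invisible(path)
}

#' Remove implausible usage records
#'
#' Daily records exceeding `max_hours` are treated as unreliable
#' measurements and deleted (not recoded as zeros): the day simply drops out
#' of that patient's likelihood, which the per-patient products accommodate.
#' The operation is idempotent.
#'
#' @param data a cohort tibble.
#' @param max_hours removal threshold (default 15 h).
#' @return a list with `data` (the filtered cohort) and `report` (a one-row
#'   tibble: `n_patients`, `n_obs_in`, `n_removed`, `n_obs_out`).
#' @export
preprocess <- function(data, max_hours = 15) {
  keep <- data$hours <= max_hours
  report <- tibble::tibble(
    n_patients = dplyr::n_distinct(data$patient_id),
    n_obs_in = nrow(data),
    n_removed = sum(!keep),
    n_obs_out = sum(keep)
  )
  message(sprintf("preprocess: removed %d of %d records above %.1f h",
                  report$n_removed, report$n_obs_in, max_hours))
  list(data = data[keep, , drop = FALSE], report = report)
}
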