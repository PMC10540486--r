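#' Patient follow-up records
#'
#' A patient record holds the calendar recruitment time and, if an event
#' (death/progression) occurred, the continuous time from recruitment to the
#' event. Events are only *observed* at scheduled assessments: a patient with
#' an event at 4.61 months is recorded alive at the 3-month assessment and
#' dead at the 6-month assessment. A missing `event_time` means no event
#' within the follow-up horizon. `lost_to_followup` flags patients censored
#' by loss to follow-up, who are conservatively counted as failures at the
#' landmark and never contribute predicted survival at an interim.
#'
#' @param recruit_time Numeric vector of calendar recruitment times (months,
#'   >= 0).
#' @param event_time Numeric vector of event times since recruitment (months,
#'   > 0), `NA` for no event.
#' @param id Optional identifiers; defaults to `1:n`.
#' @param lost_to_followup Logical/0-1 vector, default all `FALSE`.
#' @return A `patient_records` data frame with columns `id`, `recruit_time`,
#'   `event_time`, `lost_to_followup`.
#' @examples
#' patient_records(recruit_time = c(0, 2), event_time = c(4.61, NA))
#' @export
patient_records <- function(recruit_time, event_time = NA_real_, id = NULL,
                            lost_to_followup = FALSE) {
  n <- length(recruit_time)
  event_time <- rep_len(as.numeric(event_time), n)
  lost_to_followup <- rep_len(as.logical(lost_to_followup), n)
  if (is.null(id)) id <- seq_len(n)
  if (any(is.na(recruit_time)) || any(recruit_time < 0)) {
    stop("recruitment times must be non-negative and non-missing", call. = FALSE)
  }
  if (any(!is.na(event_time) & event_time <= 0)) {
    stop("event times must be positive (measured from recruitment)", call. = FALSE)
  }
  structure(
    data.frame(
      id = id, recruit_time = as.numeric(recruit_time),
      event_time = event_time, lost_to_followup = lost_to_followup
    ),
    class = c("patient_records", "data.frame")
  )
}

#' Worked-example patient data
#'
#' The 18-patient interim dataset used as the package's worked example: a
#' single simulated scenario-1 trial (Weibull event times, about one
#' recruit per month) frozen at the calendar month-28 interim look, at which
#' point 12 of 18 patients had survived their 3-month assessment. The same
#' data ships as a CSV fixture under `inst/extdata/worked_example_patients.csv`.
#'
#' @return A `patient_records` data frame with 18 rows.
#' @examples
#' worked_example_patients()
#' @export
worked_example_patients <- function() {
  patient_records(
    id = 1:18,
    recruit_time = c(0, 0, 1, 6, 7, 7, 8, 11, 11, 11, 20, 20, 21, 22, 22, 22, 24, 25),
    event_time = c(
      4.61, 0.66, 3.70, 13.51, 6.86, 12.94, 18.71, 8.64, 0.90,
      2.91, 5.11, 0.81, 4.85, 2.20, 15.21, 4.77, 0.81, 13.04
    )
  )
}

#' Read patient follow-up tables from delimited text
#'
#' Expects a CSV with columns `id`, `recruit_time`, `event_time` (empty for
#' no event) and optionally `lost_to_followup` (0/1). Unknown columns are
#' kept but warned about; missing required columns are an error.
#'
#' @param path Path to a CSV file.
#' @return A `patient_records` data frame (possibly with 0 rows).
#' @seealso [worked_example_patients()]
#' @export
parse_patient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "recruit_time", "event_time")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(
      sprintf(
        "patient table %s lacks required column(s): %s (need %s)",
        path, paste(missing_cols, collapse = ", "), paste(required, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  unknown <- setdiff(names(df), c(required, "lost_to_followup"))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) {
    warning(sprintf("patient table %s is empty", path), call. = FALSE)
    return(patient_records(numeric(0), numeric(0), id = character(0), lost_to_followup = logical(0)))
  }
  ev <- df$event_time
  if (is.character(ev)) ev[!nzchar(trimws(ev))] <- NA
  ev <- as.numeric(ev)
  bad <- which(is.na(df$recruit_time) | df$recruit_time < 0)
  if (length(bad)) {
    stop(sprintf(
      "row(s) %s: recruitment time missing or negative",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(!is.na(ev) & ev <= 0)
  if (length(bad)) {
    stop(sprintf(
      "row(s) %s: event time must be positive (it is measured from recruitment)",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  ltfu <- if ("lost_to_followup" %in% names(df)) df$lost_to_followup != 0 else FALSE
  patient_records(df$recruit_time, ev, id = df$id, lost_to_followup = ltfu)
}
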