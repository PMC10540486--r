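#' Discrete assessment schedule
#'
#' Defines the grid of post-baseline survival assessments. Patients are seen
#' at calendar times `spacing * 1, ..., spacing * k_star` after their own
#' recruitment; the landmark (primary) endpoint is survival at the last
#' assessment `k_star`. The default is the common oncology schedule of
#' 3-monthly scans up to 12 months.
#'
#' @param k_star Integer number of post-baseline assessments (the landmark
#'   assessment index). Must be >= 1.
#' @param spacing Calendar time between assessments, in months. Must be > 0.
#'
#' @return An object of class `assessment_schedule` with fields `k_star`,
#'   `spacing` and the derived `assessment_times`.
#' @examples
#' assessment_schedule() # 3, 6, 9, 12 months
#' @export
assessment_schedule <- function(k_star = 4L, spacing = 3) {
  if (length(k_star) != 1L || is.na(k_star) || k_star < 1 || k_star != round(k_star)) {
    stop("`k_star` must be a single integer >= 1", call. = FALSE)
  }
  if (length(spacing) != 1L || is.na(spacing) || spacing <= 0) {
    stop("`spacing` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      k_star = as.integer(k_star),
      spacing = as.numeric(spacing),
      assessment_times = as.numeric(spacing) * seq_len(k_star)
    ),
    class = "assessment_schedule"
  )
}

#' @export
print.assessment_schedule <- function(x, ...) {
  cat(sprintf(
    "Assessment schedule: k* = %d assessments every %g months (%s)\n",
    x$k_star, x$spacing, paste(x$assessment_times, collapse = ", ")
  ))
  invisible(x)
}
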