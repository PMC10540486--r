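#' Aggregate patient follow-up into an interim snapshot
#'
#' At an interim look the evaluable information is, for each assessment
#' `k`, the pair (`n_k` patients evaluated, `x_k` of them alive) plus the
#' sizes `m_{k'}` of the "pending" groups: patients last confirmed alive at
#' assessment `k'` whose later assessments have not happened yet. The group
#' `k' = 0` also contains the `n_total - recruited` patients not yet enrolled
#' (the whole second stage when the interim is taken at the end of stage 1).
#' Patients already confirmed alive at the landmark `k*` are counted in
#' `known_survivors`; observed deaths contribute to the transition counts up
#' to and including their death assessment and to no pending group.
#'
#' Assessment `k` is available for a patient iff
#' `recruit_time + spacing * k <= interim_time` (the boundary counts as
#' available) and the patient survived all earlier assessments; the outcome
#' at an available assessment `k` is alive iff `event_time > spacing * k`.
#' Patients flagged lost to follow-up contribute their completed assessments
#' to the transition counts but are conservatively excluded from pending
#' groups and from `known_survivors` (censoring treated as failure).
#'
#' @param patients A [patient_records] data frame; all recruited at or before
#'   `interim_time`.
#' @param schedule An [assessment_schedule()].
#' @param interim_time Calendar time of the interim look (months).
#' @param n_total Total planned sample size (used for the `k' = 0` group).
#' @return An `interim_snapshot` with fields `n_k`, `x_k` (length `k_star`),
#'   `m` (pending-group sizes, indices `k' = 0 .. k_star - 1`),
#'   `known_survivors`, `observed_deaths`, `n_total`, `interim_time`,
#'   `schedule`.
#' @examples
#' snap <- build_interim_snapshot(worked_example_patients(),
#'   assessment_schedule(), interim_time = 28, n_total = 38)
#' snap
#' @export
build_interim_snapshot <- function(patients, schedule, interim_time, n_total) {
  stopifnot(inherits(schedule, "assessment_schedule"))
  if (interim_time < 0 || any(patients$recruit_time < 0)) {
    stop("negative times are not allowed", call. = FALSE)
  }
  if (any(patients$recruit_time > interim_time)) {
    stop("all patients must be recruited at or before the interim time", call. = FALSE)
  }
  if (n_total < nrow(patients)) {
    stop("`n_total` cannot be smaller than the number of recruited patients", call. = FALSE)
  }
  ks <- schedule$k_star
  sp <- schedule$spacing
  if (nrow(patients) == 0L || min(patients$recruit_time) + sp > interim_time) {
    stop("no assessable data: interim time precedes every first assessment", call. = FALSE)
  }

  # available assessments: largest k with recruit + spacing*k <= interim;
  # the small tolerance keeps boundary assessments (interim exactly at
  # recruit + k*spacing) available despite floating-point rounding
  avail <- pmin(ks, floor((interim_time - patients$recruit_time) / sp + 1e-9))
  avail <- pmax(avail, 0L)
  # assessment at which death is observed (ks + 1 = never, within the grid)
  ev <- patients$event_time
  death_k <- ifelse(is.na(ev) | ev > sp * ks, ks + 1L, pmax(1L, ceiling(ev / sp)))

  n_k <- x_k <- integer(ks)
  for (k in seq_len(ks)) {
    n_k[k] <- sum(avail >= k & death_k >= k)
    x_k[k] <- sum(avail >= k & death_k > k)
  }

  alive_pending <- death_k > avail & avail < ks & !patients$lost_to_followup
  m <- vapply(0:(ks - 1L), function(kp) sum(alive_pending & avail == kp), integer(1))
  m[1] <- m[1] + (n_total - nrow(patients))
  known <- sum(avail >= ks & death_k > ks & !patients$lost_to_followup)
  deaths <- sum(avail >= death_k)

  structure(
    list(
      interim_time = interim_time, schedule = schedule, n_total = as.integer(n_total),
      n_recruited = nrow(patients),
      n_k = n_k, x_k = x_k, m = m,
      known_survivors = as.integer(known), observed_deaths = as.integer(deaths),
      n_lost = sum(patients$lost_to_followup & death_k > avail)
    ),
    class = "interim_snapshot"
  )
}

#' @export
print.interim_snapshot <- function(x, ...) {
  ks <- x$schedule$k_star
  cat(sprintf(
    "Interim snapshot at month %g (%d of %d patients recruited)\n",
    x$interim_time, x$n_recruited, x$n_total
  ))
  cat("  survivors/evaluable: ", paste(sprintf("%d/%d", x$x_k, x$n_k), collapse = "  "), "\n")
  cat(
    "  pending m_k' (k' = 0..", ks - 1, "): ", paste(x$m, collapse = ", "),
    "; confirmed landmark survivors: ", x$known_survivors,
    "; observed deaths: ", x$observed_deaths, "\n",
    sep = ""
  )
  invisible(x)
}

#' Export a snapshot as tidy data frames
#'
#' @param x An `interim_snapshot`.
#' @param ... Unused.
#' @return A data frame with one row per assessment `k` (`n_k`, `x_k`) and,
#'   as attribute `"pending"`, a data frame of pending-group sizes.
#' @export
as.data.frame.interim_snapshot <- function(x, ...) {
  out <- data.frame(k = seq_along(x$n_k), n_k = x$n_k, x_k = x$x_k)
  attr(out, "pending") <- data.frame(k_prime = seq_along(x$m) - 1L, m = x$m)
  out
}

#' Final analysis of a completed trial
#'
#' Rejects the null hypothesis iff the number of landmark survivors is
#' strictly greater than `r_final`. A patient is a landmark survivor iff
#' their event time exceeds the landmark time and they were not lost to
#' follow-up (censoring counted as failure, the conservative convention).
#'
#' @param patients Completed [patient_records] for all `n_total` patients.
#' @param schedule An [assessment_schedule()].
#' @param design A [trial_design()].
#' @param analysis_time Optional calendar time of the final analysis; if
#'   supplied, an error is raised when any patient has pending assessments
#'   (recruited too recently to have reached the landmark).
#' @return A list with `reject` (logical) and `survivors` (integer count).
#' @examples
#' final_analysis(
#'   patient_records(rep(0, 10), c(rep(NA, 5), rep(2, 5))),
#'   assessment_schedule(), scenario1_design()
#' )
#' @export
final_analysis <- function(patients, schedule, design, analysis_time = NULL) {
  stopifnot(inherits(schedule, "assessment_schedule"), inherits(design, "trial_design"))
  landmark <- schedule$spacing * schedule$k_star
  if (!is.null(analysis_time)) {
    pending <- patients$recruit_time + landmark > analysis_time + 1e-9 &
      (is.na(patients$event_time) | patients$event_time > landmark)
    if (any(pending)) {
      stop("final analysis with pending assessments: ",
        sum(pending), " patient(s) have not reached the landmark",
        call. = FALSE
      )
    }
  }
  surv <- sum(
    (is.na(patients$event_time) | patients$event_time > landmark) &
      !patients$lost_to_followup
  )
  list(reject = surv > design$r_final, survivors = as.integer(surv))
}
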