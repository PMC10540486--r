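#' Solve a Weibull survival curve through two discrete survival targets
#'
#' Finds the shape `kappa` and scale `lambda` of
#' `S(t) = exp(-(t / lambda)^kappa)` such that `S(t1) = p1` and
#' `S(t4) = p4`. Closed form:
#' `kappa = log(log(p4) / log(p1)) / log(t4 / t1)`, then the scale from
#' either constraint. The equal-rates case `p1 = p4` has no Weibull solution
#' (and `p1 = p4^(t1/t4)`... the exponential case, arises at `kappa = 1`).
#'
#' @param p1 Survival probability at the short-term time `t1`.
#' @param p4 Survival probability at the landmark time `t4`; `0 < p4 <= p1 < 1`
#'   with `p4 < p1`.
#' @param t1,t4 The two calendar times (months), `t1 < t4`.
#' @return Named numeric vector `c(shape, scale)`; the round-trip residual is
#'   checked to be below 1e-9.
#' @examples
#' solve_weibull(0.7, 0.317) # shape 0.844, scale 10.18
#' @export
solve_weibull <- function(p1, p4, t1 = 3, t4 = 12) {
  if (!(p4 > 0 && p1 < 1 && t1 < t4)) stop("need 0 < p4 <= p1 < 1 and t1 < t4", call. = FALSE)
  if (p1 < p4) stop("nesting violated: survival cannot increase over time", call. = FALSE)
  if (p1 == p4) {
    stop("p1 = p4 leaves the Weibull shape undefined; perturb the targets or use a flat hazard beyond t1",
      call. = FALSE
    )
  }
  shape <- log(log(p4) / log(p1)) / log(t4 / t1)
  scale <- t1 / (-log(p1))^(1 / shape)
  resid <- max(
    abs(exp(-(t1 / scale)^shape) - p1),
    abs(exp(-(t4 / scale)^shape) - p4)
  )
  if (resid > 1e-9) stop("Weibull solve failed the round-trip check", call. = FALSE)
  c(shape = shape, scale = scale)
}

#' Data-generating scenario for trial simulation
#'
#' Describes one cell of the simulation grid: true short-term and landmark
#' survival rates (from which the Weibull event-time law is solved), the mean
#' accrual rate of the homogeneous Poisson recruitment process, and the
#' design under evaluation. Accrual with "Poisson(`accrual_rate`) patients
#' per month" is implemented as exponential inter-arrival gaps at that rate,
#' which has the same monthly counts in distribution.
#'
#' @param p1_true,p4_true True survival probabilities at the first assessment
#'   and at the landmark (`p4_true <= p1_true`).
#' @param accrual_rate Mean number of patients recruited per month (> 0).
#' @param design A [trial_design()].
#' @param schedule An [assessment_schedule()]; its first assessment and
#'   landmark times anchor the Weibull solve.
#' @return A `scenario_spec` carrying the solved `weibull` parameters.
#' @examples
#' scenario_spec(0.7, 0.317, accrual_rate = 1, design = scenario1_design())
#' @export
scenario_spec <- function(p1_true, p4_true, accrual_rate, design,
                          schedule = assessment_schedule()) {
  stopifnot(inherits(design, "trial_design"), inherits(schedule, "assessment_schedule"))
  if (accrual_rate <= 0) stop("`accrual_rate` must be positive", call. = FALSE)
  wb <- solve_weibull(
    p1_true, p4_true,
    t1 = schedule$assessment_times[1],
    t4 = schedule$assessment_times[schedule$k_star]
  )
  structure(
    list(
      p1_true = p1_true, p4_true = p4_true, accrual_rate = accrual_rate,
      weibull = wb, design = design, schedule = schedule
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: true rates %.3g (month %g) / %.3g (month %g); Weibull(shape %.4g, scale %.4g); accrual %g/month\n",
    x$p1_true, x$schedule$assessment_times[1],
    x$p4_true, x$schedule$assessment_times[x$schedule$k_star],
    x$weibull["shape"], x$weibull["scale"], x$accrual_rate
  ))
  invisible(x)
}

# interim snapshot of stage 1 from raw vectors, bypassing data-frame overhead
sim_snapshot <- function(arr, ev, interim_time, ks, sp, n_total) {
  # boundary tolerance as in build_interim_snapshot: the interim sits exactly
  # at (last stage-1 recruitment + spacing), which floating point may round
  # just below the assessment boundary
  avail <- pmin(ks, floor((interim_time - arr) / sp + 1e-9))
  death_k <- ifelse(ev > sp * ks, ks + 1, pmax(1, ceiling(ev / sp)))
  n_k <- x_k <- integer(ks)
  for (k in seq_len(ks)) {
    n_k[k] <- sum(avail >= k & death_k >= k)
    x_k[k] <- sum(avail >= k & death_k > k)
  }
  alive_pending <- death_k > avail & avail < ks
  m <- vapply(0:(ks - 1), function(kp) sum(alive_pending & avail == kp), integer(1))
  m[1] <- m[1] + (n_total - length(arr))
  structure(
    list(
      interim_time = interim_time,
      schedule = structure(list(k_star = ks, spacing = sp), class = "assessment_schedule"),
      n_total = n_total, n_recruited = length(arr), n_k = n_k, x_k = x_k, m = m,
      known_survivors = sum(avail >= ks & death_k > ks),
      observed_deaths = sum(avail >= death_k), n_lost = 0L
    ),
    class = "interim_snapshot"
  )
}

#' Simulate two-stage trials under a scenario
#'
#' Generates `n_replicates` patient-level trials: recruitment by a
#' homogeneous Poisson process, i.i.d. Weibull event times, an interim look
#' once all `n_stage1` patients have an observed first assessment (for the
#' Simon-type rule, once they all have an observed landmark assessment), the
#' method's continuation decision, and — to support cutoff calibration and
#' paired comparisons — the final analysis the trial *would* reach had it
#' continued. Recruitment pauses between the last stage-1 enrollment and the
#' interim decision; on continuation it resumes at the interim time.
#'
#' The conditional-power statistic is computed by the exact binomial
#' convolution ([conditional_power_exact()]) with the design's alternative
#' landmark rate as plug-in; the PoS statistic by [probability_of_success()]
#' with `n_draws_pos` predictive iterations (slower).
#'
#' @param scenario A [scenario_spec()].
#' @param method One of `"simon"`, `"kunz"`, `"ste_cp"`, `"ste_pos"`. Must
#'   match the design's continuation rule, except that `cutoff_override`
#'   allows evaluating STE methods on a design searched for the Kunz rule.
#' @param n_replicates Number of simulated trials.
#' @param seed Integer seed; the patient streams depend only on the seed and
#'   the scenario, so different methods run on identical data (common random
#'   numbers).
#' @param cutoff_override Continuation cutoff for the STE methods, when not
#'   carried by the design's rule. `NULL` together with a non-STE rule on an
#'   STE method is an error (uncalibrated cutoff).
#' @param s1_override,r1_override Interim thresholds for `"kunz"`/`"simon"`
#'   when the design's rule is of a different type.
#' @param n_draws_pos,grid_size_pos PoS controls (only for `"ste_pos"`).
#' @return A data frame with one row per replicate: `statistic`,
#'   `stopped_early`, `would_reject` (final test had it continued),
#'   `rejected` (binding rule: continued and rejected), `n_used`, `duration`
#'   (months), `short_term_survivors`.
#' @export
simulate_trials <- function(scenario, method = c("kunz", "simon", "ste_cp", "ste_pos"),
                            n_replicates = 1000, seed = NULL,
                            cutoff_override = NULL,
                            s1_override = NULL, r1_override = NULL,
                            n_draws_pos = 1000, grid_size_pos = 1024) {
  stopifnot(inherits(scenario, "scenario_spec"))
  method <- match.arg(method)
  des <- scenario$design
  ks <- scenario$schedule$k_star
  sp <- scenario$schedule$spacing
  landmark <- sp * ks
  n1 <- des$n_stage1
  n <- des$n_total
  rule <- des$continuation

  cutoff <- cutoff_override
  if (method %in% c("ste_cp", "ste_pos") && is.null(cutoff)) {
    if (rule$method == method) cutoff <- rule$cutoff
    if (is.null(cutoff)) {
      stop("no calibrated cutoff available for method ", method,
        "; supply `cutoff_override` or a matching continuation rule",
        call. = FALSE
      )
    }
  }
  s1 <- if (!is.null(s1_override)) s1_override else if (rule$method == "kunz") rule$s1 else NULL
  r1 <- if (!is.null(r1_override)) r1_override else if (rule$method == "simon") rule$r1 else NULL
  if (method == "kunz" && is.null(s1)) stop("kunz method needs `s1`", call. = FALSE)
  if (method == "simon" && is.null(r1)) stop("simon method needs `r1`", call. = FALSE)

  prior <- if (method == "ste_pos") {
    if (rule$method == "ste_pos") {
      transition_prior(ks, rule$prior_alpha, rule$prior_rate)
    } else {
      transition_prior(ks, alpha_from_prior_mean(des$p_lte_alt))
    }
  }

  if (!is.null(seed)) set.seed(seed)
  gaps <- matrix(stats::rexp(n_replicates * n, rate = scenario$accrual_rate), n_replicates, n)
  events <- matrix(
    stats::rweibull(n_replicates * n,
      shape = scenario$weibull["shape"],
      scale = scenario$weibull["scale"]
    ),
    n_replicates, n
  )

  statistic <- numeric(n_replicates)
  stopped <- logical(n_replicates)
  would_reject <- logical(n_replicates)
  duration <- numeric(n_replicates)
  st_surv <- integer(n_replicates)

  interim_lag <- if (method == "simon") landmark else sp

  for (i in seq_len(n_replicates)) {
    arr1 <- cumsum(gaps[i, seq_len(n1)])
    ev1 <- events[i, seq_len(n1)]
    t_int <- arr1[n1] + interim_lag
    snap <- sim_snapshot(arr1, ev1, t_int, ks, sp, n)
    st_surv[i] <- snap$x_k[1]

    stat <- switch(method,
      kunz = snap$x_k[1],
      simon = snap$x_k[ks],
      ste_cp = {
        est <- conditional_mles(snap, plug_in_rate = des$p_lte_alt)
        conditional_power_exact(snap, est, des$r_final)
      },
      ste_pos = as.numeric(probability_of_success(
        snap, prior, des$r_final,
        n_draws = n_draws_pos, grid_size = grid_size_pos
      ))
    )
    statistic[i] <- stat
    go <- switch(method,
      kunz = stat > s1,
      simon = stat > r1,
      stat > cutoff
    )
    stopped[i] <- !go

    survivors_all <- sum(events[i, ] > landmark)
    would_reject[i] <- survivors_all > des$r_final

    if (go) {
      arr2 <- t_int + cumsum(gaps[i, (n1 + 1L):n])
      duration[i] <- arr2[n - n1] + landmark
    } else {
      duration[i] <- t_int
    }
  }

  data.frame(
    statistic = statistic,
    stopped_early = stopped,
    would_reject = would_reject,
    rejected = !stopped & would_reject,
    n_used = ifelse(stopped, n1, n),
    duration = duration,
    short_term_survivors = st_surv
  )
}

#' Operating characteristics of a design under a scenario
#'
#' Summarizes [simulate_trials()] output into the probability of early
#' termination, the rejection rate (type I error when the scenario's true
#' rates satisfy the null, power otherwise), the expected sample size and the
#' mean trial duration, each with its Monte Carlo standard error.
#'
#' @inheritParams simulate_trials
#' @param ... Passed on to [simulate_trials()].
#' @return A one-row `data.frame` of class `trial_oc`.
#' @export
estimate_oc <- function(scenario, method, n_replicates = 1000, seed = NULL, ...) {
  if (n_replicates < 100) stop("`n_replicates` must be at least 100", call. = FALSE)
  sim <- simulate_trials(scenario, method, n_replicates, seed = seed, ...)
  prop_se <- function(p) sqrt(p * (1 - p) / n_replicates)
  out <- data.frame(
    method = method,
    p1_true = scenario$p1_true, p4_true = scenario$p4_true,
    accrual_rate = scenario$accrual_rate,
    n_replicates = n_replicates,
    pet = mean(sim$stopped_early),
    reject_rate = mean(sim$rejected),
    expected_n = mean(sim$n_used),
    duration = mean(sim$duration),
    pet_se = prop_se(mean(sim$stopped_early)),
    reject_rate_se = prop_se(mean(sim$rejected)),
    expected_n_se = stats::sd(sim$n_used) / sqrt(n_replicates),
    duration_se = stats::sd(sim$duration) / sqrt(n_replicates)
  )
  class(out) <- c("trial_oc", "data.frame")
  out
}

#' Calibrate an STE futility cutoff to a type I error target
#'
#' Simulates trials under the null scenario, records every trial's interim
#' statistic together with the rejection status it would reach had it
#' continued, and returns the smallest cutoff on a grid such that the
#' binding-rule type I error — the fraction of trials with
#' `statistic > cutoff` *and* final rejection — is at most `alpha_target`
#' ("just below" the limit).
#'
#' @param null_scenario A [scenario_spec()] at the null rates (for the
#'   reference calibration: the design's hypothesized null short-term and
#'   landmark rates).
#' @param method `"ste_cp"` or `"ste_pos"`.
#' @param alpha_target Type I error limit in (0, 1\].
#' @param n_replicates Number of null trials simulated.
#' @param seed Integer seed.
#' @param grid_step Cutoff grid resolution (default 0.001).
#' @param ... Passed to [simulate_trials()] (e.g. `n_draws_pos`).
#' @return The calibrated cutoff, with the attained type I error and the
#'   Monte Carlo standard error as attributes `"type1"` and `"type1_se"`.
#' @export
calibrate_cutoff <- function(null_scenario, method = c("ste_cp", "ste_pos"),
                             alpha_target = 0.10, n_replicates = 10000,
                             seed = NULL, grid_step = 0.001, ...) {
  method <- match.arg(method)
  if (alpha_target <= 0 || alpha_target > 1) {
    stop("`alpha_target` must be in (0, 1]", call. = FALSE)
  }
  sim <- simulate_trials(null_scenario, method, n_replicates,
    seed = seed,
    cutoff_override = 0, # stopping not applied during calibration
    ...
  )
  grid <- seq(0, 1, by = grid_step)
  for (cu in grid) {
    t1 <- mean(sim$statistic > cu & sim$would_reject)
    if (t1 <= alpha_target) {
      attr(cu, "type1") <- t1
      attr(cu, "type1_se") <- sqrt(t1 * (1 - t1) / n_replicates)
      return(cu)
    }
  }
  stop("no cutoff on the grid meets the target", call. = FALSE) # unreachable: cutoff 1 stops all
}
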