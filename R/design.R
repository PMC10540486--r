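#' Continuation rules for two-stage designs
#'
#' A two-stage design stops for futility after the first stage unless its
#' continuation rule fires. Four rules are supported:
#'
#' * `simon_rule(r1)`: continue iff the number of *landmark* survivors among
#'   the stage-1 patients exceeds `r1` (requires full landmark follow-up of
#'   stage 1 before the interim look).
#' * `kunz_rule(s1)`: continue iff the number of *short-term* (first
#'   assessment) survivors among the stage-1 patients exceeds `s1`.
#' * `ste_cp_rule(cutoff)`: continue iff the conditional power computed from
#'   all available assessments exceeds `cutoff`.
#' * `ste_pos_rule(cutoff, prior_alpha, prior_rate)`: continue iff the
#'   posterior predictive probability of success exceeds `cutoff`, under
#'   negative log-Gamma transition priors (see [transition_prior()]).
#'
#' All comparisons are strict (`>`), mirroring the final-analysis rule
#' "reject iff survivors > r".
#'
#' @param r1,s1 Integer interim thresholds.
#' @param cutoff Continuation cutoff in \[0, 1\] for the statistic-based rules.
#' @param prior_alpha Prior parameter alpha of the induced Beta(alpha, 1)
#'   landmark prior (see [alpha_from_prior_mean()]).
#' @param prior_rate Rate parameter of the per-transition negative log-Gamma
#'   prior. `1` (the default) matches the published construction and the
#'   worked example; `prior_alpha` makes the induced landmark prior exactly
#'   Beta(alpha, 1). See the methods vignette.
#' @return A `continuation_rule` object.
#' @name continuation_rules
NULL

new_rule <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "continuation_rule")
}

#' @rdname continuation_rules
#' @export
simon_rule <- function(r1) {
  stopifnot(length(r1) == 1L, r1 >= 0, r1 == round(r1))
  new_rule("simon", r1 = as.integer(r1))
}

#' @rdname continuation_rules
#' @export
kunz_rule <- function(s1) {
  stopifnot(length(s1) == 1L, s1 >= 0, s1 == round(s1))
  new_rule("kunz", s1 = as.integer(s1))
}

#' @rdname continuation_rules
#' @export
ste_cp_rule <- function(cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff >= 0, cutoff <= 1)
  new_rule("ste_cp", cutoff = as.numeric(cutoff))
}

#' @rdname continuation_rules
#' @export
ste_pos_rule <- function(cutoff, prior_alpha, prior_rate = 1) {
  stopifnot(length(cutoff) == 1L, cutoff >= 0, cutoff <= 1, prior_alpha > 0, prior_rate > 0)
  new_rule("ste_pos",
    cutoff = as.numeric(cutoff),
    prior_alpha = as.numeric(prior_alpha),
    prior_rate = as.numeric(prior_rate)
  )
}

#' Two-stage trial design
#'
#' Bundles the sample sizes, the final rejection threshold, the hypothesized
#' survival rates and the continuation rule of a single-arm two-stage design
#' with a nested discrete-time survival endpoint. The final analysis rejects
#' the null hypothesis iff the number of landmark survivors among all
#' `n_total` patients is strictly greater than `r_final`.
#'
#' @param n_stage1 Stage-1 sample size (interim look after these patients).
#' @param n_total Total sample size; must exceed `n_stage1`.
#' @param r_final Final success threshold: reject iff landmark survivors
#'   `> r_final`.
#' @param continuation A [continuation rule][continuation_rules].
#' @param p_lte_null,p_lte_alt Hypothesized landmark (long-term) survival
#'   rates under the null and alternative; `0 < p_lte_null < p_lte_alt < 1`.
#' @param p_ste_null,p_ste_alt Hypothesized short-term (first assessment)
#'   survival rates; required by the Kunz design search and the simulator.
#'   Must dominate the corresponding landmark rates (nesting).
#' @param alpha,power_target Nominal one-sided type I error rate and power.
#' @return A `trial_design` object.
#' @examples
#' scenario1_design(kunz_rule(13))
#' @export
trial_design <- function(n_stage1, n_total, r_final, continuation,
                         p_lte_null, p_lte_alt,
                         p_ste_null = NULL, p_ste_alt = NULL,
                         alpha = 0.10, power_target = 0.95) {
  stopifnot(inherits(continuation, "continuation_rule"))
  if (!(n_stage1 > 0 && n_stage1 < n_total)) {
    stop("need 0 < n_stage1 < n_total", call. = FALSE)
  }
  if (!(r_final >= 0 && r_final < n_total)) {
    stop("need 0 <= r_final < n_total", call. = FALSE)
  }
  if (!(p_lte_null > 0 && p_lte_null < p_lte_alt && p_lte_alt < 1)) {
    stop("need 0 < p_lte_null < p_lte_alt < 1", call. = FALSE)
  }
  for (nm in c("null", "alt")) {
    ps <- get(paste0("p_ste_", nm))
    pl <- get(paste0("p_lte_", nm))
    if (!is.null(ps) && ps < pl) {
      stop("short-term rates must be >= long-term rates (nested endpoint)", call. = FALSE)
    }
  }
  structure(
    list(
      n_stage1 = as.integer(n_stage1), n_total = as.integer(n_total),
      r_final = as.integer(r_final), continuation = continuation,
      p_lte_null = p_lte_null, p_lte_alt = p_lte_alt,
      p_ste_null = p_ste_null, p_ste_alt = p_ste_alt,
      alpha = alpha, power_target = power_target
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  extra <- switch(x$continuation$method,
    simon = sprintf("r1 = %d", x$continuation$r1),
    kunz = sprintf("s1 = %d", x$continuation$s1),
    ste_cp = sprintf("CP cutoff = %g", x$continuation$cutoff),
    ste_pos = sprintf(
      "PoS cutoff = %g, prior alpha = %g, prior rate = %g",
      x$continuation$cutoff, x$continuation$prior_alpha, x$continuation$prior_rate
    )
  )
  cat(sprintf(
    paste0(
      "Two-stage design [%s]: n1 = %d, n = %d, reject iff survivors > %d (%s)\n",
      "  landmark rates H0/H1: %g / %g"
    ),
    x$continuation$method, x$n_stage1, x$n_total, x$r_final, extra,
    x$p_lte_null, x$p_lte_alt
  ))
  if (!is.null(x$p_ste_null)) {
    cat(sprintf("; short-term rates H0/H1: %g / %g", x$p_ste_null, x$p_ste_alt))
  }
  cat("\n")
  invisible(x)
}

#' Reference design of simulation scenario 1
#'
#' The optimal short-term-endpoint two-stage design for landmark rates
#' 0.127 vs 0.317 and short-term rates 0.7 vs 0.9 at alpha 0.10 and power
#' 0.95: `s1 = 13, r = 6, n1 = 18, n = 38`. Used throughout the examples and
#' tests; reproduced from scratch by [search_kunz_design()].
#'
#' @param continuation Continuation rule to attach; defaults to the Kunz rule
#'   with `s1 = 13`.
#' @return A `trial_design`.
#' @export
scenario1_design <- function(continuation = kunz_rule(13)) {
  trial_design(
    n_stage1 = 18, n_total = 38, r_final = 6, continuation = continuation,
    p_lte_null = 0.127, p_lte_alt = 0.317, p_ste_null = 0.7, p_ste_alt = 0.9
  )
}
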