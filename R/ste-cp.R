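#' Discrete-time Kaplan-Meier estimates of the conditional survival chain
#'
#' The likelihood of the interim data factorizes over assessments, so the
#' maximum likelihood estimator of each conditional survival probability
#' `p_{k|k-1}` is simply `x_k / n_k`, and the probability of surviving to the
#' landmark `k*` given last confirmed alive at `k'` telescopes:
#' `p_{k*|k'} = prod_{k = k'+1}^{k*} p_{k|k-1}` (the discrete Kaplan-Meier
#' estimator).
#'
#' Assessments with `n_k = 0` carry no information; their conditional
#' probability is plugged in from the design assumption `plug_in_rate`
#' (usually the landmark rate under the alternative). Two plug-in variants
#' exist:
#' * `"constant_hazard"` (default): each missing transition gets the constant
#'   per-step value `plug_in_rate^(1 / k_star)`, the unique choice consistent
#'   with equal conditional probabilities at every step
#'   (`p_{1|0} = p_{2|1} = ...`, i.e. constant hazard).
#' * `"direct_tail"`: whenever any transition after `k'` is unobserved, the
#'   conditional-to-landmark value is set wholesale to
#'   `plug_in_rate^(1 / (k_star - k'))`, discarding observed transitions in
#'   that tail. Provided for sensitivity analysis; see the methods vignette.
#'
#' @param snapshot An [interim_snapshot][build_interim_snapshot()].
#' @param plug_in_rate Assumed landmark survival rate used for unobserved
#'   transitions, in (0, 1). May be omitted when every `n_k > 0`.
#' @param plugin Plug-in variant, see Details.
#' @return A `conditional_survival_estimate` with fields `p_trans`
#'   (per-transition estimates), `observed` (logical provenance flags) and
#'   `p_to_end` (`p_{k*|k'}` for `k' = 0 .. k_star`; the last entry is 1).
#' @examples
#' snap <- build_interim_snapshot(worked_example_patients(),
#'   assessment_schedule(), 28, 38)
#' conditional_mles(snap, plug_in_rate = 0.317)
#' @export
conditional_mles <- function(snapshot, plug_in_rate = NULL,
                             plugin = c("constant_hazard", "direct_tail")) {
  stopifnot(inherits(snapshot, "interim_snapshot"))
  plugin <- match.arg(plugin)
  ks <- snapshot$schedule$k_star
  observed <- snapshot$n_k > 0L
  if (any(!observed) && is.null(plug_in_rate)) {
    stop("some assessments have no evaluable patients; supply `plug_in_rate`",
      call. = FALSE
    )
  }
  if (!is.null(plug_in_rate) && (plug_in_rate <= 0 || plug_in_rate >= 1)) {
    stop("`plug_in_rate` must be in (0, 1)", call. = FALSE)
  }
  p_trans <- ifelse(observed, snapshot$x_k / pmax(snapshot$n_k, 1L),
    if (is.null(plug_in_rate)) NA_real_ else plug_in_rate^(1 / ks)
  )
  # p_to_end[k' + 1] = prod_{k > k'} p_trans[k]; k' = 0..ks
  p_to_end <- c(rev(cumprod(rev(p_trans))), 1)
  if (plugin == "direct_tail" && any(!observed)) {
    for (kp in 0:(ks - 1L)) {
      if (any(!observed[(kp + 1L):ks])) {
        p_to_end[kp + 1L] <- plug_in_rate^(1 / (ks - kp))
      }
    }
  }
  structure(
    list(p_trans = p_trans, observed = observed, p_to_end = p_to_end, k_star = ks),
    class = "conditional_survival_estimate"
  )
}

#' @export
print.conditional_survival_estimate <- function(x, ...) {
  flag <- ifelse(x$observed, "", "*")
  cat(
    "Conditional survival MLEs p_{k|k-1}:",
    paste0(sprintf("%.4g", x$p_trans), flag, collapse = "  "), "\n"
  )
  if (any(!x$observed)) cat("  (* plugged in, no evaluable patients)\n")
  cat(
    "Conditional-to-landmark p_{k*|k'}, k' = 0..k*:",
    paste(sprintf("%.4g", x$p_to_end), collapse = "  "), "\n"
  )
  invisible(x)
}

#' Conditional power at an interim look
#'
#' Predicts the final number of landmark survivors by Monte Carlo: for every
#' pending group, `y_{k'} ~ Binomial(m_{k'}, p_{k*|k'})` independently (the
#' group `k' = 0` includes the not-yet-recruited stage-2 patients), the
#' predicted total is `known_survivors + sum(y)`, and the conditional power
#' is the fraction of iterations in which the total strictly exceeds
#' `r_final`. [conditional_power_exact()] computes the same probability
#' exactly by convolving the binomial distributions of the pending groups.
#'
#' @param snapshot An [interim_snapshot][build_interim_snapshot()].
#' @param estimate A [conditional_mles()] result (or any object with
#'   `p_to_end`).
#' @param r_final Final success threshold.
#' @param n_mc Number of Monte Carlo iterations (>= 1).
#' @param seed Optional integer seed.
#' @return Estimated (or exact) probability of final success.
#' @examples
#' snap <- build_interim_snapshot(worked_example_patients(),
#'   assessment_schedule(), 28, 38)
#' est <- conditional_mles(snap, plug_in_rate = 0.317)
#' conditional_power_exact(snap, est, r_final = 6)
#' @export
conditional_power <- function(snapshot, estimate, r_final, n_mc = 10000, seed = NULL) {
  if (n_mc < 1) stop("`n_mc` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ks <- snapshot$schedule$k_star
  p <- estimate$p_to_end[seq_len(ks)] # k' = 0 .. ks-1
  total <- rep.int(snapshot$known_survivors, n_mc)
  for (kp in seq_len(ks)) {
    if (snapshot$m[kp] > 0L) {
      total <- total + stats::rbinom(n_mc, snapshot$m[kp], p[kp])
    }
  }
  mean(total > r_final)
}

#' @rdname conditional_power
#' @export
conditional_power_exact <- function(snapshot, estimate, r_final) {
  ks <- snapshot$schedule$k_star
  p <- estimate$p_to_end[seq_len(ks)]
  need <- r_final - snapshot$known_survivors
  if (need < 0) return(1)
  pmf <- 1
  for (kp in seq_len(ks)) {
    if (snapshot$m[kp] > 0L) {
      pmf <- convolve_pmf(pmf, stats::dbinom(0:snapshot$m[kp], snapshot$m[kp], p[kp]))
    }
  }
  if (need + 2L > length(pmf)) return(0)
  sum(pmf[(need + 2L):length(pmf)])
}

# product of two pmfs on 0..(la-1) and 0..(lb-1)
convolve_pmf <- function(a, b) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0 # clip FFT noise
  out
}

#' Interim futility decision by conditional power
#'
#' Computes the conditional power from the snapshot (Monte Carlo, with the
#' exact convolution value attached) and continues iff it strictly exceeds
#' the design's cutoff.
#'
#' @param snapshot An [interim_snapshot][build_interim_snapshot()].
#' @param design A [trial_design()] with an [ste_cp_rule()] continuation.
#' @param plug_in_rate Plug-in landmark rate for unobserved transitions;
#'   defaults to the design's alternative landmark rate.
#' @param n_mc,seed Monte Carlo controls, see [conditional_power()].
#' @return A `decision_result` with `statistic` (Monte Carlo CP),
#'   `statistic_exact`, `continue` and `method`.
#' @export
decide_cp <- function(snapshot, design, plug_in_rate = design$p_lte_alt,
                      n_mc = 10000, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), design$continuation$method == "ste_cp")
  est <- conditional_mles(snapshot, plug_in_rate)
  cp <- conditional_power(snapshot, est, design$r_final, n_mc = n_mc, seed = seed)
  decision_result(
    statistic = cp, cutoff = design$continuation$cutoff, method = "ste_cp",
    statistic_exact = conditional_power_exact(snapshot, est, design$r_final)
  )
}

decision_result <- function(statistic, cutoff, method, statistic_exact = NULL) {
  structure(
    list(
      statistic = statistic, statistic_exact = statistic_exact,
      cutoff = cutoff, continue = statistic > cutoff, method = method
    ),
    class = "decision_result"
  )
}

#' @export
print.decision_result <- function(x, ...) {
  lbl <- c(ste_cp = "conditional power", ste_pos = "posterior predictive PoS")[x$method]
  cat(sprintf(
    "%s = %.4f (cutoff %.4g) -> %s\n",
    lbl, x$statistic, x$cutoff, if (x$continue) "continue to stage 2" else "stop for futility"
  ))
  if (!is.null(x$statistic_exact)) {
    cat(sprintf("  exact value by convolution: %.4f\n", x$statistic_exact))
  }
  invisible(x)
}
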