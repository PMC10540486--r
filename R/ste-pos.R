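#' Posterior predictive probability of success at an interim look
#'
#' Averages the conditional-power calculation over the joint posterior of the
#' conditional survival chain. Per Monte Carlo iteration one value of every
#' transition probability `p_{k|k-1}` is drawn from its posterior and
#' *shared across all pending groups*, the conditional-to-landmark
#' probabilities are formed by telescoping
#' (`p_{k*|k'} = prod_{k > k'} p_{k|k-1}`), the pending groups' survivors are
#' drawn as `y_{k'} ~ Binomial(m_{k'}, p_{k*|k'})`, and the iteration
#' succeeds iff `known_survivors + sum(y)` strictly exceeds `r_final`. The
#' PoS is the success fraction. Sharing the parameter draw within an
#' iteration preserves the between-group correlation induced by parameter
#' uncertainty; it is what shrinks the PoS towards the prior relative to the
#' plug-in conditional power.
#'
#' @param snapshot An [interim_snapshot][build_interim_snapshot()].
#' @param priors A single [transition_prior()] applied to all transitions, or
#'   a list of `k_star` of them.
#' @param r_final Final success threshold.
#' @param n_draws Number of posterior-predictive iterations.
#' @param seed Optional integer seed.
#' @param grid_size Grid resolution passed to [transition_posterior()].
#' @return The estimated probability of final success, with the per-transition
#'   posteriors attached as attribute `"posteriors"`.
#' @examples
#' snap <- build_interim_snapshot(worked_example_patients(),
#'   assessment_schedule(), 28, 38)
#' probability_of_success(snap, transition_prior(4, 0.464),
#'   r_final = 6, n_draws = 2000, seed = 1)
#' @export
probability_of_success <- function(snapshot, priors, r_final, n_draws = 10000,
                                   seed = NULL, grid_size = 4096) {
  stopifnot(inherits(snapshot, "interim_snapshot"))
  ks <- snapshot$schedule$k_star
  if (inherits(priors, "transition_prior")) priors <- rep(list(priors), ks)
  if (length(priors) != ks || !all(vapply(priors, inherits, TRUE, "transition_prior"))) {
    stop(sprintf("`priors` must be one transition_prior or a list of %d", ks), call. = FALSE)
  }
  posteriors <- lapply(seq_len(ks), function(k) {
    transition_posterior(priors[[k]], snapshot$n_k[k], snapshot$x_k[k], grid_size)
  })
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(
    posteriors, sample_posterior, numeric(n_draws),
    n_draws = n_draws
  )
  pos <- posterior_predictive_success(draws, snapshot$m, snapshot$known_survivors, r_final)
  attr(pos, "posteriors") <- posteriors
  pos
}

#' Predictive success probability from explicit transition draws
#'
#' The Monte Carlo core of [probability_of_success()], exposed so that the
#' predictive step can be driven by arbitrary joint draws of the transition
#' chain (for example degenerate point masses, under which the result reduces
#' exactly to the conditional power).
#'
#' @param draws Numeric matrix, one row per iteration and one column per
#'   transition `k = 1..k_star`, of conditional survival probabilities.
#' @param m Pending-group sizes for `k' = 0..k_star-1`.
#' @param known_survivors Confirmed landmark survivors.
#' @param r_final Final success threshold.
#' @return Fraction of iterations with predicted survivors `> r_final`.
#' @export
posterior_predictive_success <- function(draws, m, known_survivors, r_final) {
  draws <- as.matrix(draws)
  ks <- ncol(draws)
  if (length(m) != ks) stop("`m` must have one entry per transition", call. = FALSE)
  n_it <- nrow(draws)
  # p_to_end[, k'+1] = prod over k > k' ; build by reverse cumulative product
  p_to_end <- matrix(1, n_it, ks)
  acc <- rep(1, n_it)
  for (k in ks:1) {
    acc <- acc * draws[, k]
    p_to_end[, k] <- acc
  }
  total <- rep.int(known_survivors, n_it)
  for (kp in seq_len(ks)) {
    if (m[kp] > 0L) total <- total + stats::rbinom(n_it, m[kp], p_to_end[, kp])
  }
  mean(total > r_final)
}

#' Interim futility decision by posterior predictive probability of success
#'
#' Builds the transition priors from the design's `prior_alpha` and
#' `prior_rate`, computes the PoS and continues iff it strictly exceeds the
#' design's cutoff.
#'
#' @param snapshot An [interim_snapshot][build_interim_snapshot()].
#' @param design A [trial_design()] with an [ste_pos_rule()] continuation.
#' @param n_draws,seed,grid_size Passed to [probability_of_success()].
#' @return A `decision_result` with the posterior means per transition
#'   attached as `posterior_means`.
#' @export
decide_pos <- function(snapshot, design, n_draws = 10000, seed = NULL,
                       grid_size = 4096) {
  stopifnot(inherits(design, "trial_design"), design$continuation$method == "ste_pos")
  prior <- transition_prior(
    snapshot$schedule$k_star,
    alpha = design$continuation$prior_alpha,
    rate = design$continuation$prior_rate
  )
  pos <- probability_of_success(snapshot, prior, design$r_final,
    n_draws = n_draws, seed = seed, grid_size = grid_size
  )
  res <- decision_result(
    statistic = as.numeric(pos), cutoff = design$continuation$cutoff,
    method = "ste_pos"
  )
  res$posterior_means <- vapply(attr(pos, "posteriors"), posterior_mean, numeric(1))
  res
}
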