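#' Probability of early termination of Simon-type and Kunz-type designs
#'
#' With a stage-1 threshold `t` on Binomial(`n1`, `p`) successes and the rule
#' "continue iff successes > t", the probability of early termination is the
#' cumulative binomial `B(t; n1, p)`. For the Simon-type design `p` is the
#' landmark survival rate and `t = r1`; for the short-term-endpoint design it
#' is the short-term rate and `t = s1`.
#'
#' @param r1,s1 Stage-1 futility threshold (stop iff successes `<= r1`).
#' @param p,p_ste Success probability in \[0, 1\].
#' @param n1 Stage-1 sample size.
#' @return The early-termination probability.
#' @examples
#' pet_simon(13, 0.7, 18)
#' @export
pet_simon <- function(r1, p, n1) {
  if (r1 < 0 || r1 > n1) stop("need 0 <= r1 <= n1", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  stats::pbinom(r1, n1, p)
}

#' @rdname pet_simon
#' @export
pet_kunz <- function(s1, p_ste, n1) pet_simon(s1, p_ste, n1)

#' Non-binding type I error rate of a two-stage design
#'
#' Under a non-binding futility rule the type I error is computed as if the
#' trial never stopped: the upper binomial tail `P(X > r)` with
#' `X ~ Binomial(n, p0)` at the null landmark rate. This is the strictly
#' conservative convention (worst case over the unknown short-term rate).
#'
#' @param n Total sample size.
#' @param r Final success threshold (reject iff survivors `> r`).
#' @param p0 Null landmark survival rate.
#' @return Exact rejection probability under the null with no stopping.
#' @examples
#' kunz_type1(38, 6, 0.127)
#' @export
kunz_type1 <- function(n, r, p0) {
  if (r < 0 || r >= n) stop("need 0 <= r < n", call. = FALSE)
  stats::pbinom(r, n, p0, lower.tail = FALSE)
}

#' Exact rejection probability of a Kunz-type design with a binding stop
#'
#' Under nesting, the joint law at rates (`p_ste`, `p_lte`) is:
#' short-term survivors `S ~ Binomial(n1, p_ste)`; landmark survivors among
#' stage 1 `X1 | S ~ Binomial(S, p_lte / p_ste)`; stage-2 landmark survivors
#' `X2 ~ Binomial(n - n1, p_lte)`. The trial continues iff `S > s1` and
#' rejects iff `X1 + X2 > r`. Evaluated at the null rates this is the
#' binding-rule type I error; at the alternative rates, the power.
#'
#' @param n_stage1,n_total Stage-1 and total sample sizes.
#' @param s1 Interim threshold (continue iff short-term survivors `> s1`).
#' @param r Final success threshold.
#' @param p_ste,p_lte Short-term and landmark survival rates, `p_lte <= p_ste`.
#' @return Exact probability of continuing and rejecting.
#' @examples
#' kunz_reject_prob(18, 38, 13, 6, 0.9, 0.317) # design power at the alternative
#' @export
kunz_reject_prob <- function(n_stage1, n_total, s1, r, p_ste, p_lte) {
  if (p_lte > p_ste) stop("nesting violated: need p_lte <= p_ste", call. = FALSE)
  if (s1 >= n_stage1) return(0)
  grid <- kunz_reject_grid(n_stage1, n_total, p_ste, p_lte)
  grid[s1 + 1L, r + 1L]
}

# rejection probability for all (s1, r) at once:
# rows s1 = 0..n1-1, cols r = 0..n-1
kunz_reject_grid <- function(n1, n, p_ste, p_lte) {
  pc <- p_lte / p_ste
  n2 <- n - n1
  s <- 0:n1
  # joint pmf of (S, X1); dbinom(x1, 0, pc) handles S = 0
  J <- outer(s, s, function(ss, x1) stats::dbinom(ss, n1, p_ste) * stats::dbinom(x1, ss, pc))
  J[is.na(J)] <- 0
  # tail sums over s > s1
  cs <- apply(J, 2, function(col) rev(cumsum(rev(col))))
  W <- cs[2:(n1 + 1L), , drop = FALSE]
  Tail <- outer(s, 0:(n - 1L), function(x1, r) {
    stats::pbinom(r - x1, n2, p_lte, lower.tail = FALSE)
  })
  W %*% Tail
}

#' Power of a Kunz-type design under a binding stopping rule
#'
#' Convenience wrapper around [kunz_reject_prob()] taking a [trial_design()]
#' whose continuation rule is [kunz_rule()].
#'
#' @param design A `trial_design` with a Kunz continuation rule.
#' @param p_ste,p_lte True short-term and landmark survival rates.
#' @return Exact probability of rejecting the null hypothesis.
#' @examples
#' kunz_power(scenario1_design(), 0.7, 0.317) # misspecified short-term rate
#' @export
kunz_power <- function(design, p_ste, p_lte) {
  stopifnot(inherits(design, "trial_design"), design$continuation$method == "kunz")
  kunz_reject_prob(
    design$n_stage1, design$n_total, design$continuation$s1, design$r_final,
    p_ste, p_lte
  )
}

#' Expected sample size of a two-stage design
#'
#' `n1 + (1 - PET) * (n - n1)` where the early-termination probability is
#' evaluated at the supplied short-term rate (for Kunz-type rules) via
#' [pet_kunz()].
#'
#' @param design A `trial_design` with a Kunz continuation rule.
#' @param p_ste Short-term survival rate at which the stop probability is
#'   evaluated (typically the null assumption).
#' @return The expected number of patients.
#' @export
expected_sample_size <- function(design, p_ste) {
  stopifnot(inherits(design, "trial_design"), design$continuation$method == "kunz")
  pet <- pet_kunz(design$continuation$s1, p_ste, design$n_stage1)
  design$n_stage1 + (1 - pet) * (design$n_total - design$n_stage1)
}

#' Specification of a two-stage design search
#'
#' @param p_lte_null,p_lte_alt Landmark survival rates under H0 and H1.
#' @param p_ste_null,p_ste_alt Short-term survival rates under H0 and H1.
#' @param alpha Type I error limit.
#' @param beta Type II error limit (`power >= 1 - beta`).
#' @param n_max Largest total sample size enumerated.
#' @param criterion `"optimal"` minimizes the expected sample size under the
#'   null; `"minimax"` minimizes the total sample size.
#' @return A `design_search_spec` list.
#' @export
design_search_spec <- function(p_lte_null, p_lte_alt, p_ste_null, p_ste_alt,
                               alpha = 0.10, beta = 0.05, n_max = 60,
                               criterion = c("optimal", "minimax")) {
  criterion <- match.arg(criterion)
  stopifnot(
    alpha > 0, alpha < 1, beta > 0, beta < 1, n_max >= 2,
    p_lte_null > 0, p_lte_null < p_lte_alt, p_lte_alt < 1,
    p_ste_null >= p_lte_null, p_ste_alt >= p_lte_alt
  )
  structure(
    list(
      p_lte_null = p_lte_null, p_lte_alt = p_lte_alt,
      p_ste_null = p_ste_null, p_ste_alt = p_ste_alt,
      alpha = alpha, beta = beta, n_max = as.integer(n_max), criterion = criterion
    ),
    class = "design_search_spec"
  )
}

#' Exhaustive search for a Kunz-type two-stage design
#'
#' Enumerates all `(n1, n <= n_max, s1 < n1, r < n)` and keeps the designs
#' whose type I error is at most `alpha` and whose binding-rule power at the
#' alternative rates is at least `1 - beta`. The type I error is by default
#' the *binding* rejection probability evaluated at
#' (`p_ste_null`, `p_lte_null`) — the convention under which the reference
#' scenario-1 design (s1 = 13, r = 6, n1 = 18, n = 38) is the optimum;
#' `type1_rule = "nonbinding"` uses the conservative no-stopping tail
#' [kunz_type1()] instead. Among admissible designs the `"optimal"` criterion
#' minimizes the expected sample size under the null (PET evaluated at
#' `p_ste_null`) and `"minimax"` minimizes `n`; ties are broken by smaller
#' `n`, then smaller `n1`, then larger `s1`.
#'
#' For fixed `(n1, n, s1)` only the smallest `r` meeting the type I
#' constraint is considered: the rejection probability is decreasing in `r`,
#' so that choice maximizes power without affecting the expected sample size.
#'
#' @param spec A [design_search_spec()].
#' @param type1_rule `"binding"` (default) or `"nonbinding"`, see Details.
#' @return A [trial_design()] with a [kunz_rule()] continuation, carrying the
#'   attained exact `type1`, `power`, `expected_n` and `pet_null` as
#'   attribute `"oc"`; errors with class `"stetrials_infeasible"` if no
#'   design within `n_max` meets both constraints.
#' @examples
#' \donttest{
#' spec <- design_search_spec(0.127, 0.317, 0.7, 0.9)
#' search_kunz_design(spec) # s1 = 13, r = 6, n1 = 18, n = 38
#' }
#' @export
search_kunz_design <- function(spec, type1_rule = c("binding", "nonbinding")) {
  stopifnot(inherits(spec, "design_search_spec"))
  type1_rule <- match.arg(type1_rule)
  best <- NULL
  best_key <- c(Inf, Inf, Inf, -Inf) # objective, n, n1, -s1
  for (n in 3:spec$n_max) {
    for (n1 in 2:(n - 1L)) {
      R1 <- kunz_reject_grid(n1, n, spec$p_ste_alt, spec$p_lte_alt)
      R0 <- if (type1_rule == "binding") {
        kunz_reject_grid(n1, n, spec$p_ste_null, spec$p_lte_null)
      } else {
        matrix(
          stats::pbinom(0:(n - 1L), n, spec$p_lte_null, lower.tail = FALSE),
          nrow = n1, ncol = n, byrow = TRUE
        )
      }
      pet0 <- stats::pbinom(0:(n1 - 1L), n1, spec$p_ste_null)
      for (s1 in 0:(n1 - 1L)) {
        ok <- which(R0[s1 + 1L, ] <= spec$alpha)
        if (!length(ok)) next
        r <- ok[1L] - 1L
        pw <- R1[s1 + 1L, r + 1L]
        if (pw < 1 - spec$beta) next
        en <- n1 + (1 - pet0[s1 + 1L]) * (n - n1)
        obj <- if (spec$criterion == "optimal") en else n
        key <- c(obj, n, n1, -s1)
        if (is.null(best) || lexicographically_less(key, best_key)) {
          best_key <- key
          best <- list(s1 = s1, r = r, n1 = n1, n = n, en = en,
                       type1 = R0[s1 + 1L, r + 1L], power = pw, pet0 = pet0[s1 + 1L])
        }
      }
    }
  }
  if (is.null(best)) {
    stop(structure(
      class = c("stetrials_infeasible", "error", "condition"),
      list(message = sprintf(
        "no design with n <= %d meets alpha = %g and power = %g",
        spec$n_max, spec$alpha, 1 - spec$beta
      ), call = NULL)
    ))
  }
  design <- trial_design(
    n_stage1 = best$n1, n_total = best$n, r_final = best$r,
    continuation = kunz_rule(best$s1),
    p_lte_null = spec$p_lte_null, p_lte_alt = spec$p_lte_alt,
    p_ste_null = spec$p_ste_null, p_ste_alt = spec$p_ste_alt,
    alpha = spec$alpha, power_target = 1 - spec$beta
  )
  attr(design, "oc") <- data.frame(
    s1 = best$s1, r = best$r, n_stage1 = best$n1, n_total = best$n,
    type1 = best$type1, power = best$power,
    expected_n_null = best$en, pet_null = best$pet0
  )
  design
}

lexicographically_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Exact operating characteristics of a Simon-type two-stage design
#'
#' Both the interim and the final count refer to the *landmark* endpoint, so
#' the interim look requires full landmark follow-up of stage 1. With a
#' binding first-stage rule, the rejection probability at success rate `p` is
#' `sum_{x1 > r1} P(X1 = x1) P(X1 + X2 > r)` with `X1 ~ Binomial(n1, p)` and
#' `X2 ~ Binomial(n - n1, p)`.
#'
#' @param design A `trial_design` with a [simon_rule()] continuation.
#' @param p Landmark survival rate (type I error at the null rate, power at
#'   the alternative).
#' @return A list with `reject_prob` and `pet`.
#' @export
simon_design_oc <- function(design, p) {
  stopifnot(inherits(design, "trial_design"), design$continuation$method == "simon")
  r1 <- design$continuation$r1
  n1 <- design$n_stage1
  n2 <- design$n_total - n1
  r <- design$r_final
  if (r1 > n1 || r >= design$n_total) stop("invalid thresholds", call. = FALSE)
  if (r1 == n1) {
    reject <- 0
  } else {
    x1 <- (r1 + 1L):n1
    reject <- sum(
      stats::dbinom(x1, n1, p) * stats::pbinom(r - x1, n2, p, lower.tail = FALSE)
    )
  }
  list(reject_prob = reject, pet = pet_simon(r1, p, n1))
}
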