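# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exact posterior mean of p under the negative log-Gamma prior and binomial
# likelihood, by expanding (1 - e^{-u})^{n-x} into an alternating sum of
# Gamma integrals in u = -log p:
#   E[p^s | data] = sum_j (-1)^j C(n-x, j) (rate + x + j + s)^{-a}  /
#                   sum_j (-1)^j C(n-x, j) (rate + x + j)^{-a}
oracle_posterior_moment <- function(n, x, shape, rate, s = 1) {
  j <- 0:(n - x)
  w <- (-1)^j * choose(n - x, j)
  sum(w * (rate + x + j + s)^(-shape)) / sum(w * (rate + x + j)^(-shape))
}

# Brute-force rejection probability of a Kunz-type design by enumerating the
# full joint support of (S, X1, X2).
oracle_kunz_reject <- function(n1, n, s1, r, p_ste, p_lte) {
  pc <- p_lte / p_ste
  n2 <- n - n1
  total <- 0
  for (s in 0:n1) {
    if (s <= s1) next
    for (x1 in 0:s) {
      for (x2 in 0:n2) {
        if (x1 + x2 > r) {
          total <- total + dbinom(s, n1, p_ste) * dbinom(x1, s, pc) * dbinom(x2, n2, p_lte)
        }
      }
    }
  }
  total
}

# Brute-force Simon-type rejection probability by enumerating all 2^n
# outcome vectors (tiny n only).
oracle_simon_reject <- function(n1, n, r1, r, p) {
  paths <- expand.grid(rep(list(0:1), n))
  probs <- apply(paths, 1, function(z) prod(ifelse(z == 1, p, 1 - p)))
  x1 <- rowSums(paths[, seq_len(n1), drop = FALSE])
  xt <- rowSums(paths)
  sum(probs[x1 > r1 & xt > r])
}

# Term-by-term binomial tail, avoiding pbinom.
oracle_binom_tail <- function(r, n, p) {
  if (r >= n) return(0)
  sum(vapply((r + 1):n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

# Exact P(sum of independent binomials > threshold) by direct dynamic
# programming over the joint support (no FFT).
oracle_binom_sum_tail <- function(m, p, threshold) {
  pmf <- 1
  for (j in seq_along(m)) {
    if (m[j] == 0) next
    b <- dbinom(0:m[j], m[j], p[j])
    new <- numeric(length(pmf) + m[j])
    for (i in seq_along(pmf)) {
      new[i:(i + m[j])] <- new[i:(i + m[j])] + pmf[i] * b
    }
    pmf <- new
  }
  if (threshold + 2 > length(pmf)) return(0)
  sum(pmf[(threshold + 2):length(pmf)])
}

scenario1_snapshot <- function() {
  build_interim_snapshot(
    worked_example_patients(), assessment_schedule(),
    interim_time = 28, n_total = 38
  )
}

# random nested-survival patient set for property tests
random_patients <- function(n, accrual = 1, shape = 0.844, scale = 10.18) {
  patient_records(
    recruit_time = cumsum(rexp(n, accrual)),
    event_time = rweibull(n, shape, scale)
  )
}
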