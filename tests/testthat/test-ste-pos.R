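test_that("alpha_from_prior_mean inverts the Beta(alpha, 1) mean", {
  expect_equal(alpha_from_prior_mean(0.317), 0.464, tolerance = 1e-3)
  expect_equal(alpha_from_prior_mean(0.5), 1)
  expect_equal(alpha_from_prior_mean(0.8), 4)
  a <- alpha_from_prior_mean(0.317)
  expect_equal(a / (a + 1), 0.317)
  expect_error(alpha_from_prior_mean(0), "inside")
  expect_error(alpha_from_prior_mean(1), "inside")
})

test_that("grid posterior matches the closed-form alternating-sum oracle", {
  for (rate in c(0.464, 1, 4)) {
    prior <- transition_prior(4, alpha = rate, rate = rate)
    for (cc in list(c(18, 12), c(11, 6), c(5, 3), c(3, 3), c(7, 0))) {
      post <- transition_posterior(prior, cc[1], cc[2])
      expect_equal(
        posterior_mean(post),
        oracle_posterior_moment(cc[1], cc[2], prior$shape, rate),
        tolerance = 1e-6,
        label = sprintf("mean(n=%d, x=%d, rate=%g)", cc[1], cc[2], rate)
      )
    }
  }
  expect_error(transition_posterior(transition_prior(4, 1), 3, 4), "x_k <= n_k")
})

test_that("zero data returns the prior", {
  prior <- transition_prior(4, 0.464, rate = 0.464)
  post <- transition_posterior(prior, 0, 0)
  # prior mean of p: E[e^{-U}], U ~ Gamma(1/4, 0.464)
  expect_equal(posterior_mean(post), (0.464 / 1.464)^(1 / 4), tolerance = 1e-7)
  # CDF agrees with the analytic Gamma tail at interior grid points
  idx <- seq(100, 4000, by = 450)
  analytic <- pgamma(-log(post$p[idx]), shape = 1 / 4, rate = 0.464, lower.tail = FALSE)
  expect_equal(post$cdf[idx], analytic, tolerance = 1e-6)
  expect_true(all(post$density[-1] >= 0))
  expect_equal(max(post$cdf), 1, tolerance = 1e-8)
})

test_that("worked-example posterior means match the published chain (rate 1)", {
  prior <- transition_prior(4, 0.464, rate = 1)
  counts <- list(c(18, 12), c(11, 6), c(5, 3), c(3, 3))
  means <- vapply(
    counts,
    function(cc) posterior_mean(transition_posterior(prior, cc[1], cc[2])),
    numeric(1)
  )
  expect_equal(round(means, 3), c(0.681, 0.583, 0.658, 0.946), tolerance = 1e-3)
  # landmark posterior mean: product of independent transition means
  expect_equal(round(prod(means), 3), 0.247)
  # the all-survivors transition has the exact closed form ((rate+x)/(rate+x+1))^shape
  expect_equal(means[4], (4 / 5)^(1 / 4), tolerance = 1e-7)
  # the MLE-adjacent transition is pulled toward the per-step prior mean
  mle <- 12 / 18
  expect_gt(means[1], mle)
})

test_that("posterior concentrates on the MLE as data grow", {
  prior <- transition_prior(4, 0.464, rate = 1)
  post <- transition_posterior(prior, 10000, 6667)
  expect_equal(posterior_mean(post), 0.6667, tolerance = 1e-3)
})

test_that("inverse-CDF sampling reproduces the grid posterior's moments", {
  prior <- transition_prior(4, 0.464, rate = 1)
  post <- transition_posterior(prior, 11, 6)
  set.seed(99)
  draws <- sample_posterior(post, 200000)
  expect_equal(mean(draws), posterior_mean(post), tolerance = 0.002)
  m2 <- oracle_posterior_moment(11, 6, prior$shape, 1, s = 2)
  expect_equal(mean(draws^2), m2, tolerance = 0.003)
})

test_that("the prior product follows Beta(alpha, 1) when rate = alpha", {
  for (alpha in c(0.464, 1, 4)) {
    prior <- transition_prior(4, alpha, rate = alpha)
    draws <- sample_prior_product(prior, 100000, seed = round(alpha * 100))
    ks <- suppressWarnings(ks.test(draws, pbeta, alpha, 1))
    expect_gt(ks$p.value, 0.001, label = sprintf("KS vs Beta(%g, 1)", alpha))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - alpha / (alpha + 1)), 3 * se)
  }
})

test_that("PoS reproduces the worked example and its trivial limits", {
  snap <- scenario1_snapshot()
  prior <- transition_prior(4, 0.464, rate = 1)
  pos <- probability_of_success(snap, prior, r_final = 6, n_draws = 50000, seed = 4)
  expect_equal(as.numeric(pos), 0.7784, tolerance = 0.02)
  # known survivors already exceed the threshold
  snap_hi <- snap
  snap_hi$known_survivors <- 7L
  expect_equal(
    as.numeric(probability_of_success(snap_hi, prior, 6, n_draws = 500, seed = 1)),
    1
  )
  expect_error(probability_of_success(snap, list(prior, prior), 6), "list of 4")
})

test_that("degenerate posterior draws reduce PoS to the exact conditional power", {
  snap <- scenario1_snapshot()
  est <- conditional_mles(snap, plug_in_rate = 0.317)
  n_it <- 40000
  draws <- matrix(rep(est$p_trans, each = n_it), n_it, 4)
  set.seed(11)
  pos <- posterior_predictive_success(draws, snap$m, snap$known_survivors, 6)
  exact <- conditional_power_exact(snap, est, 6)
  expect_equal(pos, exact, tolerance = 4 * sqrt(exact * (1 - exact) / n_it))
})

test_that("PoS shrinks extreme CP values toward the prior-only prediction", {
  # 18 patients, all alive through month 9; landmark transition plugged in.
  # With a demanding threshold the MLE-based CP is near 1; averaging over the
  # posterior (PoS) must land strictly between the CP and the prediction made
  # from the prior alone (same pending-group structure, no data).
  pts <- patient_records(rep(0, 18), NA)
  snap <- build_interim_snapshot(pts, assessment_schedule(), 9, 38)
  est <- conditional_mles(snap, plug_in_rate = 0.317)
  r_final <- 18
  cp <- conditional_power_exact(snap, est, r_final)
  prior <- transition_prior(4, 0.464, rate = 1)
  pos <- as.numeric(probability_of_success(snap, prior, r_final,
    n_draws = 20000, seed = 2
  ))
  no_data <- snap
  no_data$n_k <- no_data$x_k <- rep(0L, 4)
  prior_pos <- as.numeric(probability_of_success(no_data, prior, r_final,
    n_draws = 20000, seed = 3
  ))
  expect_gt(cp, 0.99)
  expect_lt(pos, cp)
  expect_gt(pos, prior_pos)
})

test_that("decide_pos applies a strict cutoff and reports posterior means", {
  snap <- scenario1_snapshot()
  des <- scenario1_design(ste_pos_rule(0.734, 0.464, prior_rate = 1))
  res <- decide_pos(snap, des, n_draws = 20000, seed = 8)
  expect_true(res$continue) # ~0.778 > 0.734
  expect_equal(round(res$posterior_means, 2), c(0.68, 0.58, 0.66, 0.95), tolerance = 0.01)
  never <- decide_pos(snap, scenario1_design(ste_pos_rule(1, 0.464)), n_draws = 200, seed = 1)
  expect_false(never$continue)
})
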