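test_that("conditional MLE chain reproduces the worked example exactly", {
  est <- conditional_mles(scenario1_snapshot(), plug_in_rate = 0.317)
  expect_equal(est$p_trans, c(12 / 18, 6 / 11, 3 / 5, 1))
  expect_equal(round(est$p_trans, 3), c(0.667, 0.545, 0.600, 1))
  # telescoping to the landmark: 216/990
  expect_equal(est$p_to_end[1], 216 / 990)
  expect_equal(round(est$p_to_end[1:4], 3), c(0.218, 0.327, 0.600, 1))
  expect_equal(est$p_to_end[5], 1) # p_{k*|k*}
  expect_true(all(est$observed))
})

test_that("plug-in fills unobserved transitions with the constant-hazard root", {
  snap <- scenario1_snapshot()
  snap$n_k <- c(10L, 0L, 0L, 0L)
  snap$x_k <- c(5L, 0L, 0L, 0L)
  est <- conditional_mles(snap, plug_in_rate = 0.36)
  expect_equal(est$p_trans, c(0.5, rep(0.36^(1 / 4), 3)))
  expect_equal(est$observed, c(TRUE, FALSE, FALSE, FALSE))
  # with k* = 2 the root squares back: 0.6^2 = 0.36
  snap2 <- build_interim_snapshot(
    patient_records(rep(0, 10), c(rep(NA, 5), rep(2, 5))),
    assessment_schedule(2, 3), interim_time = 3, n_total = 10
  )
  est2 <- conditional_mles(snap2, plug_in_rate = 0.36)
  expect_equal(est2$p_trans, c(0.5, 0.6))
  expect_error(conditional_mles(snap), "plug_in_rate")
  expect_error(conditional_mles(snap, plug_in_rate = 1.5), "plug_in_rate")
})

test_that("the direct-tail plug-in variant overrides partially observed tails", {
  snap <- scenario1_snapshot()
  snap$n_k <- c(10L, 4L, 0L, 0L)
  snap$x_k <- c(8L, 3L, 0L, 0L)
  est <- conditional_mles(snap, plug_in_rate = 0.317, plugin = "direct_tail")
  expect_equal(est$p_to_end[1], 0.317^(1 / 4))
  expect_equal(est$p_to_end[3], 0.317^(1 / 2))
  expect_equal(est$p_to_end[5], 1)
})

test_that("fully alive data gives a degenerate chain", {
  snap <- build_interim_snapshot(
    patient_records(rep(0, 5), NA),
    assessment_schedule(), 12, 5
  )
  est <- conditional_mles(snap)
  expect_equal(est$p_trans, rep(1, 4))
  expect_equal(est$p_to_end[1], 1)
})

test_that("exact conditional power matches an independent convolution oracle", {
  snap <- scenario1_snapshot()
  est <- conditional_mles(snap, plug_in_rate = 0.317)
  cp <- conditional_power_exact(snap, est, r_final = 6)
  expect_equal(
    cp,
    oracle_binom_sum_tail(snap$m, est$p_to_end[1:4], 6 - snap$known_survivors),
    tolerance = 1e-10
  )
  # trivial reductions
  expect_equal(conditional_power_exact(snap, est, r_final = 2), 1) # known > r
  zero <- est
  zero$p_to_end <- rep(0, 5)
  expect_equal(conditional_power_exact(snap, zero, r_final = 6), 0)
  # single group, threshold needs one success: P = p
  snap1 <- snap
  snap1$m <- c(1L, 0L, 0L, 0L)
  snap1$known_survivors <- 0L
  half <- est
  half$p_to_end <- c(0.5, 1, 1, 1, 1)
  expect_equal(conditional_power_exact(snap1, half, r_final = 0), 0.5)
  # two singleton groups, need both: a * b
  snap2 <- snap
  snap2$m <- c(1L, 1L, 0L, 0L)
  snap2$known_survivors <- 0L
  ab <- est
  ab$p_to_end <- c(0.3, 0.8, 1, 1, 1)
  expect_equal(conditional_power_exact(snap2, ab, r_final = 1), 0.3 * 0.8)
})

test_that("Monte Carlo CP converges to the exact convolution", {
  snap <- scenario1_snapshot()
  est <- conditional_mles(snap, plug_in_rate = 0.317)
  exact <- conditional_power_exact(snap, est, 6)
  n_mc <- 20000
  hits <- 0
  for (s in 1:10) {
    cp <- conditional_power(snap, est, 6, n_mc = n_mc, seed = s)
    if (abs(cp - exact) <= 4 * sqrt(exact * (1 - exact) / n_mc)) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(conditional_power(snap, est, 6, n_mc = 0), "n_mc")
})

test_that("CP is monotone in the inputs", {
  snap <- scenario1_snapshot()
  est <- conditional_mles(snap, plug_in_rate = 0.317)
  base <- conditional_power_exact(snap, est, 6)
  up <- est
  up$p_to_end <- pmin(est$p_to_end * 1.2, 1)
  expect_gte(conditional_power_exact(snap, up, 6), base)
  more_known <- snap
  more_known$known_survivors <- snap$known_survivors + 1L
  expect_gte(conditional_power_exact(more_known, est, 6), base)
  expect_lte(conditional_power_exact(snap, est, 7), base)
})

test_that("decide_cp applies a strict cutoff", {
  snap <- scenario1_snapshot()
  res <- decide_cp(snap, scenario1_design(ste_cp_rule(0.728)), n_mc = 5000, seed = 1)
  expect_true(res$continue) # 0.817 > 0.728
  expect_equal(res$statistic_exact, 0.817, tolerance = 0.001)
  # statistic equal to the cutoff stops (strict inequality)
  at_cut <- stetrials:::decision_result(0.5, cutoff = 0.5, method = "ste_cp")
  expect_false(at_cut$continue)
  always <- decide_cp(snap, scenario1_design(ste_cp_rule(0)), n_mc = 100, seed = 1)
  expect_true(always$continue)
})
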