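test_that("deliberation time follows the kinetic catch-up formula", {
  expect_equal(deliberation_time(1, 0.5, 2), 1.5)
  expect_equal(deliberation_time(3, 2, 1), 3)      # no recruitment advantage
  expect_equal(deliberation_time(2, 2, 3), 2 + 2 * log2(3), tolerance = 1e-12)
  expect_error(deliberation_time(0, 1, 2), "kinetic")
})

test_that("recognition probabilities follow the escape law", {
  k <- affinity_kernel(4, 2, 4, 1)
  expect_equal(recognition_probabilities(k, 1, 0),
               list(p_mem = 0, p_naive = 1))
  # half-recognition when E * beta = ln 2
  k2 <- affinity_kernel(2, 2, 4, 1)
  e <- binding_affinity(k2, 0.3)
  p <- recognition_probabilities(k2, 0.3, log(2) / e)
  expect_equal(p$p_mem, 0.5, tolerance = 1e-12)
  # saturated deliberation against the cognate antigen
  expect_equal(recognition_probabilities(k, 0, 10)$p_naive, exp(-10),
               tolerance = 1e-12)
  # monotone: decreasing in d, increasing in beta
  d <- seq(0, 1.5, by = 0.1)
  pm <- recognition_probabilities(k, d, 5)$p_mem
  expect_true(all(diff(pm) < 0))
  pb <- vapply(1:10, function(b) recognition_probabilities(k, 0.2, b)$p_mem,
               numeric(1))
  expect_true(all(diff(pb) > 0))
})

test_that("utilities price deliberation on both branches", {
  k <- affinity_kernel(2, 2, 4, 1)
  u <- utilities(k, 0.5, 5, deliberation_cost("none"))
  expect_equal(u$u_naive, 0)
  expect_equal(u$u_mem, binding_affinity(k, 0.5))
  u2 <- utilities(k, 0.5, 2, deliberation_cost("linear", 0.1), beta_max = 10)
  expect_equal(u2$u_naive, -0.02)
  # vanishing affinity: memory utility collapses onto naive
  u3 <- utilities(k, 50, 2, deliberation_cost("linear", 0.1))
  expect_equal(u3$u_mem, u3$u_naive, tolerance = 1e-12)
})

test_that("max-entropy decision is logistic and prior-shifted", {
  expect_equal(decision_distribution(0.3, 0.3, 5), 0.5)
  expect_gt(decision_distribution(1, 0, 50), 1 - 1e-12)
  expect_equal(decision_distribution(1, 0, 0), 0.5)   # no processing: prior
  expect_gt(decision_distribution(0, 0, 3, q0_mem = 0.9), 0.5)
  # guarded for extreme |beta * dU|
  expect_equal(decision_distribution(-10, 10, 100), 0)
  expect_true(is.finite(decision_distribution(10, -10, 100)))
})

test_that("utility gap inverts the recognition law", {
  expect_equal(utility_gap_from_recognition(log(2) / 3, 3), 0)  # indifference
  expect_equal(utility_gap_from_recognition(0.1, 10), log(exp(1) - 1) / 10,
               tolerance = 1e-12)
  # exponential-dominated regime: gap approaches the affinity itself
  expect_equal(utility_gap_from_recognition(0.9, 50), 0.9, tolerance = 1e-12)
  expect_identical(utility_gap_from_recognition(0, 5), -Inf)
})

test_that("decision rule and recognition kinetics are mutually consistent", {
  # the sigmoid applied to the kinetics-implied utility gap must reproduce
  # 1 - exp(-E beta) across the whole (E, beta) operating range
  es <- seq(0.05, 1, length.out = 25)
  bs <- seq(0.25, 10, length.out = 25)
  for (e in es) {
    du <- utility_gap_from_recognition(e, bs)
    q <- decision_distribution(du, 0, bs)
    expect_equal(q, 1 - exp(-e * bs), tolerance = 1e-10)
  }
  # gap strictly increasing in affinity
  du <- utility_gap_from_recognition(es, 4)
  expect_true(all(diff(du) > 0))
})
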