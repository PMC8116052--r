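test_that("lifetime simulation respects its scoring contract", {
  st <- mem_strategy(alpha = 3, beta = 4)
  pr <- proc_dh(0.3)
  expect_error(simulate_lifetime(st, fam2(), pr, no_cost(), L = 1), "L")
  set.seed(5)
  res <- simulate_lifetime(st, fam2(), pr, no_cost(), L = 20, keep_trace = TRUE)
  expect_equal(nrow(res$trace), 19)          # scored encounters = L - 1
  expect_true(res$usage_fraction >= 0 && res$usage_fraction <= 1)
  expect_equal(res$mean_net_utility, mean(res$trace$u_net))
})

test_that("zero deliberation never uses memory and refreshes every round", {
  st <- mem_strategy(alpha = 3, beta = 0)
  set.seed(6)
  res <- simulate_lifetime(st, fam2(), proc_dh(0.4), no_cost(), L = 15,
                           keep_trace = TRUE)
  expect_equal(res$usage_fraction, 0)
  # fresh memory each round: the drift clock never advances past 1
  expect_lt(max(res$trace$d), 3 * 0.1 * 1.2)
})

test_that("conserved antigens with maximal strategy give unit net utility", {
  st <- mem_strategy(alpha = 4, beta = 10)
  set.seed(7)
  res <- simulate_lifetime(st, fam2(), pathogen_process(0), no_cost(), L = 40)
  expect_equal(res$mean_net_utility_hat, 1 - exp(-10), tolerance = 1e-9)
  expect_gt(res$usage_fraction, 0.99)
})

test_that("lifetime simulation is bit-reproducible under a fixed seed", {
  st <- mem_strategy(alpha = 2.5, beta = 3)
  set.seed(42); a <- simulate_lifetime(st, fam2(), proc_dh(0.25), lin_cost(), 30,
                                       keep_trace = TRUE)
  set.seed(42); b <- simulate_lifetime(st, fam2(), proc_dh(0.25), lin_cost(), 30,
                                       keep_trace = TRUE)
  expect_identical(a, b)
})

test_that("a two-encounter lifetime scores the single k = 1 outcome", {
  st <- mem_strategy(alpha = 3, beta = 5)
  pr <- proc_dh(0.3)
  set.seed(9)
  res <- simulate_lifetime(st, fam2(), pr, lin_cost(), L = 2)
  set.seed(9)
  d <- sample_antigenic_distance(pr, 1)
  out <- net_utility(affinity_kernel(3, 2, 4, 1), d, 5, lin_cost())
  expect_equal(res$mean_net_utility, out$u_net, tolerance = 1e-9)
})

test_that("memory usage declines with antigenic divergence", {
  st <- mem_strategy(alpha = 3, beta = 4)
  usage_at <- function(dh) {
    vapply(1:120, function(i) {
      simulate_lifetime(st, fam2(), proc_dh(dh), no_cost(), 25)$usage_fraction
    }, numeric(1))
  }
  set.seed(10)
  u1 <- usage_at(0.1); u2 <- usage_at(0.5)
  se <- sqrt(sd(u1)^2 / 120 + sd(u2)^2 / 120)
  expect_gt(mean(u1) - mean(u2), 3 * se)
})

test_that("ensemble evaluation reduces noise as 1/sqrt(n)", {
  st <- mem_strategy(alpha = 3, beta = 3)
  set.seed(12)
  e1 <- evaluate_strategy(st, fam2(), proc_dh(0.3), no_cost(), L = 15,
                          n_ensembles = 40)
  e2 <- evaluate_strategy(st, fam2(), proc_dh(0.3), no_cost(), L = 15,
                          n_ensembles = 400)
  expect_true(is.finite(e1$se) && is.finite(e2$se))
  # a decade more ensembles shrinks the SE ~ sqrt(10), within 35% slack
  expect_equal(e1$se / e2$se, sqrt(10), tolerance = 0.35)
  # single-lifetime evaluation degenerates to simulate_lifetime
  set.seed(13)
  s1 <- evaluate_strategy(st, fam2(), proc_dh(0.3), no_cost(), 15, 1)
  expect_true(is.na(s1$se))
})
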