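test_that("mixture recognition equals the product of per-slot escapes", {
  fam <- fam2()
  set.seed(41)
  for (i in 1:5) {
    alphas <- runif(8, 0, 4)
    bt <- runif(1, 0.5, 4)
    st <- mixture_strategy(alphas, bt)
    d <- runif(1, 0, 0.8)
    rec <- mixture_recognition(st, fam, d)
    # product form vs the exponential mean-affinity form
    p_prod <- 1 - prod(exp(-rec$affinities * st$beta))
    expect_equal(rec$p_mem, p_prod, tolerance = 1e-12)
  }
  # a single-slot mixture reduces exactly to single-memory recognition
  st1 <- mixture_strategy(2.5, beta_tilde = 3)
  rec1 <- mixture_recognition(st1, fam, 0.4)
  ref <- recognition_probabilities(affinity_kernel(2.5, 2, 4, 1), 0.4, 3)
  expect_equal(rec1$p_mem, ref$p_mem, tolerance = 1e-12)
  # identical slots: escape compounds Nm times
  stn <- mixture_strategy(rep(2, 6), beta_tilde = 6 * 0.5)
  e <- binding_affinity(affinity_kernel(2, 2, 4, 1), 0.3)
  expect_equal(mixture_recognition(stn, fam, 0.3)$p_mem,
               1 - exp(-6 * 0.5 * e), tolerance = 1e-12)
})

test_that("responder selection follows relative affinities", {
  expect_error(select_responder(c(0, 0, 0)), "zero")
  set.seed(42)
  expect_true(all(replicate(20, select_responder(c(0, 0.3, 0))) == 2))
  # equal affinities: uniform choice (chi-square at 1%)
  draws <- replicate(1e4, select_responder(rep(0.2, 4)))
  expect_gt(chisq.test(tabulate(draws, 4))$p.value, 0.01)
  # 2:1 affinities select in 2:1 proportion within 3 SE
  eps <- 1e-6
  sel <- replicate(1e4, select_responder(c(2 * eps, eps)))
  p1 <- mean(sel == 1)
  expect_lt(abs(p1 - 2 / 3), 3 * sqrt(2 / 9 / 1e4))
})

test_that("mixture objective reduces to the single-memory simulator at Nm = 1", {
  fam <- fam2()
  set.seed(43)
  mix <- mc_mean(30, function() {
    mixture_objective(mixture_strategy(3, 2.5), fam,
                      delta_hat_range = c(0.3, 0.3), n_antigens = 20, L = 25)
  })
  single <- mc_mean(600, function() {
    simulate_lifetime(mem_strategy(3, 2.5), fam, proc_dh(0.3), no_cost(),
                      L = 25)$mean_net_utility
  })
  se <- sqrt(mix$se^2 + single$se^2)
  expect_lt(abs(mix$mean - single$mean), 3 * se)
})

test_that("zero effective deliberation gives the pure naive objective", {
  set.seed(44)
  obj <- mixture_objective(mixture_strategy(runif(10, 0, 4), 0), fam2(),
                           n_antigens = 10, L = 10)
  expect_equal(obj, 0)
})

test_that("objective noise shrinks with the number of antigen lineages", {
  fam <- fam2()
  st <- mixture_strategy(seq(0.5, 4, length.out = 10), 2)
  set.seed(45)
  v_small <- replicate(25, mixture_objective(st, fam, n_antigens = 10, L = 15))
  v_large <- replicate(25, mixture_objective(st, fam, n_antigens = 160, L = 15))
  # 16x the lineages: sd should drop ~4x; allow broad slack
  expect_gt(sd(v_small) / sd(v_large), 2)
})

test_that("the ascent itself optimizes a known quadratic objective", {
  target <- c(1.2, 2.8, 0.9)
  set.seed(46)
  out <- optimize_mixture(
    initial_alphas = c(3.5, 0.5, 2.0), beta_tilde = 0,
    kernel_family = fam2(), n_steps = 150, n_probe = 8, epsilon = 0.05,
    objective_fn = function(a) -sum((a - target)^2)
  )
  expect_lt(max(abs(out$alphas - target)), 0.1)
})

test_that("a flat objective leaves the ascent in place up to estimator noise", {
  init <- seq(0.5, 3.5, length.out = 6)
  set.seed(47)
  out <- optimize_mixture(init, beta_tilde = 0, kernel_family = fam2(),
                          n_steps = 40, n_probe = 8,
                          objective_fn = function(a) 0)
  expect_identical(out$alphas, init)
  # flat-in-distance kernel (theta = 0): both profiles coincide, so the
  # dissipation vanishes identically
  k0 <- affinity_kernel(2, 0, 4, 1)
  expect_equal(dissipation(k0, 0.7, 5), 0, tolerance = 1e-12)
})

test_that("produced but inert zero-specificity memories are never used", {
  fam <- fam2()
  strategies <- list(mixture_strategy(c(0, 0, 2, 4), 2))
  ens <- structure(
    list(strategies = strategies,
         alphas = matrix(strategies[[1]]$alphas, 1),
         beta_tilde = 2, kernel_family = fam,
         delta_hat_range = c(0, 1.6)),
    class = "mixture_ensemble"
  )
  set.seed(48)
  u <- usage_probability(ens, n_test = 60, L = 20)
  bin <- function(x) which.min(abs(u$alpha_hat - x))
  expect_equal(u$usage[bin(0.025)], 0)
  expect_true(is.na(u$usage[bin(0.325)]))  # nothing produced there
  used_bins <- round(u$alpha_hat[!is.na(u$usage) & u$usage > 0], 3)
  expect_true(all(used_bins %in% c(0.525, 0.975)))
})

test_that("specificity histograms locate modes and the inert bin", {
  a <- c(rep(0, 3), rep(2, 5), rep(3.9, 7), 2.1)
  h <- specificity_histogram(a, alpha_max = 4)
  expect_equal(h$zero_mass, 3 / 16)
  expect_equal(h$mode_low, 0.525, tolerance = 0.051)
  expect_equal(h$mode_high, 0.975, tolerance = 0.026)
  expect_equal(sum(h$density), 1)
})
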