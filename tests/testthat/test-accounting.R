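test_that("expected profile interpolates between memory and antigen profiles", {
  k <- affinity_kernel(2, 2, 4, 1)
  gs <- c(-5, 5.5, 801)
  # no deliberation: pure naive branch, antigen-centered profile
  p0 <- expected_profile(k, 0, 0.5, beta = 0, grid_spec = gs)
  ant <- normalized_profile(k, 0.5, gs)
  expect_equal(p0$weights, ant$weights, tolerance = 1e-12)
  # saturated recognition at d = 0: memory profile itself
  p1 <- expected_profile(k, 0, 0, beta = 50, grid_spec = gs)
  mem <- normalized_profile(k, 0, gs)
  expect_equal(p1$weights, mem$weights, tolerance = 1e-10)
  # mixture of normalized profiles stays normalized
  pm <- expected_profile(k, 0, 0.7, beta = 4, grid_spec = gs)
  expect_equal(sum(pm$weights), 1, tolerance = 1e-9)
})

test_that("dissipation is a proper divergence with the Gaussian limit", {
  k <- affinity_kernel(2, 2, 4, 1)
  expect_identical(dissipation(k, 0, 5), 0)
  expect_identical(dissipation(k, 0.4, 0), 0)   # no-memory limit
  d <- seq(0.05, 1, by = 0.05)
  kd <- vapply(d, function(x) dissipation(k, x, 5), numeric(1))
  expect_true(all(kd >= 0))
  # while memory stays engaged (saturated recognition) the dissipation grows
  # with the separation across [0, 2/alpha]; at moderate beta it instead
  # peaks and falls once recognition disengages
  kd_sat <- vapply(d, function(x) dissipation(k, x, 400), numeric(1))
  expect_true(all(diff(kd_sat) > -1e-9))
  expect_gt(max(kd), kd[1])
  # saturated-memory theta = 2 limit: KL of shifted equal-variance Gaussians
  for (d0 in c(0.3, 0.5)) {
    beta_sat <- 200 # recognition ~ 1
    expect_equal(dissipation(k, d0, beta_sat), (2 * d0)^2 / beta_sat,
                 tolerance = 0.01)
  }
})

test_that("dissipation is stable under grid refinement", {
  k <- affinity_kernel(2, 2, 4, 1)
  for (d in c(0.2, 0.6)) {
    gs1 <- c(d / 2 - 4 - d / 2, d / 2 + 4 + d / 2, 801)
    gs2 <- c(gs1[1], gs1[2], 1601)
    expect_lt(abs(dissipation(k, d, 5, gs1) - dissipation(k, d, 5, gs2)), 1e-4)
  }
})

test_that("tabulated dissipation interpolant matches direct evaluation", {
  for (params in list(c(2, 5), c(3.5, 8), c(1, 2))) {
    k <- affinity_kernel(params[1], 2, 4, 1)
    f <- dissipation_interpolant(k, params[2])
    ds <- c(0.01, 0.1, 0.35, 0.7, 1.1, 1.9)
    direct <- vapply(ds, function(d) dissipation(k, d, params[2]), numeric(1))
    expect_lt(max(abs(f(ds) - direct)), 1e-6)
  }
  # theta = 1 kernel as well
  k1 <- affinity_kernel(2, 1, 4, 1)
  f1 <- dissipation_interpolant(k1, 5)
  expect_lt(abs(f1(0.8) - dissipation(k1, 0.8, 5)), 1e-6)
})

test_that("net utility assembles expectation minus dissipation", {
  k <- affinity_kernel(4, 2, 4, 1)
  # conserved antigen, saturated deliberation, zero cost: utility ~ e_max
  out <- net_utility(k, 0, 10, deliberation_cost("none"))
  expect_equal(out$u_net, 1 - exp(-10), tolerance = 1e-12)
  # pure naive response at zero cost
  out0 <- net_utility(k, 0.5, 0, deliberation_cost("none"))
  expect_equal(out0$u_net, 0)
  # dissipation only ever lowers the expected utility
  for (d in c(0.1, 0.4, 0.9)) {
    o <- net_utility(affinity_kernel(3, 2, 4, 1), d, 6,
                     deliberation_cost("linear", 0.1))
    expect_lte(o$u_net, o$expected_utility)
    expect_equal(o$u_net, o$expected_utility - o$k_diss)
  }
})
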