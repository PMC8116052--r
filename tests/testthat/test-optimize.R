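test_that("conserved antigens at zero cost select the maximal strategy", {
  # with d identically 0 and no cost, net utility increases in both alpha and
  # beta, so the exhaustive grid argmax must sit at the upper corner
  set.seed(21)
  opt <- optimize_strategy(fam2(), pathogen_process(0), no_cost(),
                           grid = c(12L, 12L), L = 10L, n_ensembles = 10L)
  expect_equal(opt$alpha_hat_star, 1)
  expect_equal(opt$beta_hat_star, 1)
  expect_equal(opt$u_net_star, 1 - exp(-10), tolerance = 1e-9)
  # argmax equals the exhaustive surface maximum by construction
  expect_equal(opt$u_net_star, max(opt$surface$u_net))
})

test_that("ensemble grid simulation agrees with the reference lifetime loop", {
  # the C++ common-random-numbers sweep and the plain R simulator are two
  # routes to the same expectation
  set.seed(22)
  opt <- optimize_strategy(fam2(), proc_dh(0.3), lin_cost(),
                           grid = c(6L, 6L), L = 25L, n_ensembles = 400L)
  dist <- (opt$surface$alpha_hat - 0.6)^2 + (opt$surface$beta_hat - 0.6)^2
  cell <- opt$surface[which.min(dist), ]
  set.seed(23)
  ref <- evaluate_strategy(mem_strategy(0.6 * 4, 6), fam2(), proc_dh(0.3),
                           lin_cost(), L = 25L, n_ensembles = 400L)
  se <- sqrt(cell$u_net_se^2 + ref$se^2)
  expect_lt(abs(cell$u_net - ref$mean), 4 * se)
})

test_that("common random numbers keep the surface smooth", {
  set.seed(24)
  opt <- optimize_strategy(fam2(), proc_dh(0.2), lin_cost(),
                           grid = c(10L, 10L), L = 30L, n_ensembles = 150L)
  s <- opt$surface
  for (bh in unique(s$beta_hat)[c(3, 7)]) {
    g <- s[s$beta_hat == bh, ]
    g <- g[order(g$alpha_hat), ]
    du <- abs(diff(g$u_net))
    se_pair <- g$u_net_se[-1] + g$u_net_se[-nrow(g)]
    # neighbouring cells differ by less than 5 joint SEs plus the smooth
    # trend of the surface itself (~0.1 per cell at this coarse spacing)
    expect_true(all(du < 5 * se_pair + 0.12))
  }
})

test_that("prohibitive quadratic costs shut memory down entirely", {
  set.seed(25)
  opt <- optimize_strategy(fam2(), proc_dh(2),
                           deliberation_cost("quadratic", 20),
                           grid = c(10L, 10L), L = 20L, n_ensembles = 60L)
  expect_equal(opt$alpha_hat_star, 0)
  expect_equal(opt$beta_hat_star, 0)
})

test_that("divergence scan is deterministic given seeds and well-shaped", {
  dh <- c(0.1, 0.4)
  s1 <- divergence_scan(fam2(), lin_cost(), dh, grid = c(8L, 8L), L = 15L,
                        n_ensembles = 40L, seed = 31)
  s2 <- divergence_scan(fam2(), lin_cost(), dh, grid = c(8L, 8L), L = 15L,
                        n_ensembles = 40L, seed = 31)
  expect_identical(s1$alpha_hat_star, s2$alpha_hat_star)
  expect_equal(nrow(s1), 2)
  expect_named(s1, c("delta_hat", "alpha_hat_star", "beta_hat_star",
                     "u_net_star", "k_max"))
  expect_true(all(s1$k_max >= 0))
})

test_that("lifetime scan locates the specificity minimum", {
  sc <- lifetime_scan(fam2(), proc_dh(0.35), lin_cost(), L_list = c(2, 6, 20),
                      grid = c(10L, 10L), n_ensembles = 80L, seed = 33)
  expect_equal(nrow(sc), 3)
  cs <- attr(sc, "c_star")
  expect_true(cs %in% c(2, 6, 20))
  expect_equal(sc$alpha_hat_star[sc$L == cs], min(sc$alpha_hat_star))
})
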