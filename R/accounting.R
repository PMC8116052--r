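# Per-encounter accounting: expected binding profile, KL dissipation, and
# net utility, given the current memory state.

# default grid for comparing a memory profile at `center_m` with an antigen
# profile at `center_a`: 8 cross-reactive ranges beyond each center, 801
# points. Reduces to midpoint +/- 8/alpha when the centers coincide.
default_grid_spec <- function(kernel, center_m, center_a, n_points = 801L) {
  span <- 8 / kernel$alpha
  c(min(center_m, center_a) - span, max(center_m, center_a) + span, n_points)
}

#' Expected binding profile after a decision
#'
#' The binding profile the immune system expects to carry after an encounter:
#' with probability `p_mem` the old memory (centered at `memory_center`) is
#' engaged and kept, with probability `p_naive` a naive response stores fresh
#' memory centered at the infecting antigen. The result is the
#' probability-weighted mixture of the two normalized profiles.
#'
#' @param kernel an [affinity_kernel()] with `alpha > 0`.
#' @param memory_center,antigen_center shape-space coordinates of the stored
#'   memory's cognate antigen and of the current antigen.
#' @param beta deliberation factor.
#' @param grid_spec optional `c(lo, hi, n)`; defaults to 8 cross-reactive
#'   ranges beyond each center with 801 points.
#' @return A `profile_grid` (weights sum to 1).
#' @export
expected_profile <- function(kernel, memory_center, antigen_center, beta,
                             grid_spec = NULL) {
  if (is.null(grid_spec)) {
    grid_spec <- default_grid_spec(kernel, memory_center, antigen_center)
  }
  d <- abs(antigen_center - memory_center)
  p <- recognition_probabilities(kernel, d, beta)
  mem <- normalized_profile(kernel, memory_center, grid_spec)
  ant <- normalized_profile(kernel, antigen_center, grid_spec)
  structure(
    list(positions = mem$positions,
         weights = p$p_mem * mem$weights + p$p_naive * ant$weights),
    class = "profile_grid"
  )
}

#' Dissipation of a memory response
#'
#' The non-equilibrium price of deciding on the fly: the Kullback-Leibler
#' divergence (in nats) between the expected binding profile after the
#' encounter and the optimal profile of freshly matured memory centered on
#' the current antigen, per unit deliberation,
#' \deqn{K_{diss} = \frac{1}{\beta} D_{KL}(\bar E \,\|\, E_{antigen}).}
#' It vanishes iff the profiles coincide (`d = 0`) and is defined as 0 at
#' `beta = 0` (no memory engagement, by continuity).
#'
#' @inheritParams expected_profile
#' @param d distance between the memory's cognate antigen and the current
#'   antigen, `>= 0`.
#' @return Dissipation in utility units (nats of KL per unit `beta`).
#' @export
dissipation <- function(kernel, d, beta, grid_spec = NULL) {
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (d == 0) return(0)            # profiles coincide exactly
  if (beta == 0) return(0)
  if (kernel$alpha == 0) return(0) # zero-height profile: memory never engaged
  if (is.null(grid_spec)) grid_spec <- default_grid_spec(kernel, 0, d)
  pbar <- expected_profile(kernel, 0, d, beta, grid_spec)
  opt <- normalized_profile(kernel, d, grid_spec)
  kl_discrete(pbar$weights, opt$weights) / beta
}

# KL divergence between two discrete distributions on the same grid, in nats;
# 0 * log(0) := 0, and float cancellation around coinciding profiles is
# clamped at the mathematical lower bound 0
kl_discrete <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  max(0, sum(p[nz] * (log(p[nz]) - log(q[nz]))))
}

#' Net utility of one encounter
#'
#' Assembles the full per-encounter bookkeeping given the memory state:
#' recognition probabilities, expected utility
#' `<U> = u_mem p_mem + u_naive p_naive`, dissipation, and net utility
#' `u_net = <U> - k_diss`. All quantities are deterministic given `d` and the
#' parameters; which branch is realized (`memory_used`) is drawn by the
#' lifetime simulator, not here.
#'
#' @inheritParams dissipation
#' @param cost a [deliberation_cost()].
#' @param beta_max bound used to scale `beta` inside the cost.
#' @param use_cache optional [dissipation_interpolant()] matching `kernel` and
#'   `beta`, used instead of the direct KL evaluation.
#' @return An object of class `encounter_outcome`: a list with `d`, `p_mem`,
#'   `p_naive`, `u_mem`, `u_naive`, `expected_utility`, `k_diss`, `u_net`,
#'   `memory_used` (NA here).
#' @export
net_utility <- function(kernel, d, beta, cost, beta_max = 10,
                        grid_spec = NULL, use_cache = NULL) {
  p <- recognition_probabilities(kernel, d, beta)
  u <- utilities(kernel, d, beta, cost, beta_max = beta_max)
  kd <- if (is.null(use_cache)) {
    dissipation(kernel, d, beta, grid_spec = grid_spec)
  } else {
    use_cache(d)
  }
  eu <- u$u_mem * p$p_mem + u$u_naive * p$p_naive
  structure(
    list(d = d, p_mem = p$p_mem, p_naive = p$p_naive,
         u_mem = u$u_mem, u_naive = u$u_naive,
         expected_utility = eu, k_diss = kd, u_net = eu - kd,
         memory_used = NA),
    class = "encounter_outcome"
  )
}

#' @export
print.encounter_outcome <- function(x, ...) {
  cat(sprintf(
    "<encounter_outcome> d = %.4g, p_mem = %.4f, <U> = %.4f, K_diss = %.4g, U_net = %.4f\n",
    x$d, x$p_mem, x$expected_utility, x$k_diss, x$u_net
  ))
  invisible(x)
}

#' Fast dissipation interpolant for a fixed strategy
#'
#' Precomputes `K_diss(d)` for one `(alpha, beta)` on 2048 distance points and
#' returns a natural-spline interpolating function, the performance-critical
#' cache used by the lifetime optimizers. Beyond the tabulated range the
#' memory recognition probability is numerically zero and the dissipation is
#' returned as 0.
#'
#' @inheritParams dissipation
#' @param n_d number of tabulation points.
#' @return A function `f(d)` vectorized over `d`.
#' @export
dissipation_interpolant <- function(kernel, beta, n_d = 2048L) {
  if (beta <= 0 || kernel$alpha == 0) {
    return(function(d) rep(0, length(d)))
  }
  lambda <- beta * kernel$e_max * kernel$alpha / kernel$alpha_max
  s_max <- dissipation_s_max(kernel$theta, lambda)
  s_grid <- seq(0, s_max, length.out = n_d)
  kl <- cpp_kl_cache(s_grid, lambda, kernel$theta, 801L, 8.0)[, 1]
  f <- splinefun(s_grid, kl, method = "natural")
  alpha <- kernel$alpha
  function(d) {
    s <- alpha * d
    out <- numeric(length(s))
    inside <- s < s_max
    out[inside] <- pmax(0, f(s[inside])) / beta
    out
  }
}

# scaled distance beyond which K_diss is numerically zero: the recognition
# probability ~ lambda * exp(-s^theta) has fallen below ~1e-15
dissipation_s_max <- function(theta, lambda) {
  if (theta == 0) return(1)
  (log(max(lambda, 1)) + 36)^(1 / theta)
}
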