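# Multi-specificity ("mixture") memory: recognition, stochastic responder
# selection, lifetime objective over a distribution of divergences, gradient
# ascent over the specificity vector, and usage statistics.

#' Mixture memory strategy
#'
#' A repertoire holding `Nm` memory specificities simultaneously. Each slot
#' deliberates with the per-slot factor `beta`, and the effective
#' deliberation of the whole repertoire is `beta_tilde = Nm * beta`, the
#' quantity that is comparable across repertoires of different sizes.
#'
#' @param alphas vector of specificities, each in `[0, alpha_max]`.
#' @param beta_tilde effective deliberation factor (`Nm * beta`), `>= 0`.
#' @return An object of class `mixture_strategy` with fields `alphas`,
#'   `beta`, `beta_tilde`.
#' @export
mixture_strategy <- function(alphas, beta_tilde) {
  if (length(alphas) < 1L) stop("need at least one specificity", call. = FALSE)
  if (any(alphas < 0)) stop("`alphas` must be >= 0", call. = FALSE)
  if (beta_tilde < 0) stop("`beta_tilde` must be >= 0", call. = FALSE)
  structure(
    list(alphas = as.numeric(alphas), beta = beta_tilde / length(alphas),
         beta_tilde = beta_tilde),
    class = "mixture_strategy"
  )
}

#' @export
print.mixture_strategy <- function(x, ...) {
  cat(sprintf("<mixture_strategy> Nm = %d, beta_tilde = %g, alphas in [%g, %g]\n",
              length(x$alphas), x$beta_tilde, min(x$alphas), max(x$alphas)))
  invisible(x)
}

#' Mixture recognition probability and mean affinity
#'
#' A pathogen escapes every slot independently, so the memory-recognition
#' probability is `1 - prod_i exp(-E_i * beta) = 1 - exp(-beta_tilde * Ebar)`
#' with `Ebar` the mean affinity over slots. For `Nm = 1` this reduces
#' exactly to the single-memory recognition law.
#'
#' @param strategy a [mixture_strategy()].
#' @param kernel_family a [kernel_family()].
#' @param d antigenic distance from the common memory center, `>= 0`.
#' @return A list with `p_mem`, `mean_affinity`, and the per-slot
#'   `affinities`.
#' @export
mixture_recognition <- function(strategy, kernel_family, d) {
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  e <- vapply(strategy$alphas, function(a) {
    binding_affinity(affinity_kernel(a, kernel_family$theta,
                                     kernel_family$alpha_max,
                                     kernel_family$e_max), d)
  }, numeric(1))
  ebar <- mean(e)
  list(p_mem = -expm1(-strategy$beta_tilde * ebar),
       mean_affinity = ebar, affinities = e)
}

#' Stochastic responder selection
#'
#' Which stored memory answers an infection is stochastic, with rate
#' proportional to relative affinity: slot `i` responds with probability
#' `E_i / sum_j E_j`.
#'
#' @param affinities non-negative per-slot affinities, at least one positive.
#' @return The selected slot index. Uses the R RNG.
#' @export
select_responder <- function(affinities) {
  if (any(affinities < 0)) stop("affinities must be >= 0", call. = FALSE)
  total <- sum(affinities)
  if (total <= 0) stop("no memory can respond: all affinities are zero",
                       call. = FALSE)
  sample.int(length(affinities), 1L, prob = affinities / total)
}

# shared KL(s, eta) table for mixture accounting, eta = beta_tilde * Ebar;
# memoized per (family, beta_tilde)
mixture_kl_table <- function(kernel_family, beta_tilde, n_s = 1024L,
                             n_eta = 257L, n_profile = 801L) {
  key <- paste("mix", signif(c(kernel_family$theta, kernel_family$alpha_max,
                               kernel_family$e_max, beta_tilde), 12),
               n_s, n_eta, collapse = ",")
  hit <- .memstrat_cache[[key]]
  if (!is.null(hit)) return(hit)
  eta_max <- max(beta_tilde * kernel_family$e_max, 1e-8)
  s_max <- dissipation_s_max(kernel_family$theta, eta_max)
  s_grid <- seq(0, s_max, length.out = n_s)
  etas <- seq(0, eta_max, length.out = n_eta)
  tab <- cpp_kl_table_w(s_grid, -expm1(-etas), kernel_family$theta,
                        n_profile, 8.0)
  out <- list(tab = tab, s_max = s_max, eta_max = eta_max)
  .memstrat_cache[[key]] <- out
  out
}

#' Lifetime net-utility objective of a mixture strategy
#'
#' Simulates, for each of `n_antigens` independently evolving pathogen
#' lineages (each with its own divergence drawn uniformly from
#' `delta_hat_range`), a host lifetime of `L` encounters: a naive response
#' stores one memory per specificity slot, all centered on the triggering
#' antigen; later encounters are answered by a stochastically selected
#' responder slot or by a new naive response. Per-round accounting mirrors
#' the single-memory case with the responder's profile as the memory
#' profile. Returns the grand mean net utility per scored encounter.
#'
#' @param strategy a [mixture_strategy()].
#' @param kernel_family a [kernel_family()].
#' @param delta_hat_range length-2 range of scaled divergences.
#' @param n_antigens number of pathogen lineages, `>= 1`.
#' @param L encounters per lifetime, `>= 2`.
#' @param cost a [deliberation_cost()] (scaled by
#'   `beta_tilde / beta_eff_max`).
#' @param beta_eff_max bound used to scale `beta_tilde` in the cost.
#' @param rel_sd relative SD of drift draws.
#' @param return_usage if `TRUE`, also return per-slot responder counts.
#' @return Mean net utility per encounter (utility units), or a list when
#'   `return_usage = TRUE`.
#' @export
mixture_objective <- function(strategy, kernel_family,
                              delta_hat_range = c(0, 1.6),
                              n_antigens = 50L, L = 40L,
                              cost = deliberation_cost("none"),
                              beta_eff_max = 10, rel_sd = 0.05,
                              return_usage = FALSE) {
  stopifnot(inherits(strategy, "mixture_strategy"), n_antigens >= 1, L >= 2)
  tabs <- mixture_kl_table(kernel_family, strategy$beta_tilde)
  deltas <- runif(n_antigens, delta_hat_range[1], delta_hat_range[2]) /
    kernel_family$alpha_max
  sim <- cpp_sim_mixture(
    strategy$alphas, strategy$beta_tilde, deltas, rel_sd, as.integer(L),
    kernel_family$theta, kernel_family$alpha_max, kernel_family$e_max,
    cost_code(cost), cost$omega0_hat, beta_eff_max,
    tabs$tab, tabs$s_max, tabs$eta_max
  )
  if (return_usage) sim else sim$u_net
}

#' Gradient-ascent optimization of a mixture strategy
#'
#' Iterates `alphas <- clip(alphas + epsilon * grad)` where the gradient of
#' the stochastic lifetime objective is estimated at each step from
#' `n_probe` Gaussian perturbations of the specificity vector (SD
#' `0.05 * alpha_max`) by a least-squares fit of objective differences
#' against the perturbations. The base and probe objectives within a step
#' share random numbers, so their differences reflect the perturbations
#' rather than simulation noise.
#'
#' @inheritParams mixture_objective
#' @param initial_alphas starting specificity vector.
#' @param epsilon gradient-ascent step size.
#' @param n_steps number of ascent steps.
#' @param n_probe perturbations per step; must be `>= Nm + 1`.
#' @param keep_path if `TRUE`, attach the objective trace.
#' @param objective_fn optional replacement objective `function(alphas)`,
#'   used in place of the lifetime-summed [mixture_objective()] (e.g. a
#'   closed-form test objective for validating the ascent itself).
#' @return A `mixture_strategy` with optimized `alphas`; attribute
#'   `"objective"` holds the final-step base objective, and `"path"` the
#'   per-step objective when requested.
#' @export
optimize_mixture <- function(initial_alphas, beta_tilde, kernel_family,
                             delta_hat_range = c(0, 1.6),
                             n_antigens = 50L, L = 40L,
                             cost = deliberation_cost("none"),
                             beta_eff_max = 10, epsilon = 0.1,
                             n_steps = 300L, n_probe = 30L, rel_sd = 0.05,
                             keep_path = FALSE, objective_fn = NULL) {
  nm <- length(initial_alphas)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (n_probe < nm + 1L) {
    stop("`n_probe` must be >= Nm + 1 for gradient estimation", call. = FALSE)
  }
  amax <- kernel_family$alpha_max
  alphas <- pmin(pmax(as.numeric(initial_alphas), 0), amax)
  sd_probe <- 0.05 * amax
  path <- numeric(n_steps)
  obj <- NA_real_
  n_enc <- L - 1L
  for (step in seq_len(n_steps)) {
    step_seed <- sample.int(.Machine$integer.max, 1L)
    # lifetime-summed net utility: the ascent maximizes the total over the
    # scored encounters (the per-encounter mean times their number), which is
    # the quantity the optimal-strategy argmax is defined on
    eval_obj <- function(a) {
      set.seed(step_seed)
      if (!is.null(objective_fn)) return(objective_fn(a))
      n_enc * mixture_objective(mixture_strategy(a, beta_tilde),
                                kernel_family, delta_hat_range, n_antigens,
                                L, cost, beta_eff_max, rel_sd)
    }
    base <- eval_obj(alphas)
    xi <- matrix(rnorm(n_probe * nm, sd = sd_probe), n_probe, nm)
    dy <- numeric(n_probe)
    for (p in seq_len(n_probe)) {
      probe <- pmin(pmax(alphas + xi[p, ], 0), amax)
      xi[p, ] <- probe - alphas # effective perturbation after clipping
      dy[p] <- eval_obj(probe) - base
    }
    # least-squares slope with an intercept absorbing curvature and
    # common-random-number offsets
    fit <- qr.solve(cbind(1, xi), dy)
    grad <- fit[-1]
    alphas <- pmin(pmax(alphas + epsilon * grad, 0), amax)
    path[step] <- base / n_enc
    obj <- base / n_enc
  }
  out <- mixture_strategy(alphas, beta_tilde)
  attr(out, "objective") <- obj
  if (keep_path) attr(out, "path") <- path
  out
}

#' Ensemble of mixture optimizations
#'
#' Runs `n_restarts` independent gradient-ascent optimizations, each starting
#' from a uniform random specificity vector, and pools the optimized
#' components. The pooled distribution of functional (`alpha > 0`)
#' specificities is the mixture strategy an immune system should maintain
#' against pathogens of unknown evolutionary rate.
#'
#' @inheritParams optimize_mixture
#' @param n_restarts number of independent optimizations.
#' @param nm repertoire size per optimization.
#' @param seed optional integer; restart `r` re-seeds with `seed + r`.
#' @return An object of class `mixture_ensemble`: a list with `strategies`
#'   (list of `mixture_strategy`), `alphas` (matrix `n_restarts x nm`), and
#'   the run parameters.
#' @export
mixture_ensemble <- function(kernel_family, n_restarts = 20L, nm = 20L,
                             beta_tilde = 2,
                             delta_hat_range = c(0, 1.6),
                             n_antigens = 50L, L = 40L,
                             cost = deliberation_cost("none"),
                             beta_eff_max = 10, epsilon = 0.1,
                             n_steps = 300L, n_probe = 30L, seed = NULL) {
  strategies <- vector("list", n_restarts)
  amat <- matrix(NA_real_, n_restarts, nm)
  for (r in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(seed + r)
    init <- runif(nm, 0, kernel_family$alpha_max)
    strategies[[r]] <- optimize_mixture(
      init, beta_tilde, kernel_family, delta_hat_range, n_antigens, L,
      cost, beta_eff_max, epsilon, n_steps, n_probe
    )
    amat[r, ] <- strategies[[r]]$alphas
  }
  structure(
    list(strategies = strategies, alphas = amat, beta_tilde = beta_tilde,
         kernel_family = kernel_family, delta_hat_range = delta_hat_range),
    class = "mixture_ensemble"
  )
}

#' Histogram and modes of pooled optimized specificities
#'
#' Bins the pooled functional (`alpha > 0`) scaled specificities of a
#' [mixture_ensemble()] with bin width 0.05 and locates the low- and
#' high-specificity modes: the highest-mass bins below and above the
#' `split` point.
#'
#' @param ensemble a [mixture_ensemble()], or a numeric matrix/vector of
#'   optimized alphas.
#' @param alpha_max bound used for scaling when `ensemble` is numeric.
#' @param bin_width histogram bin width on the scaled axis.
#' @param split boundary between the two search windows.
#' @param zero_tol alphas below this are counted as the non-functional
#'   `alpha = 0` bin.
#' @return A list with `breaks`, `mid`, `density` (over functional alphas),
#'   `zero_mass` (fraction at `alpha = 0`), `mode_low`, `mode_high`.
#' @export
specificity_histogram <- function(ensemble, alpha_max = NULL,
                                  bin_width = 0.05, split = 0.75,
                                  zero_tol = 1e-3) {
  if (inherits(ensemble, "mixture_ensemble")) {
    a <- as.vector(ensemble$alphas)
    amax <- ensemble$kernel_family$alpha_max
  } else {
    a <- as.vector(ensemble)
    amax <- if (is.null(alpha_max)) stop("`alpha_max` needed") else alpha_max
  }
  ahat <- a / amax
  zero_mass <- mean(ahat <= zero_tol)
  fun <- ahat[ahat > zero_tol]
  breaks <- seq(0, 1 + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(fun, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  mid <- breaks[-length(breaks)] + bin_width / 2
  dens <- counts / max(sum(counts), 1L)
  low <- mid <= split
  list(breaks = breaks, mid = mid, density = dens, zero_mass = zero_mass,
       mode_low = mid[low][which.max(dens[low])],
       mode_high = mid[!low][which.max(dens[!low])])
}

#' Usage probability of stored specificities
#'
#' Tests an optimized ensemble against fresh pathogens and measures, per
#' scaled-specificity bin, the fraction of all memory responses answered by
#' receptors in that bin divided by the fraction of produced receptors in
#' that bin: the conditional probability of a produced memory being used,
#' up to the overall usage rate. Receptors with `alpha = 0` are produced but
#' can never respond, so their usage is 0; bins with no produced receptors
#' are reported as `NA` (undefined, not zero).
#'
#' @param ensemble a [mixture_ensemble()].
#' @param n_test total number of test pathogen lineages.
#' @param L encounters per test lifetime.
#' @param bin_width histogram bin width on the scaled axis.
#' @inheritParams mixture_objective
#' @return A data frame with columns `alpha_hat` (bin midpoint), `produced`
#'   (production share), `used` (usage share), `usage` (ratio, `NA` for
#'   empty bins).
#' @export
usage_probability <- function(ensemble, n_test = 1000L, L = 40L,
                              cost = deliberation_cost("none"),
                              beta_eff_max = 10, rel_sd = 0.05,
                              bin_width = 0.05) {
  stopifnot(inherits(ensemble, "mixture_ensemble"))
  fam <- ensemble$kernel_family
  n_r <- length(ensemble$strategies)
  per <- max(1L, ceiling(n_test / n_r))
  breaks <- seq(0, 1 + bin_width / 2, by = bin_width)
  nb <- length(breaks) - 1L
  produced <- numeric(nb)
  used <- numeric(nb)
  for (r in seq_len(n_r)) {
    st <- ensemble$strategies[[r]]
    sim <- mixture_objective(st, fam, ensemble$delta_hat_range,
                             n_antigens = per, L = L, cost = cost,
                             beta_eff_max = beta_eff_max, rel_sd = rel_sd,
                             return_usage = TRUE)
    bins <- findInterval(pmin(st$alphas / fam$alpha_max, 1), breaks,
                         rightmost.closed = TRUE)
    for (j in seq_along(bins)) {
      produced[bins[j]] <- produced[bins[j]] + 1
      used[bins[j]] <- used[bins[j]] + sim$usage_counts[j]
    }
  }
  prod_share <- produced / sum(produced)
  used_share <- if (sum(used) > 0) used / sum(used) else used
  data.frame(
    alpha_hat = breaks[-length(breaks)] + bin_width / 2,
    produced = prod_share,
    used = used_share,
    usage = ifelse(produced > 0, used_share / pmax(prod_share, 1e-12), NA_real_)
  )
}
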