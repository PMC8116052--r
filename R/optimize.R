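# Grid-search optimization of (alpha, beta) and the divergence / lifetime
# scans built on it.

# Shared KL cache for a strategy grid. K_diss * beta depends only on the
# scaled separation s = alpha * d and on lambda = beta * e_max * alpha_hat,
# so one matrix of KL(s) columns (one per grid point) serves every
# divergence and every lifetime. Memoized per (family, grids) in the
# package-local environment.
strategy_grid_cache <- function(kernel_family, alphas, betas, n_d = 2048L,
                                n_profile = 801L) {
  key <- paste(
    signif(c(kernel_family$theta, kernel_family$alpha_max,
             kernel_family$e_max, alphas, betas), 12),
    collapse = ","
  )
  hit <- .memstrat_cache[[key]]
  if (!is.null(hit)) return(hit)
  ahat <- alphas / kernel_family$alpha_max
  lambdas <- as.vector(outer(ahat * kernel_family$e_max, betas)) # alpha fastest
  s_max <- dissipation_s_max(kernel_family$theta, max(lambdas, 1e-12))
  s_grid <- seq(0, s_max, length.out = n_d)
  kl <- cpp_kl_cache(s_grid, lambdas, kernel_family$theta, n_profile, 8.0)
  out <- list(kl = kl, s_max = s_max, alphas = alphas, betas = betas)
  .memstrat_cache[[key]] <- out
  out
}

#' Grid-search optimization of a memory strategy
#'
#' Sweeps an `n_alpha x n_beta` grid of strategies spanning
#' `[0, alpha_max] x [0, beta_max]`, simulating `n_ensembles` lifetimes of
#' `L` encounters at each grid point with common random numbers (the same
#' drift innovations and decision draws are reused across grid points, so
#' surface differences reflect the strategies, not the noise). Returns the
#' argmax strategy and the full net-utility surface. Ties are broken toward
#' the cheaper strategy: smallest `beta`, then smallest `alpha`.
#'
#' @param kernel_family a [kernel_family()].
#' @param process a [pathogen_process()].
#' @param cost a [deliberation_cost()].
#' @param grid integer vector `c(n_alpha, n_beta)`, each `>= 2`.
#' @param L encounters per lifetime, `>= 2`.
#' @param n_ensembles lifetimes per grid point.
#' @param beta_max deliberation bound.
#' @return An object of class `optimization_result`: `alpha_star`,
#'   `beta_star`, `alpha_hat_star`, `beta_hat_star`, `u_net_star`, `k_max`
#'   (maximum mean dissipation over the surface), and `surface`, a data frame
#'   with columns `alpha_hat`, `beta_hat`, `u_net`, `u_net_se`, `k_diss`,
#'   `usage`.
#' @export
optimize_strategy <- function(kernel_family, process, cost,
                              grid = c(50L, 50L), L = 60L,
                              n_ensembles = 200L, beta_max = 10) {
  stopifnot(inherits(kernel_family, "kernel_family"),
            inherits(process, "pathogen_process"),
            inherits(cost, "deliberation_cost"))
  if (length(grid) != 2L || any(grid < 2L)) {
    stop("`grid` must be c(n_alpha, n_beta) with both >= 2", call. = FALSE)
  }
  if (L < 2L) stop("`L` must be >= 2", call. = FALSE)
  alphas <- seq(0, kernel_family$alpha_max, length.out = grid[1])
  betas <- seq(0, beta_max, length.out = grid[2])
  cache <- strategy_grid_cache(kernel_family, alphas, betas)
  n_enc <- L - 1L
  Z <- matrix(rnorm(n_ensembles * n_enc), n_ensembles, n_enc)
  U <- matrix(runif(n_ensembles * n_enc), n_ensembles, n_enc)
  sim <- cpp_sim_strategy_grid(
    alphas, betas, kernel_family$alpha_max, kernel_family$e_max,
    kernel_family$theta, process$delta, process$rel_sd,
    process$drift_scaling == "sqrt", as.integer(L), cost_code(cost),
    cost$omega0_hat, beta_max, Z, U, cache$kl, cache$s_max
  )
  surface <- data.frame(
    alpha_hat = rep(alphas / kernel_family$alpha_max, times = length(betas)),
    beta_hat = rep(betas / beta_max, each = length(alphas)),
    u_net = as.vector(sim$u_net) / kernel_family$e_max,
    u_net_se = as.vector(sim$u_net_se) / kernel_family$e_max,
    k_diss = as.vector(sim$k_diss),
    usage = as.vector(sim$usage)
  )
  # argmax with cheap-strategy tie-breaking (beta, then alpha)
  ord <- order(-surface$u_net, surface$beta_hat, surface$alpha_hat)
  best <- surface[ord[1], ]
  structure(
    list(alpha_star = best$alpha_hat * kernel_family$alpha_max,
         beta_star = best$beta_hat * beta_max,
         alpha_hat_star = best$alpha_hat,
         beta_hat_star = best$beta_hat,
         u_net_star = best$u_net,
         k_max = max(surface$k_diss),
         surface = surface,
         grid = grid, L = L, n_ensembles = n_ensembles,
         beta_max = beta_max,
         delta_hat = process$delta * kernel_family$alpha_max),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    paste0("<optimization_result> delta_hat = %.3g: alpha_hat* = %.3f, ",
           "beta_hat* = %.3f, U_net* = %.4f (grid %dx%d, %d ensembles, L = %d)\n"),
    x$delta_hat, x$alpha_hat_star, x$beta_hat_star, x$u_net_star,
    x$grid[1], x$grid[2], x$n_ensembles, x$L
  ))
  invisible(x)
}

#' Optimal strategy as a function of antigenic divergence
#'
#' Maps [optimize_strategy()] over a set of scaled divergences `delta_hat`,
#' reusing the dissipation cache across the scan. This is the sweep behind
#' the specificity/deliberation-vs-divergence curves and the phase diagram.
#'
#' @inheritParams optimize_strategy
#' @param delta_hat_list scaled divergences to scan.
#' @param rel_sd relative SD of the drift draws.
#' @param drift_scaling drift clock scaling, see [pathogen_process()].
#' @param seed optional integer; if given, the RNG is re-seeded with
#'   `seed + index` before each divergence so entries are independent of scan
#'   order and share no trajectories.
#' @return A data frame with one row per divergence: `delta_hat`,
#'   `alpha_hat_star`, `beta_hat_star`, `u_net_star`, `k_max`. The individual
#'   `optimization_result` objects are attached as attribute `"fits"`.
#' @export
divergence_scan <- function(kernel_family, cost, delta_hat_list,
                            grid = c(50L, 50L), L = 60L, n_ensembles = 200L,
                            beta_max = 10, rel_sd = 0.05,
                            drift_scaling = "linear", seed = NULL) {
  fits <- vector("list", length(delta_hat_list))
  for (i in seq_along(delta_hat_list)) {
    if (!is.null(seed)) set.seed(seed + i)
    pr <- pathogen_process(delta_hat_list[i] / kernel_family$alpha_max,
                           rel_sd = rel_sd, drift_scaling = drift_scaling)
    fits[[i]] <- optimize_strategy(kernel_family, pr, cost, grid = grid,
                                   L = L, n_ensembles = n_ensembles,
                                   beta_max = beta_max)
  }
  out <- data.frame(
    delta_hat = delta_hat_list,
    alpha_hat_star = vapply(fits, `[[`, numeric(1), "alpha_hat_star"),
    beta_hat_star = vapply(fits, `[[`, numeric(1), "beta_hat_star"),
    u_net_star = vapply(fits, `[[`, numeric(1), "u_net_star"),
    k_max = vapply(fits, `[[`, numeric(1), "k_max")
  )
  attr(out, "fits") <- fits
  out
}

#' Optimal strategy as a function of life expectancy
#'
#' Optimizes the strategy for each life expectancy in `L_list` at a fixed
#' antigenic divergence, and estimates the transition point `c_star`: the
#' life expectancy at which the optimal specificity attains its minimum
#' (cross-reactivity is maximal) before rising again in long-lived hosts.
#'
#' @inheritParams optimize_strategy
#' @param L_list life expectancies (encounters per lifetime), each `>= 2`.
#' @param seed optional integer, as in [divergence_scan()].
#' @return A data frame with columns `L`, `alpha_hat_star`, `beta_hat_star`,
#'   `u_net_star`, plus attributes `"c_star"` and `"fits"`.
#' @export
lifetime_scan <- function(kernel_family, process, cost, L_list,
                          grid = c(50L, 50L), n_ensembles = 200L,
                          beta_max = 10, seed = NULL) {
  fits <- vector("list", length(L_list))
  for (i in seq_along(L_list)) {
    if (!is.null(seed)) set.seed(seed + i)
    fits[[i]] <- optimize_strategy(kernel_family, process, cost, grid = grid,
                                   L = as.integer(L_list[i]),
                                   n_ensembles = n_ensembles,
                                   beta_max = beta_max)
  }
  a <- vapply(fits, `[[`, numeric(1), "alpha_hat_star")
  out <- data.frame(
    L = as.integer(L_list),
    alpha_hat_star = a,
    beta_hat_star = vapply(fits, `[[`, numeric(1), "beta_hat_star"),
    u_net_star = vapply(fits, `[[`, numeric(1), "u_net_star")
  )
  attr(out, "c_star") <- L_list[which.min(a)]
  attr(out, "fits") <- fits
  out
}
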