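#' Simulate a lifetime of sequential infections
#'
#' Runs one host lifetime of `L` encounters with a single evolving pathogen
#' lineage. The primary infection (round 1) triggers a naive response that
#' seeds memory and is not scored. At each later round the drift clock `k`
#' (rounds since the last memory storage) sets the distance distribution of
#' the current antigen from the stored memory; the encounter is scored with
#' its deterministic [net_utility()], and the realized branch is drawn as
#' `memory_used ~ Bernoulli(p_mem)`. A naive response overwrites the single
#' memory slot with receptors centered on the current antigen (resetting
#' `k`); a memory response leaves the stored receptor unchanged. Memory has
#' no intrinsic expiry.
#'
#' @param strategy a [mem_strategy()].
#' @param kernel_family a [kernel_family()] supplying `theta`, `alpha_max`,
#'   `e_max`.
#' @param process a [pathogen_process()].
#' @param cost a [deliberation_cost()].
#' @param L total number of encounters, `>= 2`.
#' @param keep_trace if `TRUE`, attach a per-round data frame.
#' @param use_cache optional [dissipation_interpolant()] for speed; by default
#'   the dissipation is evaluated directly from the profiles each round.
#' @return An object of class `lifetime_result`: a list with
#'   `mean_net_utility` (per scored encounter, utility units),
#'   `mean_net_utility_hat` (divided by `e_max`), `usage_fraction`,
#'   `n_encounters`, and optionally `trace`.
#' @export
simulate_lifetime <- function(strategy, kernel_family, process, cost, L,
                              keep_trace = FALSE, use_cache = NULL) {
  stopifnot(inherits(strategy, "mem_strategy"),
            inherits(kernel_family, "kernel_family"),
            inherits(process, "pathogen_process"),
            inherits(cost, "deliberation_cost"))
  if (L < 2) stop("`L` must be >= 2", call. = FALSE)
  kernel <- affinity_kernel(strategy$alpha, kernel_family$theta,
                            kernel_family$alpha_max, kernel_family$e_max)
  n_scored <- L - 1L
  u_net <- numeric(n_scored)
  k_diss <- numeric(n_scored)
  used <- logical(n_scored)
  dvec <- numeric(n_scored)
  pvec <- numeric(n_scored)
  k <- 1L
  for (i in seq_len(n_scored)) {
    d <- sample_antigenic_distance(process, k)
    out <- net_utility(kernel, d, strategy$beta, cost,
                       beta_max = strategy$beta_max, use_cache = use_cache)
    u_net[i] <- out$u_net
    k_diss[i] <- out$k_diss
    dvec[i] <- d
    pvec[i] <- out$p_mem
    mem <- runif(1L) < out$p_mem
    used[i] <- mem
    k <- if (mem) k + 1L else 1L
  }
  res <- structure(
    list(mean_net_utility = mean(u_net),
         mean_net_utility_hat = mean(u_net) / kernel_family$e_max,
         usage_fraction = mean(used),
         n_encounters = L),
    class = "lifetime_result"
  )
  if (keep_trace) {
    res$trace <- data.frame(
      round = 2:L, d = dvec, p_mem = pvec, memory_used = used,
      u_net = u_net, k_diss = k_diss
    )
  }
  res
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf(
    "<lifetime_result> L = %d, mean U_net_hat = %.4f, memory usage = %.3f\n",
    x$n_encounters, x$mean_net_utility_hat, x$usage_fraction
  ))
  invisible(x)
}

#' Ensemble evaluation of a strategy
#'
#' Mean and standard error of the per-encounter net utility over
#' `n_ensembles` independent lifetimes. Used to compare strategies optimized
#' for one life expectancy when lived at another.
#'
#' @inheritParams simulate_lifetime
#' @param n_ensembles number of independent lifetimes, `>= 1`.
#' @return A list with `mean`, `se`, `mean_hat`, `se_hat`, `usage_fraction`,
#'   `n_ensembles`.
#' @export
evaluate_strategy <- function(strategy, kernel_family, process, cost, L,
                              n_ensembles) {
  stopifnot(n_ensembles >= 1)
  kernel <- affinity_kernel(strategy$alpha, kernel_family$theta,
                            kernel_family$alpha_max, kernel_family$e_max)
  cache <- dissipation_interpolant(kernel, strategy$beta)
  means <- numeric(n_ensembles)
  usage <- numeric(n_ensembles)
  for (r in seq_len(n_ensembles)) {
    sim <- simulate_lifetime(strategy, kernel_family, process, cost, L,
                             use_cache = cache)
    means[r] <- sim$mean_net_utility
    usage[r] <- sim$usage_fraction
  }
  se <- if (n_ensembles > 1) sd(means) / sqrt(n_ensembles) else NA_real_
  list(mean = mean(means), se = se,
       mean_hat = mean(means) / kernel_family$e_max,
       se_hat = se / kernel_family$e_max,
       usage_fraction = mean(usage), n_ensembles = n_ensembles)
}
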