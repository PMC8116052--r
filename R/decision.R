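#' Memory strategy (specificity and deliberation)
#'
#' A single-memory immune strategy: the specificity `alpha` of the receptors
#' it stores and the deliberation factor `beta`, the pathogen load accumulated
#' during the lag in which a stored memory may recognize the antigen before a
#' novel naive response is initiated. `beta` doubles as the
#' information-processing efficacy of the maximum-entropy decision rule and is
#' bounded by `beta_max` (the host must eventually mount a naive response to
#' survive).
#'
#' @param alpha specificity, `[0, alpha_max]` of the kernel it is used with.
#' @param beta deliberation factor, `[0, beta_max]`.
#' @param beta_max upper bound on deliberation.
#' @return An object of class `mem_strategy`.
#' @export
mem_strategy <- function(alpha, beta, beta_max = 10) {
  if (beta < 0 || beta > beta_max) {
    stop("`beta` must lie in [0, beta_max]", call. = FALSE)
  }
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, beta_max = beta_max),
            class = "mem_strategy")
}

#' @export
print.mem_strategy <- function(x, ...) {
  cat(sprintf("<mem_strategy> alpha = %g, beta = %g (beta_hat = %.3f)\n",
              x$alpha, x$beta, x$beta / x$beta_max))
  invisible(x)
}

#' Deliberation cost model
#'
#' The cost of deliberating before a naive response, i.e. the damage incurred
#' while pathogens proliferate unchecked: the naive utility is
#' `-e_max * omega_hat(beta_hat)` with `omega_hat` identically 0 (`"none"`),
#' `omega0_hat * beta_hat` (`"linear"`), or `omega0_hat * beta_hat^2`
#' (`"quadratic"`), where `beta_hat = beta / beta_max`.
#'
#' @param form cost form, one of `"none"`, `"linear"`, `"quadratic"`.
#' @param omega0_hat dimensionless amplitude, `>= 0`.
#' @return An object of class `deliberation_cost`.
#' @export
deliberation_cost <- function(form = c("none", "linear", "quadratic"),
                              omega0_hat = 0) {
  form <- match.arg(form)
  if (omega0_hat < 0) stop("`omega0_hat` must be >= 0", call. = FALSE)
  structure(list(form = form, omega0_hat = omega0_hat),
            class = "deliberation_cost")
}

# scaled cost omega_hat(beta_hat); non-negative, non-decreasing in beta_hat
cost_scaled <- function(cost, beta_hat) {
  switch(cost$form,
    none = 0 * beta_hat,
    linear = cost$omega0_hat * beta_hat,
    quadratic = cost$omega0_hat * beta_hat^2
  )
}

# integer code used by the C++ simulators
cost_code <- function(cost) {
  match(cost$form, c("none", "linear", "quadratic")) - 1L
}

#' Effective deliberation time from response kinetics
#'
#' Memory cells start dividing a head-start `tau0` earlier than naive cells
#' and are recruited in `b`-fold larger numbers; both then double every
#' `t_half`. The deliberation time for the naive population to catch up with
#' the memory clone size is
#' \deqn{\tau = \tau_0 + t_{1/2} \ln b / \ln 2.}
#'
#' @param tau0 head-start of memory initiation, days, `> 0`.
#' @param t_half doubling time, days, `> 0`.
#' @param b recruitment-size ratio memory/naive, `> 0`.
#' @return Deliberation time in days.
#' @examples
#' deliberation_time(tau0 = 1, t_half = 0.5, b = 2) # 1.5 days
#' @export
deliberation_time <- function(tau0, t_half, b) {
  if (any(c(tau0, t_half, b) <= 0)) {
    stop("all kinetic parameters must be > 0", call. = FALSE)
  }
  tau0 + t_half * log(b) / log(2)
}

#' Recognition probabilities of memory vs. naive response
#'
#' During the deliberation window the stored memory receptor encounters and
#' binds the antigen at a rate proportional to its affinity, so the
#' probability that no memory recognition occurs and a novel naive response is
#' initiated is `p_naive = exp(-E(d) * beta)`; `p_mem = 1 - p_naive`.
#'
#' @param kernel an [affinity_kernel()].
#' @param d antigenic distance(s) between the memory's cognate antigen and the
#'   infecting antigen.
#' @param beta deliberation factor, `>= 0`.
#' @return A list with vectors `p_mem` and `p_naive`.
#' @export
recognition_probabilities <- function(kernel, d, beta) {
  if (any(beta < 0)) stop("`beta` must be >= 0", call. = FALSE)
  e <- binding_affinity(kernel, d)
  p_naive <- exp(-e * beta)
  list(p_mem = 1 - p_naive, p_naive = p_naive)
}

#' Utilities of memory and naive responses
#'
#' The naive response pays the deliberation cost, `u_naive = -e_max *
#' omega_hat(beta_hat)`; an effective memory response additionally gains the
#' binding affinity to the current antigen, `u_mem = u_naive + E(d)`.
#'
#' @inheritParams recognition_probabilities
#' @param cost a [deliberation_cost()].
#' @param beta_max bound used to scale `beta` inside the cost.
#' @return A list with vectors `u_mem` and `u_naive`.
#' @export
utilities <- function(kernel, d, beta, cost, beta_max = 10) {
  u_naive <- -kernel$e_max * cost_scaled(cost, beta / beta_max)
  e <- binding_affinity(kernel, d)
  list(u_mem = u_naive + e, u_naive = rep_len(u_naive, length(e)))
}

#' Maximum-entropy decision distribution
#'
#' Probability of choosing the memory action for a rational but constrained
#' decision-maker with processing efficacy `beta` and prior `q0_mem`:
#' `q_mem = q0 e^{beta u_mem} / (q0 e^{beta u_mem} + (1-q0) e^{beta u_naive})`,
#' a logistic function of `beta * (u_mem - u_naive)` for the default uniform
#' prior. Computed in log space, finite for `|beta * dU|` up to at least 1e3.
#'
#' @param u_mem,u_naive action utilities.
#' @param beta processing efficacy (deliberation factor), `>= 0`.
#' @param q0_mem prior probability of the memory action (default uniform).
#' @return `q_mem`, vectorized.
#' @export
decision_distribution <- function(u_mem, u_naive, beta, q0_mem = 0.5) {
  if (any(beta < 0)) stop("`beta` must be >= 0", call. = FALSE)
  if (any(q0_mem <= 0 | q0_mem >= 1)) {
    stop("`q0_mem` must be in (0, 1)", call. = FALSE)
  }
  # logit of prior shifts the logistic; uniform prior leaves it centered
  stats::plogis(beta * (u_mem - u_naive) + log(q0_mem / (1 - q0_mem)))
}

#' Utility gap implied by the recognition kinetics
#'
#' Equating the maximum-entropy decision probability with the kinetic
#' recognition probability `p_mem = 1 - exp(-E beta)` fixes the utility gap
#' \deqn{\Delta U = \log(e^{E\beta} - 1) / \beta.}
#' At `E beta = ln 2` the two actions are exactly indifferent; for
#' `E beta >> 1` the gap approaches the affinity `E`.
#'
#' @param e binding affinity (or affinities) of the memory to the antigen.
#' @param beta deliberation factor, with `e * beta > 0`.
#' @return `dU = u_mem - u_naive`. For `e * beta = 0` the gap is `-Inf`
#'   (memory is never used); returned as `-Inf` with a warning suppressed
#'   contract rather than an error.
#' @export
utility_gap_from_recognition <- function(e, beta) {
  if (any(e < 0) || any(beta < 0)) {
    stop("`e` and `beta` must be >= 0", call. = FALSE)
  }
  x <- e * beta
  # log(exp(x) - 1) = x + log1p(-exp(-x)), stable for large x
  out <- ifelse(x > 0, (x + log1p(-exp(-x))) / beta, -Inf)
  out
}
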