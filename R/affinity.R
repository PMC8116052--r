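#' Affinity/cross-reactivity tradeoff kernel
#'
#' Constructs the receptor binding kernel
#' \deqn{E_{\alpha,\theta}(d) = E_{max} \frac{\alpha}{\alpha_{max}}
#'       \exp[-(\alpha d)^\theta],}
#' the affinity of a receptor to an antigen at distance `d` from its cognate
#' antigen in shape space. Peak affinity grows linearly with specificity
#' `alpha` while the cross-reactive range shrinks as `1/alpha`: sharper
#' receptors bind their cognate target more strongly but recognize fewer
#' variants. `theta` sets the profile shape (flat at `theta = 0`, double
#' exponential at 1, Gaussian at 2, top-hat for large `theta`). The
#' proportionality constant is fixed so that the maximally specific receptor
#' (`alpha = alpha_max`) has peak affinity `e_max`, which normalizes net
#' utilities to 1 for conserved antigens at zero cost.
#'
#' @param alpha specificity, in inverse antigenic-distance units; must lie in
#'   `[0, alpha_max]`.
#' @param theta shape factor, dimensionless, `>= 0`.
#' @param alpha_max maximum attainable specificity (same units as `alpha`).
#' @param e_max peak affinity scale in utility units.
#' @return An object of class `affinity_kernel`.
#' @examples
#' k <- affinity_kernel(alpha = 2, theta = 2, alpha_max = 4)
#' binding_affinity(k, d = 0.5) # 0.5 * exp(-1)
#' @export
affinity_kernel <- function(alpha, theta = 2, alpha_max = 4, e_max = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0 || alpha > alpha_max) {
    stop("`alpha` must lie in [0, alpha_max]", call. = FALSE)
  }
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (e_max <= 0) stop("`e_max` must be > 0", call. = FALSE)
  if (alpha_max <= 0) stop("`alpha_max` must be > 0", call. = FALSE)
  structure(
    list(alpha = alpha, theta = theta, alpha_max = alpha_max, e_max = e_max),
    class = "affinity_kernel"
  )
}

#' Kernel family (fixed shape, free specificity)
#'
#' A light container for the kernel parameters that are held fixed while
#' `alpha` is varied by an optimizer: shape `theta`, bound `alpha_max`, and
#' scale `e_max`.
#'
#' @inheritParams affinity_kernel
#' @return An object of class `kernel_family`.
#' @seealso [affinity_kernel()]
#' @export
kernel_family <- function(theta = 2, alpha_max = 4, e_max = 1) {
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (alpha_max <= 0) stop("`alpha_max` must be > 0", call. = FALSE)
  if (e_max <= 0) stop("`e_max` must be > 0", call. = FALSE)
  structure(
    list(theta = theta, alpha_max = alpha_max, e_max = e_max),
    class = "kernel_family"
  )
}

#' @export
print.affinity_kernel <- function(x, ...) {
  cat(sprintf(
    "<affinity_kernel> alpha = %g (alpha_hat = %.3f), theta = %g, e_max = %g\n",
    x$alpha, x$alpha / x$alpha_max, x$theta, x$e_max
  ))
  invisible(x)
}

# exponent of the kernel: (alpha*d)^theta for theta > 0; at theta = 0 the
# profile is exactly flat at the peak height (no tradeoff), so the exponent
# is taken as 0 for every distance (0^0 := 1 never introduces a dip)
.power_term <- function(ad, theta) {
  if (theta == 0) return(rep(0, length(ad)))
  ad^theta
}

#' Binding affinity at an antigenic distance
#'
#' Evaluates the tradeoff kernel at distance `d`. Monotone non-increasing in
#' `d` (for `theta > 0`), with peak `e_max * alpha/alpha_max` at `d = 0`.
#'
#' @param kernel an [affinity_kernel()].
#' @param d antigenic distance(s), `>= 0`.
#' @return Affinity in utility units, vectorized over `d`.
#' @export
binding_affinity <- function(kernel, d) {
  stopifnot(inherits(kernel, "affinity_kernel"))
  if (any(d < 0)) stop("antigenic distance `d` must be >= 0", call. = FALSE)
  kernel$e_max * (kernel$alpha / kernel$alpha_max) *
    exp(-.power_term(kernel$alpha * d, kernel$theta))
}

#' Discretized, normalized binding profile
#'
#' Evaluates the kernel centered at `center` on a uniform grid and normalizes
#' the weights to sum to one, giving the discrete probability profile used in
#' the dissipation (KL) computations. The grid must cover the center.
#'
#' @param kernel an [affinity_kernel()] with `alpha > 0`.
#' @param center antigenic coordinate of the receptor's cognate antigen.
#' @param grid_spec numeric vector `c(lo, hi, n_points)`; `n_points >= 200`.
#' @return An object of class `profile_grid` with fields `positions` and
#'   `weights` (summing to 1).
#' @export
normalized_profile <- function(kernel, center, grid_spec) {
  stopifnot(inherits(kernel, "affinity_kernel"), length(grid_spec) == 3L)
  lo <- grid_spec[[1]]; hi <- grid_spec[[2]]; n <- as.integer(grid_spec[[3]])
  if (hi <= lo) stop("grid_spec: `hi` must exceed `lo`", call. = FALSE)
  if (n < 200L) stop("grid_spec: need n_points >= 200", call. = FALSE)
  if (center < lo || center > hi) {
    stop("grid does not cover the profile center", call. = FALSE)
  }
  if (kernel$alpha == 0) {
    stop("alpha = 0 gives a zero-height profile with undefined normalization",
         call. = FALSE)
  }
  positions <- seq(lo, hi, length.out = n)
  w <- exp(-.power_term(kernel$alpha * abs(positions - center), kernel$theta))
  total <- sum(w)
  if (total <= 0) stop("profile is numerically zero on this grid", call. = FALSE)
  structure(
    list(positions = positions, weights = w / total),
    class = "profile_grid"
  )
}

#' @export
print.profile_grid <- function(x, ...) {
  cat(sprintf(
    "<profile_grid> %d points on [%g, %g], weight sum = %.9f\n",
    length(x$positions), min(x$positions), max(x$positions), sum(x$weights)
  ))
  invisible(x)
}
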