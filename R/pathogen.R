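#' Antigenic drift process
#'
#' The synthetic-data generator: a pathogen lineage diffuses in antigenic
#' shape space, so that `k` infection rounds after a memory was stored the
#' antigenic distance between the stored receptor's cognate antigen and the
#' current antigen is drawn from `Normal(delta * k, rel_sd * delta * k)`,
#' truncated at zero (negative draws are redrawn, not clipped, preserving the
#' stated relative spread). `delta` is the mean antigenic divergence per
#' infection round; the scaled divergence `delta_hat = delta * alpha_max`
#' measures drift in units of the minimal cross-reactive range.
#'
#' The default `drift_scaling = "linear"` grows the mean distance as
#' `delta * k`. The alternative `"sqrt"` grows it as `delta * sqrt(k)`, the
#' root-mean-square displacement of a pure diffusion; both are provided
#' because the two descriptions coincide only at `k = 1`.
#'
#' @param delta mean antigenic divergence per round (distance units), `>= 0`.
#' @param rel_sd relative standard deviation of the drawn distance.
#' @param drift_scaling `"linear"` (default) or `"sqrt"` growth of the mean
#'   with the drift clock `k`.
#' @return An object of class `pathogen_process`.
#' @examples
#' pr <- pathogen_process(delta = 0.05)
#' sample_antigenic_distance(pr, k = 3)
#' @export
pathogen_process <- function(delta, rel_sd = 0.05,
                             drift_scaling = c("linear", "sqrt")) {
  drift_scaling <- match.arg(drift_scaling)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (rel_sd < 0) stop("`rel_sd` must be >= 0", call. = FALSE)
  structure(
    list(delta = delta, rel_sd = rel_sd, drift_scaling = drift_scaling),
    class = "pathogen_process"
  )
}

#' @export
print.pathogen_process <- function(x, ...) {
  cat(sprintf("<pathogen_process> delta = %g, rel_sd = %g, drift = %s\n",
              x$delta, x$rel_sd, x$drift_scaling))
  invisible(x)
}

# mean drift distance after k rounds under the process' scaling rule
.drift_mean <- function(process, k) {
  if (process$drift_scaling == "sqrt") process$delta * sqrt(k)
  else process$delta * k
}

#' Sample the antigenic distance after k rounds of drift
#'
#' @param process a [pathogen_process()].
#' @param k integer number of infection rounds since the current memory was
#'   stored (the drift clock); `k = 0` returns exactly 0.
#' @return A single non-negative antigenic distance. Uses the R RNG.
#' @export
sample_antigenic_distance <- function(process, k) {
  stopifnot(inherits(process, "pathogen_process"))
  if (length(k) != 1L || k < 0 || k != round(k)) {
    stop("`k` must be a non-negative integer", call. = FALSE)
  }
  if (k == 0) return(0)
  mu <- .drift_mean(process, k)
  if (mu == 0) return(0)
  repeat {
    d <- rnorm(1L, mean = mu, sd = process$rel_sd * mu)
    if (d >= 0) return(d)
  }
}

#' Grid or sample of divergence processes
#'
#' Builds `n` drift processes whose scaled divergences `delta_hat` are evenly
#' spaced (default) or uniformly sampled on `[delta_hat_lo, delta_hat_hi]`,
#' converting to distance units via `delta = delta_hat / alpha_max`.
#'
#' @param delta_hat_lo,delta_hat_hi scaled-divergence range, `0 <= lo < hi`
#'   (for `n = 1` with `lo == hi` a single process is returned).
#' @param n number of processes.
#' @param alpha_max maximum specificity used for the unit conversion.
#' @param sampling `"even"` for a deterministic grid, `"uniform"` for random
#'   draws (uses the R RNG).
#' @inheritParams pathogen_process
#' @return A list of [pathogen_process()] objects with a `delta_hat` attribute
#'   on each element.
#' @export
divergence_grid <- function(delta_hat_lo, delta_hat_hi, n, alpha_max = 4,
                            sampling = c("even", "uniform"), rel_sd = 0.05,
                            drift_scaling = "linear") {
  sampling <- match.arg(sampling)
  if (delta_hat_hi < delta_hat_lo) stop("`hi` must be >= `lo`", call. = FALSE)
  if (delta_hat_lo < 0) stop("`lo` must be >= 0", call. = FALSE)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  dh <- if (sampling == "even") {
    if (n == 1L) mean(c(delta_hat_lo, delta_hat_hi))
    else seq(delta_hat_lo, delta_hat_hi, length.out = n)
  } else {
    runif(n, delta_hat_lo, delta_hat_hi)
  }
  lapply(dh, function(h) {
    p <- pathogen_process(delta = h / alpha_max, rel_sd = rel_sd,
                          drift_scaling = drift_scaling)
    attr(p, "delta_hat") <- h
    p
  })
}

#' Export a drift trajectory as a data frame
#'
#' Draws one trajectory of `n_rounds` successive infections with no memory
#' update (the drift clock simply advances), for inspection or CSV export.
#'
#' @inheritParams sample_antigenic_distance
#' @param n_rounds number of rounds to draw.
#' @return A data frame with columns `round`, `k`, `distance`.
#' @export
drift_trajectory <- function(process, n_rounds) {
  k <- seq_len(n_rounds)
  data.frame(
    round = k,
    k = k,
    distance = vapply(k, function(ki) sample_antigenic_distance(process, ki),
                      numeric(1))
  )
}
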