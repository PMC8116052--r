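# Shared fixtures: the canonical parameter set used throughout (Gaussian
# kernel, alpha_max = 4, beta_max = 10) and small constructors.

fam2 <- function() kernel_family(theta = 2, alpha_max = 4, e_max = 1)

lin_cost <- function() deliberation_cost("linear", 0.1)

no_cost <- function() deliberation_cost("none")

proc_dh <- function(delta_hat, alpha_max = 4) {
  pathogen_process(delta = delta_hat / alpha_max)
}

# mean +/- se of repeated stochastic scalar evaluations
mc_mean <- function(n, f) {
  v <- vapply(seq_len(n), function(i) f(), numeric(1))
  list(mean = mean(v), se = sd(v) / sqrt(n))
}
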