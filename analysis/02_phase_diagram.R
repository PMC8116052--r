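#!/usr/bin/env Rscript
# Optimal single-memory strategies against pathogens of increasing antigenic
# divergence, and the net-utility / dissipation surface behind them. For
# each scaled divergence delta_hat the (alpha, beta) grid is swept with
# common random numbers and the argmax strategy recorded; the surface at a
# representative divergence is exported for phase-diagram plotting, with
# cells labelled by dissipation regime (equilibrium memory / non-equilibrium
# memory / equilibrium naive) using the 40% and 70% K_max conventions.
#
# Desk-scale budgets (50x50 grid, 120 ensembles of 60 encounters) resolve
# the argmax to grid resolution in a few minutes.

suppressPackageStartupMessages(library(memstrat))
dir.create("results", showWarnings = FALSE)

seed <- 1L
fam <- kernel_family(theta = 2, alpha_max = 4, e_max = 1)
lin <- deliberation_cost("linear", 0.1)
delta_hats <- seq(0.05, 0.8, by = 0.05)

scan <- divergence_scan(fam, lin, delta_hats, grid = c(50L, 50L), L = 60L,
                        n_ensembles = 120L,
                        seed = substream_seed(seed, "phase-scan"))
write.csv(scan, "results/divergence_scan.csv", row.names = FALSE)

cat("optimal strategy vs divergence:\n")
print(scan, digits = 3)
boundary <- scan$delta_hat[which(scan$alpha_hat_star < 0.95)[1]]
cat(sprintf("\nspecificity first leaves the 5%%-of-maximum band at delta_hat = %.2f\n",
            boundary))

# full surface at a moderately evolving pathogen, with regime labels
fits <- attr(scan, "fits")
mid <- fits[[which.min(abs(scan$delta_hat - 0.4))]]
surf <- mid$surface
k_max <- max(surf$k_diss)
surf$regime <- ifelse(surf$k_diss >= 0.7 * k_max, "non-equilibrium memory",
               ifelse(surf$k_diss >= 0.4 * k_max, "transitional",
               ifelse(surf$usage > 0.5, "equilibrium memory",
                      "equilibrium naive")))
write.csv(surf, "results/utility_surface_dh0.4.csv", row.names = FALSE)
cat(sprintf("surface at delta_hat = 0.4: K_max = %.3f, regimes: %s\n",
            k_max, paste(names(table(surf$regime)), collapse = ", ")))
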