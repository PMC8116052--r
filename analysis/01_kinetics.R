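#!/usr/bin/env Rscript
# Effective deliberation time of the naive response across the measured
# ranges of the three kinetic factors: the memory head start tau0 (1-2 days),
# the recruitment-size ratio b (2-3x), and the doubling time t_half (0.5-2
# days). The catch-up time tau = tau0 + t_half * ln(b)/ln(2) spans roughly
# 1.5-5 days, which is the window the deliberation factor beta integrates
# pathogen load over.

suppressPackageStartupMessages(library(memstrat))
dir.create("results", showWarnings = FALSE)

grid <- expand.grid(tau0 = c(1, 1.5, 2), t_half = c(0.5, 1, 2), b = c(2, 3))
grid$tau <- mapply(deliberation_time, grid$tau0, grid$t_half, grid$b)

write.csv(grid, "results/deliberation_times.csv", row.names = FALSE)
cat(sprintf("deliberation time spans %.2f-%.2f days over the kinetic ranges\n",
            min(grid$tau), max(grid$tau)))
cat(sprintf("fastest kinetics (tau0=1, t_half=0.5, b=2): tau = %.1f days\n",
            deliberation_time(1, 0.5, 2)))
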