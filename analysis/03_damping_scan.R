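#!/usr/bin/env Rscript
# Damping of late-phase oscillations in the dual-feedback model: scan the
# secondary delay tau2 (and the loop strength eps) and locate the most-damped
# configuration.  Writes results/03_damping_scan.json and a tau2 profile CSV.

suppressPackageStartupMessages(library(nfkbdde))
dir.create("results", showWarnings = FALSE)

p <- reference_params()
K <- reference_K()

sc <- damping_scan(p, K = K, tau2_grid = seq(0, 90, by = 7.5),
                   eps_grid = c(0, 0.35, p$eps, 1),
                   t_cut = 360, t_end = 720)
write_results(sc, "results/03_damping_scan.json")

prof <- data.frame(tau2_min = sc$tau2_grid,
                   metric_nM = sc$metric[, as.character(p$eps)])
write_results(prof, "results/03_tau2_profile.csv")

cat("late-oscillation metric (max peak-trough after 6 h), reference eps:\n")
print(prof, row.names = FALSE)
cat(sprintf("argmin: tau2 = %.1f min at eps = %.2f\n",
            sc$argmin[["tau2"]], sc$argmin[["eps"]]))
cat(sprintf("single-loop (eps = 0) metric: %.4f nM\n", sc$metric[1, "0"]))
cat("note: short secondary delays (tau2 below about a quarter of the primary\n")
cat("period, where cos(omega tau2) > 0) damp the late oscillation below the\n")
cat("single-loop level, while tau2 near half the period (45 min) maximally\n")
cat("destabilizes it -- see the methods vignette for the two-delay linear\n")
cat("analysis behind this.\n")
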