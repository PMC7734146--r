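#!/usr/bin/env Rscript
# Excitatory-only network: coarse sweep of the synaptic (g_e) x autaptic
# (g_e_aut) conductance plane at desk scale (N = 200, 8 s, window
# [4, 8] s). Reports the time-averaged order parameter for all /
# autaptic / non-autaptic neurons, the mean ISI coefficient of
# variation, the mean rate and the mean synaptic current per grid point.
# Writes results/excitatory_plane.csv (~15 runs, ~5 min).

library(aeifnet)

dir.create("results", showWarnings = FALSE)

base <- config_excitatory_only()
sw <- sweep_2d(base,
               axis_x = list(param = "g_e", values = c(0.05, 0.1, 0.3)),
               axis_y = list(param = "g_e_aut",
                             values = c(0, 10, 15, 22, 31)),
               metrics = c("R_mean", "R_mean_non", "R_mean_aut",
                           "CV_mean", "F_mean", "I_s_mean"),
               seeds = 1)
write.csv(sw, "results/excitatory_plane.csv", row.names = FALSE)

wide <- reshape(sw[, c("x", "y", "metric", "value")],
                idvar = c("x", "y"), timevar = "metric",
                direction = "wide")
names(wide) <- sub("^value\\.", "", names(wide))
cat("g_e x g_e_aut plane (seed 1):\n")
print(wide, digits = 3, row.names = FALSE)
cat("\nReading: at weak coupling (g_e = 0.05) the autaptic conductance",
    "moves the autaptic subgroup between incoherent and synchronized",
    "regimes; high CV with strong autapses marks the spike-to-burst",
    "transition.\n")
cat("wrote results/excitatory_plane.csv\n")
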