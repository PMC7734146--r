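#!/usr/bin/env Rscript
# Mixed 80/20 excitatory/inhibitory network at strong within-population
# coupling (g_e = 0.5, g_i = 2 nS): sweep of the cross-population
# conductances g_ei x g_ie without autapses, then the same grid with
# strong excitatory autapses (g_e_aut = 30 nS). A minimal
# excitatory-inhibitory interaction suppresses the highly synchronized
# state; excitatory autapses reshape both the synchronization boundary
# and the population rates. Writes results/mixed_plane{,_aut}.csv
# (~18 runs, ~7 min).

library(aeifnet)

dir.create("results", showWarnings = FALSE)

grid_x <- list(param = "g_ei", values = c(0.5, 1.8, 4.5))
grid_y <- list(param = "g_ie", values = c(0.5, 1.5))
mets <- c("R_mean", "F_mean", "F_mean_exc", "F_mean_inh")

for (aut in c(0, 30)) {
  base <- config_mixed(g_e = 0.5, g_i = 2, g_e_aut = aut,
                       g_i_aut = 0)
  sw <- sweep_2d(base, grid_x, grid_y, metrics = mets, seeds = 1)
  f <- if (aut == 0) "results/mixed_plane.csv" else
    "results/mixed_plane_aut.csv"
  write.csv(sw, f, row.names = FALSE)
  wide <- reshape(sw[, c("x", "y", "metric", "value")],
                  idvar = c("x", "y"), timevar = "metric",
                  direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  cat(sprintf("\ng_ei x g_ie plane, g_e_aut = %g nS (seed 1):\n", aut))
  print(wide, digits = 3, row.names = FALSE)
  cat("wrote", f, "\n")
}
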