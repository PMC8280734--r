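#!/usr/bin/env Rscript
# Free-energy reconstruction along the carrier-membrane separation:
# plan the standard 51-window umbrella ladder, draw Boltzmann-exact
# samples from a double-well model surface with the 2000 kJ/mol/nm^2
# restraint, reconstruct with WHAM, and report wells and recovery
# error. Tables under results/pmf/.

suppressPackageStartupMessages(library(nanomem))
out <- "results/pmf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

pmf <- pmf_double_well(z_lo = 0.5, z_hi = 5.6)
centers <- window_plan(5.5, 0.5, 0.1)
wins <- sample_umbrella_windows(pmf, centers, k_bias = 2000,
                                n_samples = 5000, seed = seed)
prof <- wham(wins)
write.csv(as.data.frame(prof), file.path(out, "profile.csv"),
          row.names = FALSE)

occ <- !is.na(prof$G) & prof$count >= 10
truth <- pmf$fn(prof$z[occ])
truth <- truth - mean(truth[prof$z[occ] >= max(prof$z[occ]) - 0.5])
rmsd <- sqrt(mean((prof$G[occ] - truth)^2))
pm <- profile_minimum(prof)

log <- data.frame(
  quantity = c("windows", "samples per window", "WHAM iterations",
               "final residual (kT)", "global minimum z (nm)",
               "minimum depth (kcal/mol)", "RMSD vs truth (kcal/mol)"),
  value = c(length(wins), 5000, attr(prof, "iterations"),
            signif(attr(prof, "residual"), 3), round(pm$z_min, 3),
            round(pm$delta_G, 2), round(rmsd, 3)))
write.csv(log, file.path(out, "convergence.csv"), row.names = FALSE)

cat("Umbrella sampling on the double-well model surface (wells at 1.6\n")
cat("and 3.5 nm, 5 kcal/mol barrier), 51 windows at 0.1 nm spacing:\n")
print(log, row.names = FALSE)
cat(sprintf(paste0(
  "WHAM recovers the contact minimum at %.2f nm with depth %.1f\n",
  "kcal/mol (truth 1.60 nm); profile RMSD against the known surface\n",
  "is %.2f kcal/mol.\n"), pm$z_min, pm$delta_G, rmsd))
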