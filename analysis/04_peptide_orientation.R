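#!/usr/bin/env Rscript
# Orientation of the membranotropic helix on the bilayer: inclination
# and rolling angles of a synthetic surface-bound ensemble whose
# rolling angle is drawn from a wrapped normal centred at 94 degrees
# with 22 degrees spread (the surface-bound binding mode), measured
# back with the angle observables and summarised circularly.

suppressPackageStartupMessages(library(nanomem))
out <- "results/orientation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(1)
n <- 200
phi_true <- rnorm(n, 94, 22) %% 360
theta_true <- rnorm(n, 90, 8)
theta_true <- pmin(150, pmax(30, theta_true))
frames <- lapply(seq_len(n), function(i)
  make_helix(theta_true[i], phi_true[i])$frames[[1]])
tr <- angle_trace(frame_set(frames))
write.csv(tr, file.path(out, "angle_trace.csv"), row.names = FALSE)

s_phi <- angle_summary(tr$phi_roll)
s_theta <- angle_summary(tr$theta_inc)
summary <- data.frame(
  angle = c("theta_inc", "phi_roll"),
  circ_mean_deg = round(c(s_theta[["mean"]], s_phi[["mean"]]), 2),
  circ_sd_deg = round(c(s_theta[["sd"]], s_phi[["sd"]]), 2),
  truth_mean = c(90, 94), truth_sd = c("8 (clipped)", "22"))
write.csv(summary, file.path(out, "angle_summary.csv"),
          row.names = FALSE)

cat("Orientation ensemble of", n, "surface-lying helices:\n")
print(summary, row.names = FALSE)
cat("Measured circular means recover the generator truth; at a rolling\n")
cat("angle near 90 degrees the Trp634 side chain faces the bilayer.\n")
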