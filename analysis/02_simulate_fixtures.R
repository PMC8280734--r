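#!/usr/bin/env Rscript
# Generate the synthetic ground-truth systems the analysis stages
# consume: a pure-PC bilayer, a 55:45 PC:sterol bilayer, an oriented
# helix, and a nanoparticle approach trace. Writes a GRO snapshot per
# system and a JSON manifest of the ground-truth parameters.

suppressPackageStartupMessages({
  library(nanomem)
  library(jsonlite)
})
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

specs <- list(
  popc = bilayer_spec(separation = 4.0, sigma = 0.05, n_frames = 5,
                      seed = seed),
  popc_chol = bilayer_spec(separation = 4.3, sterol_fraction = 0.45,
                           sigma = 0.05, n_frames = 5, seed = seed))

snapshot <- function(fs, path) {
  b <- fs$frames[[1]]$beads
  beads <- data.frame(index = seq_len(nrow(b)), x = b$x, y = b$y,
                      z = b$z, bead_type = substr(b$role, 1, 5),
                      charge = 0, residue_tag = b$residue)
  write_gro(beads, path, box = fs$frames[[1]]$box)
}

for (nm in names(specs)) {
  fs <- make_flat_bilayer(specs[[nm]])
  snapshot(fs, file.path(out, paste0(nm, ".gro")))
}

helix <- make_helix(90, 94)
snapshot(helix, file.path(out, "helix_flat.gro"))

core <- build_core_bonds(place_beads_on_sphere(187, 2.5))
sched <- data.frame(frame = 1:20,
                    z = c(seq(5.0, 1.6, length.out = 12), rep(1.6, 8)))
trace <- make_binding_trace(sched, specs$popc, core)
snapshot(trace, file.path(out, "binding_final_frame.gro"))

manifest <- list(
  seed = seed,
  popc = specs$popc[c("lipids_per_leaflet", "spacing", "separation",
                      "tilt", "sterol_fraction", "sigma", "n_frames")],
  popc_chol = specs$popc_chol[c("lipids_per_leaflet", "spacing",
                                "separation", "tilt", "sterol_fraction",
                                "sigma", "n_frames")],
  helix = list(theta_inc = 90, phi_roll = 94),
  binding = list(schedule_final_z = 1.6, n_frames = nrow(sched)))
write_json(manifest, file.path(out, "manifest.json"),
           auto_unbox = TRUE, pretty = TRUE)

cat("Wrote bilayer, helix and binding-trace fixtures with known truth\n")
cat("parameters to", out, "(see manifest.json).\n")
cat(sprintf("PC bilayer: %d lipids/leaflet, %.1f nm thick; PC:sterol at 55:45.\n",
            specs$popc$lipids_per_leaflet, specs$popc$separation))
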