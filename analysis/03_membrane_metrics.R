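#!/usr/bin/env Rscript
# Membrane metrics on the synthetic systems: 50x50 thickness maps,
# acyl order parameters, Voronoi area per lipid with and without a
# bound nanoparticle, transversal phosphate density, and a
# phosphate-phosphate RDF. Tables go under results/membrane/.

suppressPackageStartupMessages(library(nanomem))
out <- "results/membrane"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

spec <- bilayer_spec(separation = 4.0, sigma = 0.05, n_frames = 5,
                     seed = seed)
popc <- make_flat_bilayer(spec)
core <- build_core_bonds(place_beads_on_sphere(187, 2.5))
bound <- make_binding_trace(data.frame(frame = 1:5, z = rep(1.3, 5)),
                            spec, core)

## thickness
tm <- thickness_map(popc, grid = 50)
write.csv(
  data.frame(ix = rep(seq_len(50), 50), iy = rep(seq_len(50), each = 50),
             thickness_nm = as.vector(tm$values)),
  file.path(out, "thickness_map.csv"), row.names = FALSE)

## order parameter
op <- order_parameter(popc)

## area per lipid
apl_free <- area_per_lipid(popc)
apl_bound <- area_per_lipid(bound)

## transversal density
dens <- transversal_density(popc, bin_width = 0.1)
write.csv(dens, file.path(out, "transversal_density.csv"),
          row.names = FALSE)

## phosphate-phosphate RDF
sel_ph <- bead_selection(role = "phosphate")
rdf <- radial_distribution(popc, sel_ph, sel_ph, bin_width = 0.05)
write.csv(as.data.frame(rdf), file.path(out, "rdf_phosphate.csv"),
          row.names = FALSE)

## binding CV
cv <- cv_trace(bound, bead_selection(role = "core"),
               bead_selection(role = c("phosphate", "tail")))
bind_frame <- detect_binding(cv, threshold = 2.0, dwell = 3)

stats <- data.frame(
  metric = c("mean thickness (nm)", "tail order parameter P2",
             "area per lipid, free membrane (nm^2)",
             "area per lipid, NP bound (nm^2)",
             "upper density peak (nm)", "binding frame (threshold 2 nm)"),
  value = round(c(mean(tm$values), op$mean, apl_free$mean,
                  apl_bound$mean,
                  dens$z[dens$z > 0][which.max(dens$density[dens$z > 0])],
                  bind_frame), 4))
write.csv(stats, file.path(out, "summary.csv"), row.names = FALSE)

cat("Membrane metrics on the synthetic PC bilayer (truth: 4.0 nm thick,\n")
cat("0.64 nm^2 per lipid, tails along the normal):\n")
print(stats, row.names = FALSE)
cat(sprintf(paste0(
  "The thickness map recovers the built separation, P2 is near 1 for\n",
  "the untilted tails, and the bound nanoparticle carves the mean lipid\n",
  "area down from %.3f to %.3f nm^2.\n"),
  apl_free$mean, apl_bound$mean))
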