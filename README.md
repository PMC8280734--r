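# nanomem

Coarse-grained construction and analysis tools for studying how small
peptide-coated metal nanoparticles associate with lipid membranes.

Cell-penetrating peptides such as gH(625-644) are grafted onto ~2.5 nm
metal cores to ferry cargo across cell membranes. At Martini
(coarse-grained bead) resolution, the questions are geometric and
thermodynamic: how is the carrier built, how does the membrane deform
around it, how is the helix oriented on the bilayer, and how deep is
the binding free-energy minimum along the separation coordinate? This
package implements that workflow for computational membrane
biophysicists — the builders, the trajectory metrics, the
free-energy estimator, and synthetic ground-truth generators that
replace cluster-scale MD for testing and development.

## What it computes

* **Carrier topologies** — `n` beads on a Fibonacci sphere lattice
  (default 187 beads, 2.5 nm, hydrophobic `C1`), harmonic bonds to the
  six nearest neighbours and the antipodal bead
  (k<sub>b</sub> = 2250 kJ mol⁻¹ nm⁻²), implicit citrate capping
  (28 sites × −2e = −56e), six helical peptides grafted at the
  cardinal points (+5e each, +30e per carrier), elastic networks
  (k = 500 kJ mol⁻¹ nm⁻², 0.5-0.9 nm), inertia-tensor eccentricity
  e = 1 − I<sub>min</sub>/Ī, and GRO/ITP writers and readers.
* **Membrane metrics** — radial distribution g(r) with minimum-image
  pair counting; acyl order parameter
  P₂ = ⟨(3cos²ω − 1)/2⟩; 50×50 gridded thickness maps (mean z of the
  three nearest phosphates per leaflet); Voronoi area per lipid with
  periodic ghost replication, carrier beads carving but not counting;
  transversal density; the centre-of-mass separation CV; and
  threshold/dwell binding detection.
* **Peptide orientation** — inclination θ_inc of the Leu627→Ala639
  helix axis against the membrane normal and rolling angle φ_roll
  (torsion of z, Trp634→Thr630, Thr630→Thr632), with circular
  statistics for their distributions.
* **Free-energy profiles** — umbrella-window planning
  (5.0 → 0.0 nm every 0.1 nm = 51 windows), Boltzmann-exact synthetic
  window sampling at k_bias = 2000 kJ mol⁻¹ nm⁻², and self-consistent
  WHAM reconstruction in kcal mol⁻¹ with minimum extraction.

## Worked example

```r
library(nanomem)

core  <- build_core_bonds(place_beads_on_sphere(187, 2.5), k_b = 2250)
citnp <- assign_surface_charges(core, n_sites = 28, site_charge = -2)
ghnp  <- graft_peptides(core, synthetic_gh_model(),
                        select_graft_sites(core, 6))
citnp
#> core_topology: 187 beads, 681 bonds, diameter 2.500 nm, total charge -56 e
ghnp
#> assembled_np: 187 core beads + 6 peptides, total charge +30 e
compute_eccentricity(as.matrix(core$beads[, c("x", "y", "z")]))
#> [1] 0.0003338314
```

The 187-bead shell is spherical to an eccentricity of 3×10⁻⁴; the
citrate carrier totals −56e over 28 sites and the peptide carrier +30e
over six grafted helices.

```r
pmf  <- pmf_double_well(z_lo = 0.5, z_hi = 5.6)   # wells 1.6 / 3.5 nm
wins <- sample_umbrella_windows(pmf, window_plan(5.5, 0.5, 0.1),
                                k_bias = 2000, n_samples = 5000, seed = 1)
prof <- wham(wins)
profile_minimum(prof)[c("z_min", "delta_G")]
#> $z_min
#> [1] 1.60897
#>
#> $delta_G
#> [1] -8.186684
```

WHAM places the contact minimum at 1.61 nm with a depth of
−8.2 kcal mol⁻¹ against the dissociated plateau; the generator's true
well is at 1.60 nm, and the profile RMSD against the known surface is
0.15 kcal mol⁻¹ at these sampling conditions.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce
the study workflow end to end, writing tables under `results/`:

1. `01_build_nanoparticles.R` — NP0, CitNP and gHNP structures plus a
   summary table,
2. `02_simulate_fixtures.R` — synthetic bilayers (pure PC and 55:45
   PC:sterol), an oriented helix, a binding trace, with a ground-truth
   manifest,
3. `03_membrane_metrics.R` — thickness, order, area per lipid (free
   and with a bound carrier), density, RDF, binding detection,
4. `04_peptide_orientation.R` — orientation-angle ensemble and
   circular summaries,
5. `05_pmf_reconstruction.R` — the 51-window umbrella ladder and WHAM
   profile with convergence log.

Run each with `Rscript analysis/01_build_nanoparticles.R` (etc.) from
the repository root. The methods vignette
(`vignettes/nanomem-methods.Rmd`) documents the models, conventions
and numerical choices behind every stage.

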