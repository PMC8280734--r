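---
title: "Methods: coarse-grained nanoparticle-membrane construction and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained nanoparticle-membrane construction and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomem)
```

nanomem implements the computational workflow around coarse-grained
(Martini-resolution) models of small peptide-coated metal nanoparticles
associating with lipid bilayers: building the carrier topologies,
measuring membrane and peptide observables on bead trajectories, and
reconstructing binding free-energy profiles from umbrella-sampling
data. Because the multi-microsecond molecular dynamics that produces
real trajectories is far outside the scope of an R package, every
analysis stage is exercised against synthetic systems whose ground
truth is known by construction; the generators are first-class,
tested code, not throwaway fixtures.

## Nanoparticle construction

The metal core is a rigid spherical shell: `n_beads` (default 187)
hydrophobic `C1` beads placed on a sphere of diameter 2.5 nm. The
placement rule is a deterministic Fibonacci (golden-spiral) lattice —
equal-area latitudes, golden-angle azimuths — followed by three
recentring passes that push the centroid below $10^{-3}$ nm while
keeping every bead exactly on the sphere. The lattice is reproducible
and quasi-uniform: the minimum inter-bead chord is $\ge 80\%$ of the
equal-area ideal $\sqrt{4\pi r^2/n}$.

Rigidity comes from a harmonic bond network
($k_b = 2250$ kJ mol$^{-1}$ nm$^{-2}$): each bead is bonded to its six
nearest neighbours and to its radially opposing neighbour. With an odd
bead count no exact antipode exists, so the opposing neighbour is the
bead minimising the distance to the exact antipodal point; one bead
may therefore serve as the partner of two others. Every equilibrium
length $r_0$ is the build-time distance, so the as-built shell is the
energy minimum. The bond graph is verified connected by traversal.

Sphericity is monitored through the eccentricity of the bead cloud,
$e = 1 - I_{\min}/\bar{I}$ computed from the principal moments of
inertia of unit-mass beads. This specific convention (one of several
in use) is fixed and documented here; the as-built 187-bead core gives
$e \approx 3\times10^{-4}$, and $e$ is invariant under rigid rotation
to $10^{-9}$.

Citrate capping is implicit: 28 surface beads receive $-2e$ each
(total $-56e$) rather than explicit ligands, reflecting the stiff
covalent character of citrate complexation on noble-metal surfaces.
Which beads carry charge is not physically determined, so the package
uses greedy farthest-point selection seeded at the first bead —
deterministic, and maximally spread so like charges repel least.

The peptide-coated carrier grafts six copies of the membranotropic
gH(625-644) helix at the cardinal points (the $\pm x, \pm y, \pm z$
axis intersections of the build frame), matching the experimentally
resolved six-peptide coating. Each copy is placed rigidly: the
C-terminal glycine-linker bead sits radially outward from its site
bead at the graft bond length (default: the nearest core inter-bead
spacing), the helix axis points radially outward, the azimuth is the
deterministic by-product of the rotation taking the build axis onto
the site radial, and a harmonic bond (default $k_b$ of the core) ties
linker to site. A steric check rejects placements that bring any
peptide bead within `clash_distance` (default 0.3 nm) of the core.

### The synthetic peptide model

The real model is a Martini v2.2P mapping of the NMR structure of
glycoprotein H residues 625-644; atomistic-to-CG mapping is outside
this package, so `synthetic_gh_model()` constructs a geometrically
ideal stand-in *in code*: one backbone bead per residue on an ideal
$\alpha$-helix (0.15 nm rise, 100° twist, 0.23 nm radius), single
side-chain beads for residues larger than Ala/Gly, a three-glycine
C-terminal linker, backbone and side bonds, and an elastic network
($k = 500$ kJ mol$^{-1}$ nm$^{-2}$ over backbone pairs 0.5-0.9 nm
apart) that pins the secondary structure. The net charge is $+5e$ per
peptide — both arginines, both histidines taken protonated, and the
free N-terminus — so the six-peptide monolayer totals $+30e$.

One model constant deserves mention: side-chain beads sit 0.25 nm
from their backbone bead at a fixed azimuthal offset of $-69.5°$ from
the radial direction. The offset is a one-time calibration chosen so
that the model reproduces the force-field property used to anchor the
rolling-angle convention: at $\varphi_{\mathrm{roll}} \approx 90°$
the Trp634 side chain points at the bilayer interior below the
peptide. The synthetic side-chain directions are otherwise arbitrary,
so fixing this gauge costs nothing and makes the angle observables
physically interpretable.

## Synthetic trajectory generators

`make_flat_bilayer()` builds a two-leaflet membrane on a square
lattice: phosphate planes at $\pm d/2$ (midplane at $z = 0$),
four-bead tails pointing inward at a prescribed tilt, an optional
fraction of sites replaced by single-bead sterol heads just below the
phosphate plane (the 55:45 sterol-containing membrane is
`sterol_fraction = 0.45`), and optional isotropic Gaussian noise.
Defaults — 100 lipids per leaflet on a 0.8 nm lattice (0.64 nm$^2$
per lipid), 4.0 nm phosphate separation — are typical fluid-phase
phosphatidylcholine numbers. The generator provides *known truth*,
not realism: there are no conformational ensembles, no undulations,
no water structure, and tails are straight. Passing tests therefore
demonstrate that the metrics measure what they claim on ideal input,
not that they are robust to every pathology of real trajectories.

`make_helix()` places the synthetic peptide at prescribed orientation
angles by inverse construction: the Leu627→Ala639 axis is rotated
onto the target inclination exactly, then the helix is rolled about
its own axis until the torsion-angle definition returns the requested
rolling angle (coarse scan plus local refinement). Two geometric
caveats, both discovered during implementation and encoded in tests:
rolling the helix by $\delta$ moves the measured rolling angle by
approximately but not exactly $\delta$ (the torsion's middle vector
is not parallel to the axis), and toward inclinations of 0° or 180°
the roll becomes uncontrollable — at the poles an axial rotation
leaves the torsion unchanged entirely. The generator warns when a
requested roll is unattainable; roll-recovery guarantees hold for
inclinations in roughly $[30°, 150°]$, which covers the
surface-bound regime the observable exists for.

`sample_umbrella_windows()` draws collective-variable samples exactly
from $p(z) \propto e^{-[G(z) + \frac{k}{2}(z - z_c)^2]/k_BT}$ by
inverse-CDF interpolation on a fine grid (8192 points). The
cumulative density is trapezoidal: a plain cumulative sum treats grid
weights as point masses and biases every draw by half a grid cell,
which is invisible per window ($\sim$0.3 pm) but — amplified by a
2000 kJ mol$^{-1}$ nm$^{-2}$ restraint — tilts a reconstructed 5 nm
profile by $\sim$0.7 kcal mol$^{-1}$. The corrected sampler matches
adaptive-quadrature moments to $3\times10^{-5}$ nm and an independent
Metropolis chain to total variation $< 0.02$ at $10^5$ samples.
Model surfaces are provided (`pmf_double_well()`, `pmf_harmonic()`,
`pmf_flat()`); the double-well default — wells at 1.6 and 3.5 nm
separated by a 5 kcal mol$^{-1}$ barrier, flattening to zero at large
separation — caricatures a carrier that first contacts and then
embeds into a bilayer.

## Membrane metrics

All metrics use minimum-image distances in the orthorhombic box and a
50 × 50 lateral grid by default.

**Radial distribution function.** Pair-distance histogram of
selection A against selection B normalised by spherical shell volume
and mean B density, so an ideal gas gives $g = 1$; verified bin-exact
against a brute-force $O(n^2)$ loop on 50 random systems. No
anisotropy correction is applied near the membrane, matching common
practice for first-shell structure; first-shell values above 1 are
expected and meaningful only comparatively.

**Order parameter.** $P_2 = \langle(3\cos^2\omega - 1)/2\rangle$ with
$\omega$ the angle between the $z$ axis and the vector joining chain
beads $i-1$ and $i+1$, averaged over time, molecules and beads. The
exact endpoints ($1$, $-0.5$, $0$ at 0°, 90° and the magic angle
54.7356°) are asserted, as are the hard bounds $[-0.5, 1]$.

**Thickness map.** Per grid point and leaflet, the surface height is
the mean $z$ of the three laterally nearest phosphates of that
leaflet; thickness is upper minus lower surface, averaged over
frames. The source description of this rule is one line and
ambiguous about whether the three nearest phosphates are taken per
leaflet or overall; the per-leaflet reading is implemented because
the overall reading degenerates wherever one leaflet dominates the
neighbourhood. Leaflets are assigned by sign of $z$ against the
per-frame phosphate median; sterols follow their head bead.

**Area per lipid.** Per frame, a 2-D Voronoi tessellation (deldir) of
the $x$-$y$ coordinates of upper-leaflet phosphates, upper-leaflet
sterol heads, and any nanocarrier bead whose $z$ lies between the
frame's lowest and highest phosphate. Carrier beads participate in
the tessellation — their footprint carves area out of the lipids —
but are excluded from the reported averages. Lateral periodicity is
handled by 8-neighbour ghost replication, after which the real cells
tile the box exactly; area conservation to $10^{-6}$ relative is
asserted on every frame, and the noise-free lattice reproduces its
closed-form 0.64 nm$^2$ squares.

**Transversal density, CV, binding.** The transversal density is the
per-frame-recentred histogram of selected bead heights about the
phosphate midplane, normalised to integrate to the mean selected
count. The binding collective variable is
$z(\mathrm{COM_{carrier}}) - z(\mathrm{COM_{bilayer}})$ with equal
bead masses. A binding event is the earliest frame starting a run of
at least `dwell` consecutive frames below the threshold — a
deliberately simple rule; empty cells in grid maps are reported as
`NA`, never interpolated.

## Peptide orientation angles

The inclination $\theta_{\mathrm{inc}}$ is the angle between the
Leu627→Ala639 backbone vector and $+z$: with the membrane below, 0°
means the N-terminus points at the membrane, 180° the C-terminus, 90°
a helix lying flat. The rolling angle $\varphi_{\mathrm{roll}}$ is
the torsion between the plane spanned by $z$ and
$v_1 = \mathrm{Trp634} \to \mathrm{Thr630}$ and the plane spanned by
$v_1$ and $v_2 = \mathrm{Thr630} \to \mathrm{Thr632}$, computed with
the atan2 formulation and mapped to $[0°, 360°)$. The three-vector
torsion reading (the two planes share $v_1$) is an interpretation of
a terse definition; it is pinned down operationally by the Trp634
convention above. Distribution summaries use circular statistics
(mean direction, Mardia's $\sqrt{-2\log R}$ spread), the appropriate
treatment for a periodic observable; a wrapped-normal ensemble with
mean 94° and spread 22° is recovered within 2° at $n = 10^4$.

## Free-energy reconstruction

`window_plan()` is the umbrella ladder arithmetic (the standard plan,
5.0 → 0.0 nm every 0.1 nm, gives 51 windows; non-commensurate ranges
are clamped with a warning). `wham()` merges the windows' biased
histograms with the self-consistent WHAM equations, iterating the
per-window shifts to a $10^{-8}$ kT tolerance and failing loudly on
non-convergence or on adjacent windows with no occupied bin in
common.

Numerical choices, each of which was tested rather than assumed:

* **Bin width 0.025 nm.** The biased-sample standard deviation at the
  standard restraint is $\sqrt{k_BT/k} \approx 0.036$ nm; bins wider
  than that (e.g. 0.05 nm, half the window spacing) visibly bias the
  bin-centre reconstruction. Across seeds, truth RMSD on the
  double-well benchmark improves from 0.08-0.32 to 0.07-0.22
  kcal mol$^{-1}$ and agreement with a binless reference estimator
  from 0.05-0.13 to 0.015-0.06 kcal mol$^{-1}$ when moving from 0.05
  to 0.025 nm bins.
* **Bias factors at bin centres.** Analytically bin-averaging the
  bias Boltzmann factor sounds more accurate but is inconsistent with
  reporting per-bin average density, and empirically *tripled* the
  disagreement with the binless reference; the plain bin-centre
  convention is kept.
* **Reference zeroing.** The unbound reference is the mean free
  energy over the 0.5 nm of largest $z$ with occupied bins — the
  flat, dissociated plateau — configurable via `ref_width`. Minimum
  depths are reported relative to that zero.
* **No Jacobian correction.** The 1-D $z$-separation treatment is
  kept as-is; no $2\pi z^2$ volume or entropic correction is applied.
  Absolute association free energies from such profiles are
  semiquantitative by construction.

Energies are kept in kJ mol$^{-1}$ internally (with
$k_B = 0.008314$ kJ mol$^{-1}$ K$^{-1}$, default temperature 310 K)
and profiles reported in kcal mol$^{-1}$ (4.184 kJ per kcal);
`profile_minimum()` locates the global minimum with parabolic
refinement over three bins and flags minima on the domain edge.

WHAM is cross-checked two ways: against the generator's known surface
(RMSD $< 0.3$ kcal mol$^{-1}$ over adequately sampled bins at the
standard 51 × 5000-sample conditions), and against an independent
binless MBAR estimator implemented separately in the test suite
(agreement $< 0.1$ kcal mol$^{-1}$ on shared samples). Statistical,
not systematic, error dominates the remaining truth mismatch: with
0.1 nm spacing and a 0.036 nm window width, adjacent-window overlap
is modest and window-to-window free-energy noise accumulates like a
random walk along the ladder — visible as slow profile drift at the
far end from the reference. That is a property of the prescribed
sampling plan, not of the estimator.

## Problem sizes

The shipped tests and analysis scripts run bilayers of 100 lipids per
leaflet over a handful of frames, umbrella ladders of 51 windows with
1000-5000 samples each, and oracle comparisons on systems of tens of
beads; these sizes were chosen so the whole suite completes in a few
minutes on a single core while leaving every statistical tolerance
comfortably non-degenerate.

## Limitations

* The bilayer generator is a lattice, not an ensemble: metrics that
  depend on realistic lipid disorder (e.g. absolute RDF shapes,
  realistic $P_2$ profiles along the chain) are only checked for
  definition-level correctness.
* The peptide stand-in shares the real model's labels, anchors, net
  charge and helical geometry, but not its mapped bead positions;
  observables that depend on fine side-chain geometry inherit the
  calibrated gauge described above.
* WHAM error bars (bootstrap or otherwise) are not produced; the
  convergence metadata and the benchmark RMSDs are the uncertainty
  statement.
* Binding-time detection is a threshold-dwell rule on the CV trace;
  it is not an attempt to reproduce kinetics.
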