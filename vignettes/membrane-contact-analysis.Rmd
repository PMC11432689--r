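---
title: "Quantifying ligand-membrane engagement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand-membrane engagement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroraft)
```

## The problem

Serotonin is an amphipathic neurotransmitter: it is released at
concentrations above its solubility limit, self-aggregates by aromatic
π-stacking, and interacts with the lipids of the postsynaptic membrane —
gangliosides attract it electrostatically, cholesterol retains it at the
membrane surface. Studying this experimentally combines all-atom membrane
trajectories, Langmuir-monolayer tensiometry and drop-snapshot imaging.
`seroraft` implements the quantitative layer of such a study as reusable,
tested estimators:

* per-frame **membrane-contact scores** and species-wise **protrusion
  profiles** of bilayer trajectories, with **insertion-onset** detection;
* **π-stacking dimer** detection and **dissociation events**, plus a
  geometric contact taxonomy (hydrogen bond, CH-π, van der Waals);
* **CMC estimation** by continuous two-segment break-point regression of
  surface-tension titrations;
* **adsorption-kinetics fits** of surface-pressure traces, with one-way
  ANOVA + Tukey HSD for group comparison;
* **aggregate-area quantification** of grayscale drop snapshots.

Because raw trajectories and tensiometer recordings of such studies are
rarely deposited, the package ships a first-class synthetic-data module
that generates all four data types with *planted ground truth*, so every
estimator can be validated end to end.

## Conventions

Coordinates are in Å with the membrane normal along +z and the upper
leaflet at positive z; times are in ns (trajectories) or min (kinetics);
frame `f` of a trajectory corresponds to `(f - 1) * dt` ns. Trajectories
travel as multi-frame XYZ plus a JSON topology that carries the per-atom
elements and masses, molecule roles (`ligand`, `phospholipid`, `sterol`,
`ganglioside`), leaflet labels, aromatic-ring cycles and hydrogen-bond
donor/acceptor annotations. Hydrogens, when present, are excluded from all
heavy-atom metrics. Inputs are assumed whole-molecule; no periodic-boundary
unwrapping is attempted.

## Membrane metrics

**Average protrusion.** The "membrane surface" of a species is, per frame,
the mean over upper-leaflet molecules of the per-molecule maximum
heavy-atom z. This turns each species into a single surface line per
frame, directly comparable with a ligand's mass-center z: the definition
matches the everyday meaning of "how far the lipid protrudes" and is
trivially auditable.

**Contact score.** A ligand earns +1 in a frame when any of its heavy
atoms lies within `cutoff` (default 4.0 Å, closed interval) of any heavy
atom of a membrane molecule; the per-frame score sums ligands and the
total sums frames. Distance-based contact is the standard, assumption-free
choice; a `com_below` mode (mass-center at or below the protrusion line)
is provided so the two definitions can be compared on the same data.
Whether ganglioside atoms count as membrane surface is a flag
(`include_ganglioside`, default `TRUE`), since either convention is
defensible.

**Insertion onset.** The onset is the first frame where the mass-center
sits at or below the protrusion line for `persistence_frames` consecutive
frames (default 10) *and* in at least `occupancy_min` (default 0.9) of all
frames to the end of the trajectory. The persistence window suppresses
single-frame dips; the tail-occupancy condition encodes "inserts and stays
inserted". Both defaults are package choices — at full planted occupancy
the detected onset is exact to the frame, while at occupancy near the 0.9
threshold detection is conservative (it may report a later frame or none).

**Leaflet assignment** is taken from the topology; the synthetic generator
assigns it at construction. For imported data the importer exposes the
labels explicitly rather than guessing from geometry.

## Interaction geometry

Ring centroids are unweighted means of the ring-atom coordinates; normals
are best-fit plane directions (smallest singular vector), compared
sign-free with angles folded to [0°, 90°]. Two ligands are **π-stacked**
in a frame when some pair of rings has centroid distance ≤ 5.0 Å and
inter-normal angle ≤ 30°. A **dimer forms** when stacking holds for
`dwell_frames` (default 5) consecutive frames and **dissociates** at the
first later time the minimum ring-centroid distance stays ≥ 8.0 Å for the
same dwell — the two-sided dwell is a hysteresis that keeps flickering
frames from being double-counted as events.

The contact taxonomy applies, in priority order:

| class | criterion | defaults |
|---|---|---|
| hbond | donor-acceptor heavy distance; donor-H-acceptor angle when the H is annotated | ≤ 3.5 Å, ≥ 120° |
| ch_pi | apolar partner carbon near a ring centroid, elevated above the ring plane | ≤ 4.0 Å, ≥ 60° |
| vdw | any remaining heavy-atom pair | ≤ 4.0 Å |

A partner atom consumed by a higher class is not re-reported as vdW. The
thresholds are standard literature values, all configurable; visual
criteria used when reading rendered simulation snapshots cannot be
reconstructed, so an explicit, auditable geometric definition is used
instead. The indole of a serotonin-like ligand is treated as two rings
(6- and 5-membered), both tested for stacking and CH-π.

## Tensiometry

**CMC.** Surface tension γ(c) falls with surfactant concentration and is
nearly constant above the CMC. The estimator fits
γ(c) = β₀ + β₁·c + β₂·(c − κ)₊ — a two-segment linear model forced
continuous at the knot κ — and locates κ by an exhaustive SSR search over
midpoints between interior concentrations followed by golden-section
refinement (`optimize`, tol 1e-9) in the bracketing interval; at least 3
points are required on each side. The fit is flagged `degenerate` when
|β₂| < 0.01 mN·m⁻¹·mM⁻¹, i.e. when the two slopes are indistinguishable
and the "break" is an artifact. Analysis runs on the linear concentration
axis by default (matching the usual graphical extrapolation at the curve
break); a log₁₀ axis mode is available. A case-resampling bootstrap
(seeded) yields percentile confidence intervals on request. The estimator
is scale-equivariant and exact on noiseless two-segment data.

**Kinetics.** Monolayer adsorption is modelled as first-order:
π(t) = π₀ + Δπ∞·(1 − e^(−kt)), fitted by Levenberg-Marquardt with Δπ∞ and
k bounded at zero, self-derived starts and a rate-grid fallback;
non-convergence is an error carrying diagnostics, never a silent default.
A perfectly flat trace is reported as Δπ∞ = 0 with k = 0 by convention
(the rate is unidentifiable without signal). `delta_pi_at(60)` gives the
1 h pressure increase commonly used as the comparison endpoint.

**Group statistics** use `stats::aov` and `stats::TukeyHSD` (Tukey-Kramer
for unbalanced designs), re-packaged with the studentized-range q
statistic per pair; all-identical data return F = 0, p = 1 by convention.
The tests validate both against the textbook sums-of-squares formulas.

**Mole-count arithmetic.** At equal spread area and surface pressure the
molecule counts of two monolayer species scale inversely with their
molecular areas, so `monolayer_mole_ratio(area_a, area_b) = area_b /
area_a` gives how many-fold species *a* outnumbers species *b* — e.g.
~40 Å² cholesterol against a ~1000 Å² ganglioside footprint gives 25.

## Imaging

Snapshots are 8-bit grayscale with dark aggregates on a light background.
Segmentation thresholds via Otsu's method (or a fixed threshold), labels
the foreground with 8-connectivity, and discards components below
`min_component_px` (default 25 px) as speckle; an optional ROI polygon
excludes the probe and window reflections. Areas are reported both in px²
and, through the `mm_per_pixel` calibration, mm² — the appropriate unit
depends on the optics, so neither is privileged. Uniform images are
flagged degenerate rather than thresholded arbitrarily. Measured areas are
exactly invariant under 90° rotation and mirroring, and within 2 % of
πr² on synthetic disks of radius ≥ ~20 px (pixelization dominates below
that).

Connected-component labelling is implemented in the package as a
vectorised minimum-label propagation (8-neighbour), because the
segmentation contract specifies diagonal connectivity.

## The synthetic-data module

The generator is a *geometric* stand-in for MD, not a physical
simulation: every downstream metric depends only on distances, heights
and ring orientations, so a static jittered-lattice slab suffices to
validate them.

* **Membrane:** POPC and cholesterol on an 8 Å lattice per leaflet
  (defaults 32 + 32, phosphate planes at ±20 Å), lateral Gaussian
  placement jitter (σ = 0.5 Å), exact z heights: choline tops at ±21 Å,
  sterol OH slightly below the phosphate plane, ganglioside headgroups
  rising above the phospholipid maximum by +12 Å (GM1-like), +8 Å
  (GM3-like) or +16 Å (GT1b-like) — heights chosen only to make the three
  geometries distinguishable, echoing their different glycan bulk.
  Gangliosides are placed in the upper leaflet only, as in the outer
  leaflet of a postsynaptic membrane.
* **Ligands:** a 13-heavy-atom serotonin-like template (fused 6/5-ring
  indole, phenolic OH, ethylamine) with fixed flat orientation. Before
  the onset frame a ligand random-walks (reflected Gaussian steps,
  σ = 1.0 Å/frame) above a floor well clear of the tallest headgroup;
  from the onset frame on, each frame is a contact frame independently
  with probability `contact_fraction`, so the expected score contribution
  is exactly p·(F − f₀ + 1) with binomial spread. Contact frames tether
  the ligand flat among the headgroups: mass-center ~1.5 Å below the
  protrusion line and within ~2 Å of a phosphate, guaranteeing both the
  distance-contact and the insertion criteria; non-contact frames hover
  ≥ 5 Å clear of every membrane atom.
* **Dimers:** two member ligands hold parallel rings at exactly 3.5 Å
  centroid separation from `stacked_from_frame` until
  `dissociate_at_frame`, then sit at anchors ≥ 8 Å apart — formation and
  dissociation are therefore recoverable to the frame.
* **Curves and images** follow their stated models (two-segment linear;
  first-order adsorption; shrinking disks) plus Gaussian noise.

Default trajectory size is 250 frames at 0.1 ns/frame (25 ns): the frame
stride behind published score totals is generally unstated, and this
choice is the package's own convention, not an assertion about any
particular study.

All randomness flows from one explicit seed per generator
(`withr::with_seed`): identical spec + seed is bit-identical, and no
global RNG state leaks.

**What passing tests do and do not show.** Recovery on these synthetics
demonstrates that the estimators are correct implementations of their
definitions and are robust at the stated noise levels. It does not show
that a 4 Å heavy-atom cutoff (or any other threshold) is the *right*
reading of a particular rendered trajectory, nor does the slab capture
lipid diffusion, membrane undulation, rotational ligand dynamics or
correlated contact runs of real MD. One visible artifact of the fixed
flat ligand orientation is that two independent ligands tethered to
nearby lattice sites can transiently satisfy the parallel-ring stacking
criterion; stacking analysis on synthetic data is therefore meaningful
chiefly for planted dimers.

## Numerical and degenerate-input choices

* Ties at exactly a distance cutoff count as contact (closed intervals).
* Zero-frame trajectories are legal and round-trip through XYZ as empty
  files; XYZ coordinates carry three decimals, so round-trips are exact
  to 1e-3 Å.
* The knot search keeps the better of the grid and refined optima, so a
  noiseless break on a grid midpoint is recovered exactly.
* `estimate_cmc` requires ≥ 6 points; `fit_binding_kinetics` ≥ 5;
  groups of < 2 replicates are rejected, not silently dropped.
* Insertion when the series never dips: onset is `NA`, not an error.

## Problem sizes used by the test-suite

The shipped tests validate against brute-force oracles on 100 random
systems of ≤ 8 frames and ≤ ~90 atoms (loops over every atom pair, ring
pair and rule), recover planted contact fractions over 50 seeds (3
binomial-SD band, with the expected rare 3σ exceedance tolerated), sweep
100 noisy titrations for the CMC, and calibrate the ANOVA type-I error on
2,000 null datasets. These sizes make the whole suite run in about a
minute and a half while keeping every check exhaustive at its scale.

## Known limitations

* The membrane is static; protrusion series on synthetic data have no
  frame-to-frame variance, so occupancy statistics near the threshold
  are sharper than they would be on real trajectories.
* Ligand orientation never rotates; CH-π and H-bond geometries on
  synthetic data exercise the classifier through the randomized test
  fixtures rather than the generator.
* Only text formats are read (XYZ, JSON, CSV, PNG; multi-model PDB via
  `bio3d` as a convenience); binary MD formats are out of scope.
* Energetic scoring of contacts is out of scope; the package classifies
  geometry only.

## A compact end-to-end run

```{r, eval = FALSE}
library(seroraft)

# a 25 ns synthetic system with one ligand inserting at 14 ns
sim <- gen_membrane_trajectory(trajectory_spec(
  n_frames = 250, dt = 0.1, n_ligands = 1,
  onset_frame = 141, contact_fraction = 1, seed = 7))
prot <- average_protrusion_series(sim$trajectory, sim$topology, "POPC")
com <- ligand_com_series(sim$trajectory, sim$topology,
                         sim$truth$ligand_molecule_ids[1])
detect_insertion_onset(com, prot)

# CMC from a noisy synthetic titration
est <- estimate_cmc(gen_tensiometry_curve(
  tensiometry_spec(break_point = 42, noise_sigma = 0.3, seed = 1))$curve)
est$cmc

# the five-system comparison scenario shipped with the package
cfg <- system.file("extdata", "five_system_scenario.yaml",
                   package = "seroraft")
bundle <- run_pipeline(cfg)
cat(generate_report(bundle, "markdown"))
```
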