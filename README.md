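# seroraft

Quantitative analysis of how an amphipathic neurotransmitter such as
serotonin engages model lipid membranes — for structural-bioinformatics
and membrane-biophysics groups who combine bilayer trajectories,
Langmuir-monolayer tensiometry and drop-snapshot imaging and want the
downstream numbers to come from tested, auditable estimators rather than
one-off scripts.

## What it computes

**Trajectory metrics** (multi-frame XYZ + JSON topology, Å/ns, membrane
normal = +z):

- *Average protrusion* of a lipid species: per frame, the mean over
  upper-leaflet molecules of the per-molecule maximum heavy-atom z —
  the "membrane surface" line.
- *Contact score*: a ligand scores +1 in a frame when any heavy atom is
  within a cutoff (default 4.0 Å) of any membrane heavy atom; totals are
  summed over frames and ligands.
- *Insertion onset*: first frame f where the ligand mass-center z stays
  at or below the protrusion line for ≥ 10 consecutive frames and in
  ≥ 90 % of frames from f to the end.
- *π-stacking dimers*: rings stacked when centroid distance ≤ 5 Å and
  inter-normal angle ≤ 30° (sign-free, folded to [0°, 90°]); dissociation
  called when the minimum ring-centroid distance holds ≥ 8 Å for a dwell
  window, with hysteresis against flicker.
- *Contact taxonomy*: hbond (donor–acceptor ≤ 3.5 Å, D–H–A ≥ 120° when
  the hydrogen is annotated) > CH-π (apolar C ≤ 4 Å from a ring centroid,
  elevation ≥ 60°) > van der Waals (≤ 4 Å), mutually exclusive in that
  order.

**Tensiometry**: the critical micelle concentration (CMC) as the knot κ of
a continuous two-segment fit γ(c) = β₀ + β₁·c + β₂·(c − κ)₊ minimizing the
SSR over candidate knots (grid + golden-section refinement), with a
degenerate-slope flag and optional bootstrap CI; first-order adsorption
kinetics π(t) = π₀ + Δπ∞(1 − e^(−kt)) by bounded Levenberg–Marquardt;
one-way ANOVA with Tukey HSD; monolayer mole-ratio arithmetic
(N_a/N_b = area_b/area_a).

**Imaging**: Otsu or fixed thresholding of grayscale snapshots,
8-connected component labelling with speckle rejection and optional ROI
polygon; aggregate areas in px² and mm².

**Synthetic data**: seeded generators for all four data types with planted
ground truth (contact schedules, insertion onsets, dimer lifetimes,
break-points, rate constants, disk areas), used throughout the test suite
and available to users as fixtures.

## Worked example

```r
library(seroraft)

# a 25 ns synthetic membrane system, one ligand planted to insert at 14 ns
sim <- gen_membrane_trajectory(trajectory_spec(
  n_frames = 250, dt = 0.1, n_ligands = 1,
  onset_frame = 141, contact_fraction = 1, seed = 7))

prot <- average_protrusion_series(sim$trajectory, sim$topology, "POPC")
com  <- ligand_com_series(sim$trajectory, sim$topology,
                          sim$truth$ligand_molecule_ids[1])
detect_insertion_onset(com, prot)
#> <srf_insertion_report> onset at frame 141 (t = 14 ns), occupancy 1.000

compute_contact_score(sim$trajectory, sim$topology)
#> <srf_contact_score> total 110 over 250 frames x 1 ligands (distance mode, cutoff 4 A)
#>   per ligand: 129=110

# CMC from a noisy synthetic titration (true break 42 mM, sigma 0.3 mN/m)
estimate_cmc(gen_tensiometry_curve(tensiometry_spec(
  break_point = 42, noise_sigma = 0.3, seed = 1))$curve)
#> <srf_cmc_estimate> cmc = 42.434 mM (slopes -0.4922 / -0.0009 mN/m per mM)

# adsorption kinetics (true delta_pi_inf 10 mN/m, k 0.1 /min, sigma 0.2)
fit_binding_kinetics(gen_kinetics_curve(kinetics_spec(
  pi0 = 20, delta_pi_inf = 10, rate_k = 0.1,
  noise_sigma = 0.2, seed = 1))$curve)
#> <srf_kinetics_fit> pi0 = 20.018, delta_pi_inf = 9.999 mN/m, k = 0.1002 /min  (delta_pi at 60 min: 9.975 mN/m)
```

The onset report reads: the ligand's mass center first drops below the
POPC protrusion line at frame 141 (14.0 ns) and stays inserted for the
rest of the trajectory (occupancy 1.0). The contact score counts the 110
frames in which the ligand touched the membrane within 4 Å. The CMC
estimate lands 0.4 mM from the planted break under realistic noise, and
the kinetics fit recovers the planted asymptote and rate to a fraction of
a percent; `delta_pi_at(60)` is the 1 h surface-pressure increase used as
a comparison endpoint.

A complete multi-system comparison (five membrane compositions, CMC,
kinetics and imaging in one report) ships as a YAML scenario:

```r
bundle <- run_pipeline(system.file("extdata", "five_system_scenario.yaml",
                                   package = "seroraft"))
cat(generate_report(bundle, "markdown"))
```

A thin command-line front end (`exec/seroraft`) exposes the same
operations as subcommands (`pipeline`, `simulate-traj`, `score`,
`insertion`, `cmc`, `kinetics`, `stats`, `area`).

## Vignette

`vignettes/membrane-contact-analysis.Rmd` documents the models, every
tunable threshold with units and defaults, what the synthetic generators
do and do not emulate, and the numerical choices and known limitations.
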