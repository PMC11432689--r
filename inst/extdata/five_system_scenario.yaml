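# Fully synthetic five-system membrane comparison.
#
# Planted contact fractions are chosen to reproduce the qualitative
# contact-score ordering GM3 > GM1 > POPC/cholesterol > POPC > GT1b and
# the ganglioside-dependent insertion onsets (early for GM1/GM3, late for
# GT1b); the absolute totals are NOT calibrated to any measured system.
scenario: five-system synthetic membrane comparison
seed: 1
metrics:
  cutoff: 4.0
  persistence_frames: 10
  occupancy_min: 0.9
systems:
  - name: GM3
    n_frames: 250
    dt: 0.1
    n_ganglioside: 4
    ganglioside_kind: GM3-like
    n_ligands: 3
    onset_frame: 31      # 3 ns
    contact_fraction: 0.9
  - name: GM1
    n_frames: 250
    dt: 0.1
    n_ganglioside: 4
    ganglioside_kind: GM1-like
    n_ligands: 3
    onset_frame: 21      # 2 ns
    contact_fraction: 0.7
  - name: POPC-cholesterol
    n_frames: 250
    dt: 0.1
    n_ligands: 3
    onset_frame: 1
    contact_fraction: 0.55
  - name: POPC
    n_frames: 250
    dt: 0.1
    n_chol: 0
    n_ligands: 3
    onset_frame: 1
    contact_fraction: 0.3
  - name: GT1b
    n_frames: 250
    dt: 0.1
    n_ganglioside: 4
    ganglioside_kind: GT1b-like
    n_ligands: 3
    onset_frame: 141     # 14 ns
    contact_fraction: 0.12
tensiometry:
  break_point: 42
  slope_below: -0.5
  slope_above: 0
  noise_sigma: 0.3
kinetics:
  pi0: 20
  delta_pi_inf: 10
  rate_k: 0.1
  duration: 60
  sampling: 0.5
  noise_sigma: 0.2
images:
  width: 200
  height: 200
  mm_per_pixel: 0.02
  shrink_rate: 10
  n_frames: 4
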