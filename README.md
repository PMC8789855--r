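# lipogate

Analysis toolkit for studying how membrane lipid acyl tails operate the
hydrophobic gate of an inwardly rectifying potassium (Kir) channel.

Kir-type channels are occluded by a collar of four symmetry-related leucine
side chains. Lipid tails entering through lateral fenestrations can engage
this collar and lever it open; whether they do — and how often — links pore
geometry, ion permeation, single-channel kinetics and bulk flux. `lipogate`
implements the complete quantitative chain natively in R:

* **Trajectory I/O** — multi-MODEL PDB and a tabular CSV dialect, atom
  selections, role tags, minimum-image distances (`read_trajectory()`,
  `selection()`, `resolve()`).
* **Pore geometry** — HOLE-style radius profiles
  `r(z) = max_(x,y) min_i (|p − x_i| − vdw_i)`; collar aperture couplets
  (D1, D2) between opposite-subunit Cδ midpoints, (D1, D2) → (D2, D1)
  symmetrization, shoelace aperture areas; Kabsch superposition RMSD
  (`radius_profile()`, `collar_geometry()`, `superpose_rmsd()`).
* **Lipid census** — tail engagement of the collar at a 5.0 Å cutoff,
  occupancy distributions, head-group contacts at the canonical
  His/Trp/Arg site, leaflet-resolved head-group density maps
  (`engaged_tails()`, `occupancy_distribution()`, `headgroup_density_map()`).
* **Permeation** — reaction coordinate relative to the Thr96 centre of
  mass, hysteretic crossing detection, hydration numbers within 3.0 Å,
  conduction-conditioned statistics (`detect_crossings()`,
  `coordination_number()`).
* **Free energy** — native WHAM for umbrella windows,
  ρ(z) = Σᵢnᵢ(z) / ΣᵢNᵢ exp[(fᵢ − wᵢ(z))/k_BT], with Bayesian-bootstrap
  confidence bands and barrier extraction (`wham()`,
  `bayesian_bootstrap()`, `barrier_height()`).
* **Single-channel HMM** — Baum–Welch fitting of three conductance classes
  (closed / substate / open) with compiled forward–backward and Viterbi
  passes, amplitude histograms, dwell tables, burst-wise open probability
  Po and substate probability Ps, I–V summaries (`fit_hmm()`, `idealize()`,
  `burst_metrics()`).
* **Flux assays** — percent normalization between the protonophore anchor
  (100%) and the valinomycin floor (0%), first-order decay fits
  F(t) = F∞ + (F₀ − F∞)e^(−kt), and Dunnett many-to-one comparisons with
  Monte Carlo multivariate-t adjustment (`normalize_flux()`, `fit_decay()`,
  `compare_to_control()`).
* **Synthetic data** — seeded generators for gated-pore trajectories,
  umbrella windows from overdamped Langevin dynamics, aggregated-Markov
  three-level current traces, and flux curves, so every stage is testable
  without MD or patch-clamp data (`generate_pore_trajectory()`,
  `generate_umbrella_samples()`, `generate_channel_trace()`,
  `generate_flux_curve()`).

## Worked example

The demo stage runs the whole synthetic pipeline — pore trajectory, census,
crossing detection, WHAM, HMM idealization and a flux fit — from one seed:

```r
library(lipogate)
demo_pipeline(out_dir = "lipogate_demo", seed = 7)
```

`lipogate_demo/summary.json` then contains (seed 7, 2000 frames):

```json
{
  "n_frames": 2000,
  "occupancy_mode": 2,
  "n_crossings": 3,
  "pmf_min_G": 0,
  "pmf_barrier": 12.6261266858775,
  "Po": 0.693666666666667,
  "Ps": 0.2071,
  "flux_k": 0.0996878359597386
}
```

Reading those numbers: the modal number of engaged lipid tails per tetramer
is 2; the ion crossed the collar plane 3 times in 2000 frames; the WHAM
profile is normalized to min 0 and recovers the 12 kJ/mol double-well test
barrier to within its sampling error; the idealized synthetic "decyl"
recording spends 69% of burst time fully open and 21% in the substate,
matching the preset's designed stationary occupancies; and the flux curve
generated with k = 0.1 min⁻¹ fits back to 0.0997 min⁻¹.

Per-stage runs are available both as functions (`run_stage("wham", ...)`)
and through the thin command-line wrapper `inst/scripts/lipogate`.

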