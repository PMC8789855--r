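---
title: "Models and methods behind lipogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lipogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipogate)
```

## The scientific problem

Inwardly rectifying potassium (Kir) channels carry a ring of four branched
aliphatic side chains — in KirBac-type channels a leucine collar — that
physically occludes the conduction pathway between the inner cavity and the
cytoplasmic vestibule. The hypothesis this package supports analytically is
that membrane lipid acyl tails, reaching the collar through lateral
fenestrations, lever the leucine side chains apart: the collar opens, and
K+ conduction becomes possible, in proportion to how many fenestrations are
occupied by a tail long enough to engage the collar.

Testing that idea combines several very different measurements: pore
geometry from structures and trajectories, free-energy profiles from
umbrella sampling, tail/head-group contact censuses, single-channel
electrophysiology idealized with hidden Markov models, and liposome flux
assays. `lipogate` implements each analysis natively and ships seeded
generators that emulate the statistical structure of every input, so the
entire pipeline is testable end to end on a desktop with no simulation or
recording data.

## Conventions

Coordinates are in ångström, energies in kJ/mol, times in ps (trajectories),
seconds (current traces) or minutes (flux assays). Frames are 0-indexed.
The permeation reaction coordinate is the signed z offset of the tracked ion
from the mass-weighted centre of mass of the four Thr96 residues at the base
of the selectivity filter; no global polarity of the z axis is assumed, so
axis direction is per-dataset configuration. A side-chain-only reference
variant (`sidechain_only`) is provided because figure and methods
descriptions of the reference group differ in whether backbone atoms are
included; the default uses all atoms of the four residues.

Van der Waals radii come from a bundled Bondi-style table with per-element
overrides; elements not in the table get a carbon-like 1.70 Å default.
Distances honour the minimum-image convention whenever a frame carries an
orthorhombic box; non-periodic toy data simply omit the box.

## Pore geometry

`radius_profile()` computes a HOLE-style profile: at each z the pore radius
is the largest sphere centred in that plane that touches no atom,
`max_(x,y) min_i (|p - x_i| - vdw_i)`, found by a 0.25 Å coarse grid search
followed by Nelder–Mead refinement. The radius is capped at half the box
diagonal and flagged when the optimizer escapes the wall, which is the
honest answer for planes outside the structure.

`collar_geometry()` reduces the collar to four points midway between the
two delta carbons of each leucine side chain. Subunits are ordered by
azimuth about the pore axis; D1 and D2 are the two diagonals between
opposite midpoints, and the aperture area is the planar shoelace area of the
azimuth-ordered midpoints. Because the D1/D2 labelling is arbitrary,
`symmetrize_couplets()` duplicates every couplet (D1, D2) as (D2, D1) before
histogramming; the resulting 2-D histograms are exactly mirror-symmetric,
which the tests assert at integer precision. Two open choices were settled
as follows: the aperture statistic is the plain planar polygon area (a
vdW-shrunk variant sits behind `vdw_shrink = TRUE`, since published
"cross-sectional area" values do not state whether atomic radii were
subtracted), and 2-D histograms use square bins — hexagonal binning is a
plotting choice, not a statistic, and counts are only ever compared within
one binning scheme.

`superpose_rmsd()` is a standard Kabsch (SVD) least-squares superposition
over atoms matched by chain/residue/name, validated in the tests against an
independent quaternion-method implementation.

## Contact censuses

A lipid tail *engages* the collar when any of its counted atoms (by default
the terminal acyl carbon) lies within 5.0 Å of any collar side-chain atom.
Engagement, occupancy distributions, head-group site contacts (5.0 Å of the
His/Trp/Arg pocket) and leaflet-resolved head-group density maps are all
plain counting operations, and every one of them is tested for exact
equality against an O(N²) brute-force recount. Two ambiguities in the
published definitions are preserved rather than resolved: which tail atoms
define the "terminus" (configurable, default the last chain carbon), and
whether occupancy is counted per tail or per lipid (both are available; the
per-tail count is the default reported quantity).

## Permeation

`detect_crossings()` uses a two-threshold state machine: an event is
recorded only when the ion moves from below `plane - h` to above `plane + h`
(or the reverse) without re-entering its origin band. Hysteresis (default
h = 2 Å) makes double counting of diffusive recrossings impossible by
construction. Hydration is the count of water oxygens within 3.0 Å of the
ion; `coordination_histogram()` reports per-z columns normalized to exactly
100%. Conduction-conditioned statistics select the transit frames of each
event (optionally widened), which is how the "conducting frames have wider
apertures" contrast is computed.

## WHAM free-energy estimation

`wham()` implements the standard self-consistent weighted-histogram
equations for harmonically biased windows,

$$\rho(z_b) = \frac{\sum_i n_i(z_b)}{\sum_i N_i e^{(f_i - w_i(z_b))/k_BT}},
\qquad
f_i = -k_BT \ln \sum_b \rho(z_b)\, e^{-w_i(z_b)/k_BT},$$

iterated until the largest change in any window free energy falls below the
tolerance (default 1e-6 kJ/mol), with G = −k_BT ln ρ shifted to min 0. Force
constants are accepted in the MD-engine convention (kJ mol⁻¹ nm⁻²) and
converted once. Non-overlapping window groups are a hard error (the
histograms carry no information linking them); a gap between adjacent
windows merely warns. Non-convergence within `max_iter` returns a flagged
profile rather than throwing, so long bootstrap runs degrade gracefully.

Uncertainty uses the Bayesian bootstrap: each replicate draws
Dirichlet(1, …, 1) weights over *whole windows* and re-solves WHAM
(warm-started from the full-data solution); the band is the central 95%
across replicates after aligning each to min zero. The resampling unit is
not stated in the published method, so per-sample weighting is available via
`unit = "sample"`. The default temperature everywhere is 303.15 K, matching
the thermostat setting of the simulations this mirrors.

Published barrier magnitudes for the real channel (≈13 kJ/mol at the
leucine collar, and the mutant/derivative variants) require the original
microsecond all-atom trajectories — which also carried a static external
field that this estimator deliberately does not model — so they are treated
as reference annotations, not as targets. Correctness is instead
demonstrated on a synthetic double well, where quadrature of
exp(−U/k_BT) is an exact oracle: with 41 windows at 0.5 Å spacing,
k = 3000 kJ mol⁻¹ nm⁻², and 5000 decorrelated samples per window, the
recovered barrier sits within 1 kJ/mol of the quadrature truth.

## Single-channel HMM

`fit_hmm()` is Baum–Welch EM with Gaussian emissions over a fixed number of
conductance classes (default three: closed C, substate S, open O), run from
several seeded initializations with the best likelihood kept; the scaled
forward–backward and Viterbi passes are compiled (Rcpp), and the EM
log-likelihood trace is asserted non-decreasing in the tests. States are
always relabelled by sorted level magnitude, so results are invariant to
initialization permutations. Initial means come from k-means centres seeded
by range-spread quantiles — occupancy quantiles alone can start two
components on top of a dominant level. Emission variances are floored
(default 1e-3 pA) with a warning instead of collapsing onto single samples.

`idealize()` is the Viterbi maximum-likelihood path with a run-length dwell
table. `burst_metrics()` separates bursts at closed dwells longer than
t_crit (default 100 ms — the published analysis does not state its
criterion, so it is exposed as a parameter), trims leading/trailing closed
samples, and reports Po and Ps as open- and substate-class fractions of
burst time. Simplifications relative to specialised electrophysiology
packages are deliberate and documented: no modelling of filter-induced noise
correlation and no missed-event (dead-time) correction.

The packaged kinetic presets (`decyl`, `octyl`, `hexyl`) are reversible
birth–death schemes C↔S↔O constructed by detailed balance so that the
stationary open-class occupancy *equals* the burst-wise open probabilities
reported for the corresponding alkyl-derivatised constructs (0.69, 0.41,
0.46); `stationary_distribution()` verifies this by eigen-analysis. Closed
dwells are kept short (mean 12.5 ms) so that bursts span nearly the whole
record and the burst-wise Po of a long trace converges on the stationary
occupancy; recovery of Po within ±0.03 from 120 s of noisy synthetic record
is the package's acceptance bar for this stage.

## Flux assays

`normalize_flux()` anchors the percent scale at the fluorescence at
protonophore addition (100%, mean over the final half-minute of baseline)
and the post-valinomycin plateau (0%, mean of the final five minutes, with a
|slope| < 0.5 %/min attainment check). The map is affine, hence idempotent
and invariant to detector gain/offset. `fit_decay()` fits
F(t) = F∞ + (F₀ − F∞)e^(−kt) over 0–35 min by nonlinear least squares with a
Levenberg–Marquardt fallback and a grid-restart last resort. Because the
published "change in fluorescence" could mean either the fitted span over
the window or the fitted amplitude, both are reported (`dF_window`,
`dF_amplitude`); `dF` values are taken from the fitted curve, not raw
endpoints, for noise robustness.

`compare_to_control()` implements two-sided Dunnett many-to-one comparisons
with the pooled-variance statistics and the one-factor equicorrelation
structure ρᵢⱼ = bᵢbⱼ, bᵢ = √(nᵢ/(nᵢ+n₀)); family-wise p-values and
simultaneous intervals come from seeded Monte Carlo of the multivariate t.
With one treatment group the procedure reduces exactly to the pooled
two-sided t-test, and the tests verify family-wise error control under the
null by simulation and agreement with the `multcomp` reference
implementation.

## What the synthetic generators emulate — and what they do not

`generate_pore_trajectory()` produces a four-fold pseudo-pore: per
fenestration a telegraph (two-state) engagement process — the simplest
process with a unimodal occupancy distribution; a collar-tip radius
performing an Ornstein–Uhlenbeck walk retargeted between closed (2.1 Å) and
open (5.2 Å) radii; one ion diffusing overdamped along z through a Gaussian
barrier whose height falls linearly with the engaged-tail count,
B(k) = max(0, B₀ − k·ΔB) with B₀ = 25 and ΔB = 6 kJ/mol, so the closed
barrier is ≈10 k_BT and the fully engaged one ≈0.4 k_BT; and water oxygens
placed to give 6–7 first-shell neighbours in bulk and 4–5 at the collar.
Engagement probabilities default to 0.02/frame in and out, making two
engaged tails the modal occupancy of the tetramer, as observed for the
wild-type channel. The open radius and relaxation time were chosen once so
that conduction-conditioned apertures fall in the 40–50 Ų conducting band;
the ion integrator substeps each frame five-fold because a step comparable
to the barrier width would let discretization leak the closed barrier. At
the default 2×10⁴ frames the generator yields a few tens of crossings —
enough to make the gating contrasts (crossing probability versus engagement,
conducting versus population aperture) stable properties rather than
anecdotes.

The generators target *statistical structure only*: there is no force
field, no explicit membrane, no 3-D water dynamics, and no attempt to
reproduce absolute free-energy magnitudes. Tests passing on these fixtures
therefore demonstrate that the estimators are correct and that the pipeline
preserves the designed dependencies; they say nothing about force-field
accuracy or sampling convergence of real trajectories.

`generate_umbrella_samples()` integrates overdamped Langevin dynamics
(Euler–Maruyama) under the biased potential, enforcing the stability bound
dt·k/γ < 0.1, discarding a 10% burn-in, and keeping every 20th step so that
retained samples are separated by more than the integrator's correlation
time (≈γ/(k·dt) steps) — without thinning, window-mean noise accumulates
across the window ladder into kJ-scale distortions of the profile. The
O(dt) variance bias of the integrator is visible in closed-form checks and
is absorbed by their stated tolerances.

## Problem sizes and numerical choices

Default analysis sizes were picked so the full test suite and the
acceptance script each run in minutes on one core: 2×10⁴ trajectory frames
for mechanism properties, 41 windows × 5000 samples for WHAM recovery,
120 s at 1 kHz (1.2×10⁵ samples) per HMM recovery, 200 bootstrap replicates
by default (40 in tests). WHAM tolerance is 1e-6 kJ/mol on window free
energies; EM tolerance is 1e-6 relative log-likelihood; histogram bin
defaults are 0.1 Å (reaction coordinate), 0.25 Å (collar couplets), 0.1 pA
(amplitudes). Degenerate inputs fail loudly and early: collinear collar
midpoints, disconnected window ladders, non-stochastic transition matrices,
empty conditioning sets and unreached plateaus are all either hard errors
or flagged results, never silent defaults.

## Known limitations

* The pore-radius optimizer assumes a single dominant channel per z plane;
  multi-lumen geometries would need a multistart search.
* The WHAM estimator is histogram-based (no MBAR) and assumes a
  non-periodic reaction coordinate.
* The HMM assumes conditionally independent Gaussian emissions; heavily
  filtered records violate this and bias dwell estimates near the filter
  time constant.
* Dunnett comparisons assume homoscedastic groups (pooled variance), as in
  the classical procedure.
* The flux model is single-exponential; per-liposome stochastic efflux
  kinetics are out of scope.
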