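---
title: "Multicanonical docking and path-sampling binding free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicanonical docking and path-sampling binding free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdock)
```

# The problem and the model

Docking a flexible peptide into a protein binding groove and computing
its standard binding free energy is hard for plain canonical simulation:
at room temperature the bound state is metastable on any affordable
timescale, so binding/unbinding statistics never converge. The
methodology implemented here splits the problem in two. A
*multicanonical* (flat-histogram) ensemble first samples binding and
unbinding reversibly inside a restrained search volume, yielding the
room-temperature pose distribution by reweighting; *umbrella sampling*
along the pocket axis then resolves the potential of mean force (PMF) of
the identified pathway, and a standard-state correction converts the PMF
depth into ΔG⁰_b.

All of this is exercised on a built-in coarse-grained system rather than
an all-atom complex. The receptor is a rigid groove of beads (a back
wall, a floor row and two side rows) plus four harmonically tethered
"loop" beads at the pocket mouth that stand in for flexible binding-site
loops; the ligand is a short bead chain (default 6 beads, bond 3.8 Å,
straight equilibrium angle). Interactions are a Gō-type native-contact
model: every contact present in the bound pose gets a 12–10 well

$$u_{ij}(r) = \varepsilon_{ij}\left[5\left(\tfrac{\sigma_{ij}}{r}\right)^{12}
 - 6\left(\tfrac{\sigma_{ij}}{r}\right)^{10}\right],$$

with its minimum $\sigma_{ij}$ placed at the bound-pose distance, so the
bound pose is the exact global minimum with energy
$-\sum\varepsilon_{ij}$; non-native pairs are purely repulsive below an
excluded-volume diameter. Energies are kcal/mol, lengths Å, and
$k_B = 0.0019872$ kcal/mol/K throughout.

## Generator defaults and what they emulate

The toy generator's defaults define the study conditions:

* **Restraint geometry** — cylinder from λ = 2.5 to 30 Å, radius 4 Å,
  perpendicular/parallel force constants 1.0 / 20.0 kcal mol⁻¹ Å⁻²,
  origin at the center of mass of the receptor beads within 10 Å of the
  bound ligand. Restraints use the `k·d²` convention common to MD-engine
  restraint implementations (a `half_k` switch selects `k/2·d²`).
* **Ligand length 6** — a scale choice for a short epitope-like chain;
  the analogous peptide epitope has 11 residues, but 6 beads keep every
  validation oracle affordable while preserving the chain's orientational
  and conformational entropy, which is what makes binding nontrivial.
* **Contact depth ε = 2.0 kcal/mol per contact** (22 contacts, 44 kcal/mol
  total) — calibrated once so that the native complex is stable in
  unrestrained canonical runs at 300 K (R-value stays above 0.95) while
  bound and unbound states exchange freely at 700 K (both populated with
  many transitions). These are the two properties the temperature range
  of the flat ensemble relies on.
* **Loop tethers k = 1.0 kcal mol⁻¹ Å⁻²** — the position-restraint analog
  for parts of the receptor that must not drift, while the loops remain
  the only flexible receptor elements.

What the toy does *not* emulate: solvent and ions, side-chain chemistry,
rugged non-native minima of comparable depth to the native pose, and the
sheer dimensionality of an all-atom complex. Passing tests therefore
demonstrate the correctness of the statistical machinery under the
assumed funneled energy model — not that the method would converge at
the same rates on a real antibody–peptide system.

# Stage 1: multicanonical docking

## Weight estimation

Multicanonical sampling weights configurations by $1/n(E)$, making the
energy histogram flat across the band between the typical energies of
the 300 K and 700 K canonical ensembles, so the simulation random-walks
in energy between the bound basin and unbound, disordered states.
`estimate_mc_weight()` estimates $\ln n(E)$ on a fixed grid (default 200
bins over the range bracketed by canonical pilot runs at both
temperatures) by iterative pre-runs: the first pre-run is canonical at
700 K; each later pre-run samples with the current weight held fixed;
and after every pre-run the estimate is refreshed from *all* pre-run
histograms combined by multiple-histogram (WHAM-type) reweighting. Since
every pre-run's sampling weight is known exactly, the combined estimator
uses all data and can revise earlier over- or under-estimates — the
property that makes the iteration stable where purely additive update
rules oscillate.

Two numerical guards matter and are worth stating explicitly:

* **Frontier extension.** Bins beyond the explored range are
  extrapolated with the locally fitted statistical-temperature slope,
  clipped between the canonical slopes $1/k_BT_{high}$ and
  $1/k_BT_{low}$. The low-side clip means unexplored low energies are
  never made more attractive than a canonical 300 K tail would make
  them, so the frontier advances gradually without creating traps.
* **Canonical floor.** After each update a top-down sweep caps
  $dS/dE$ at $1/k_BT_{low}$ (the statistical temperature never drops
  below 300 K). Near the ground state the density of states collapses
  and a literally flat histogram would demand astronomically long
  sojourns in near-empty bins; capping the slope makes the deep tail
  sample like the 300 K canonical tail instead, which is exactly the
  coverage reweighting needs.

Iterations stop when the histogram of the last few pre-runs combined is
flat (min/max ≥ 0.5, the conventional criterion) over the target band —
the energies between the median of the 300 K pilot and the 95th
percentile of the 700 K pilot. With the defaults the toy system
converges for most seeds within 10–40 pre-runs of 10⁵ steps; when the
cap of 60 iterations is hit a warning is raised and the weight, though
rougher, remains usable (reweighting only requires the *actual* sampling
weight, which is always known).

## Production, reweighting, landscapes

`run_multicanonical()` samples with the estimated weight (Metropolis
acceptance $\min(1, n(E_{old})/n(E_{new}))$; single-bead moves plus
rigid-body ligand translations and rotations). On the default system a
production run makes several bound/unbound round trips per 10⁵ steps.
Canonical expectations at 300 K follow from `reweight()`; the docking
landscape is built by weighted PCA of the intermolecular bead–bead
distances, and `cluster_representatives()` finds basins by steepest
descent on the free-energy grid. Basin detection runs on a lightly
smoothed copy of the histogram (3×3 binomial kernel, two passes):
sparse raw histograms fragment one basin into spurious minima wherever a
cell happens to be empty, while cluster weights are still summed from
the raw cells. Cluster free energies are
$-k_BT\ln(w_k/w_1)$ relative to the most populated cluster, and each
cluster's representative is the frame nearest its weighted centroid —
the analog of picking representative bound configurations for further
study. On the default system the landscape shows two dominant basins
(the native pose and a mirror-groove pose), mirroring the two major
bound configurations such docking studies typically shortlist.

The isolated-chain mode of `distance_features()` implements the
disordered-peptide PCA convention: pairwise distances excluding pairs
within ±3 positions along the chain. Note the exclusion is inclusive
(`|i−j| ≤ 3` dropped), so a 4-bead chain has no features and a 5-bead
chain exactly one.

# Stage 2: path sampling

`assign_windows()` bins the docking ensemble by λ′ (nearest window
center, ties to the lower index; an empty pool is an error naming the
gap, the signal that docking under-sampled part of the pathway).
`pick_path()` then selects one frame per window minimizing the summed
Jaccard dissimilarity of adjacent interface contact matrices — the
"contact matrix changes slowly along λ′" requirement — by dynamic
programming, which is globally optimal for this chain objective (the
suite verifies it against exhaustive enumeration on all small
instances). The remaining seeds per window are the chain member's
nearest in-pool neighbors by the same metric.

`run_umbrella()` runs one canonical simulation at 300 K per
(window, seed) with bias $k_w(\lambda - \lambda_{ref} - c_i)^2$
(default $k_w = 0.3$, 16 windows ≈ 1.5 Å apart, chosen so adjacent
windows share well over 10% of their λ′ support at 300 K). Loop tethers
stay on during umbrella sampling: unlike a covalently connected
receptor, untethered toy loops would diffuse away in the unbound
windows.

## WHAM and the standard state

`wham()` solves the standard self-consistent equations on a λ′ grid
(default 0.25 Å bins, tolerance 10⁻⁸ on the window shifts). The PMF is
referenced so that the count-weighted mean over the unbound plateau —
the outermost 2.5 Å *ending at the outermost window center* — is zero;
bins beyond the last window are sampled only by its biased tail and
carry upward-biased free energies, so they are excluded from the
reference. ΔG is the average of G(λ′) over the bound-end window
λ′ ∈ [0, 2.5 Å]. The alternative reading of "the final 2.5 Å" (the far
end of the pull) would make ΔG the plateau value, i.e. zero by
construction; the bound-end reading is the one under which ΔG is the
depth of the binding basin, consistent with a PMF that decays to zero at
large λ′, and is what `binding_dG()` implements.

`range_error()` re-estimates ΔG on trailing fractions of every run and
attaches a block error (standard deviation of ΔG over consecutive
non-overlapping blocks divided by √n_blocks, default 2 blocks); the
pipeline reports the ε-minimizing range, which discards the
pre-equilibration part of each window run the same way one discards the
early part of production trajectories.

`g3d_from_runs()` histograms the WHAM-unbiased frame weights over
(λ′, v, ζ) (0.25 Å cells) and references the cell free energies to the
mean density over the plateau cells inside the restraint radius, so
G(λ, v, ζ) → 0 per unit volume in bulk. Then

$$V_{eff} = \sum_{site} e^{-(G(\lambda,v,\zeta) - \Delta G)/k_BT}
\,\Delta\lambda\,\Delta v\,\Delta\zeta, \qquad
\Delta G^0_b = \Delta G + k_BT \ln(V_0/V_{eff}),$$

with $V_0 = 1661$ Å³. Note the two equations compose to
$\Delta G^0_b = -k_BT\ln\left(\sum_{site} e^{-G/k_BT}\Delta V / V_0\right)$:
ΔG cancels, so ΔG⁰_b is insensitive to the λ′-binning of the PMF even
though ΔG itself is a binned average. This identity is also why the
end-to-end recovery test against an exhaustive grid partition sum is
meaningful at modest bin widths. `binding_result()` stores
(ΔG, ε, V_eff, ΔG⁰_b) and enforces the identity exactly.

# Validation strategy

Every statistical component is tested against an independent route:

* canonical sampling against equipartition and the Boltzmann law on the
  analytic harmonic reference (mean energy $d\,k_BT/2$);
* the weight estimator against the analytic density of states
  $n(E) \propto E^{d/2-1}$, and reweighted multicanonical ensembles
  against direct canonical runs (Kolmogorov–Smirnov distance < 0.05);
* WHAM against the analytic harmonic PMF (within 0.05 kcal/mol over the
  central 2 Å) and against its own single-window and refined-window
  answers;
* pathway selection against exhaustive enumeration;
* superposition against a brute-force rotational search;
* the full pipeline on a two-body benchmark (one receptor bead, one
  ligand bead, one contact) against an exhaustive 3D grid partition sum
  with identical site definitions, recovering ΔG⁰_b within 0.5 kcal/mol.

Problem sizes in the shipped tests are chosen so the whole suite runs in
a few minutes on one CPU: 10⁵-step pre-runs, 3×10⁵-step production for
the default system, 16 × 2–3 umbrella runs of 8–30 × 10³ steps, and grid
oracles at 0.05 Å resolution.

# Known limitations

* The loop-flexibility profile along λ′ reproduces the release of the
  binding-site loops upon unbinding as a rising plateau: loops are
  stiffest when gripped by the bound ligand and fluctuate at their free
  tether amplitude from mid-pathway outward. A sharp flexibility
  *maximum* at intermediate separation — partially formed contacts
  dragging the loops — is a weaker effect in this bead model and is not
  reliably resolved above the plateau noise.
* Weight estimation is stochastic; a minority of seeds exhaust the
  iteration cap before reaching the flatness target and proceed with a
  rougher weight (flagged by a warning). Round-trip mixing, not
  histogram flatness per se, is what downstream estimates depend on, and
  it is tested directly.
* The Monte-Carlo "step" is the unit of simulated effort; durations of
  the emulated protocol (microseconds of MD) have no literal counterpart
  and are replaced by step budgets in `default_config()`.
* Statistical errors on ΔG come from 2-block estimates over the chosen
  range; with so few blocks they are themselves noisy and should be read
  as order-of-magnitude indicators, which is all the range-selection
  rule needs.
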