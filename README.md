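# mcdock

Two-stage binding free-energy methodology for coarse-grained
receptor–ligand models: **multicanonical dynamic docking** inside a
cylindrical center-of-mass restraint, followed by **umbrella sampling**
along the pocket axis, **WHAM**, and a **standard-state volume
correction**.

## Who this is for

Researchers studying protein–peptide binding who want a compact, fully
tested reference implementation of the flat-histogram docking +
path-sampling workflow — the kind used to dock a disordered peptide
epitope into an antibody binding groove and convert the resulting
potential of mean force into a standard binding free energy. The package
ships a Gō-model toy receptor–ligand system on which every stage of the
workflow is exercised and validated against analytic and brute-force
oracles, so each statistical component (density-of-states estimation,
canonical reweighting, WHAM, the volume correction) can be trusted — and
inspected — in isolation.

## The method

**Stage 1 — dynamic docking.** The ligand's center of mass is confined
to a cylinder along the pocket axis λ⃗ (flat-bottomed between λ = 2.5 and
30 Å, radius 4 Å; force constants 1.0 and 20.0 kcal mol⁻¹ Å⁻²,
`k·d²` convention). A multicanonical (flat-histogram) Monte-Carlo
ensemble is built by iteratively estimating the density of states
n(E) over the energy band spanning 300–700 K; sampling with weight
1/n(E) makes the energy histogram flat, so the run random-walks between
bound, intermediate and unbound states. The canonical ensemble at 300 K
is recovered by reweighting, w ∝ n(E)·e^(−E/kT), and binding poses are
clustered on a free-energy landscape over the first two principal
components of the intermolecular distance features; cluster free
energies are −kT ln(cluster weight) relative to the top cluster.

**Stage 2 — path sampling.** Seed structures for 16 umbrella windows
along λ′ = λ − λ_ref (λ_ref = bound reference structure) are picked by
dynamic programming so that the interface contact matrix changes as
slowly as possible along the pathway (minimal summed Jaccard
dissimilarity; 3 seeds per window). Window histograms are combined by
WHAM into the PMF G(λ′), referenced to the unbound plateau; the binding
free energy is the average over the bound-end 2.5 Å:

    ΔG  = ⟨G(λ′)⟩,  λ′ ∈ [0, 2.5 Å]
    V_eff = Σ_site exp(−(G(λ,v,ζ) − ΔG)/kT) Δλ Δv Δζ
    ΔG⁰_b = ΔG + kT ln(V₀ / V_eff),   V₀ = 1661 Å³ (1 M)

with per-range block errors ε used to choose the equilibrated trailing
production range.

## Worked example

```r
library(mcdock)

sys <- build_system()          # Go-model groove + 6-bead ligand
sys
#> Coarse-grained Go-model receptor-ligand system
#>   receptor beads: 28 (4 flexible loop beads)
#>   ligand beads:   6 (bond 3.80 A)
#>   native contacts: 22, total well depth 44.00 kcal/mol
#>   bound-pose ligand COM at lambda = 2.71 A

# the standard-state correction applied to a published worked example:
# PMF depth -19.92 kcal/mol and sampled site volume 0.735 A^3 at 300 K
binding_result(-19.92, 0.735, T = 300)
#> Binding free energy
#>   PMF depth       dG    = -19.92 kcal/mol
#>   site volume     V_eff = 0.735 A^3 (V0 = 1661 A^3)
#>   standard state  dG0_b = -15.32 kcal/mol at 300 K
```

The −15.32 kcal/mol is ΔG + kT ln(V₀/V_eff) at 300 K: a site whose
Boltzmann-weighted volume is far smaller than the 1 M standard-state
volume pays an entropic penalty of kT ln(1661/0.735) ≈ 4.6 kcal/mol on
top of its PMF depth.

The full two-stage pipeline on the built-in system (weight estimation →
multicanonical docking → landscape clustering → pathway seeds →
umbrella/WHAM → ΔG⁰_b) runs in a few minutes on one CPU:

```r
pl <- binding_pipeline(default_config(seed = 1))
pl$result       # classed binding_result with the dG0 identity enforced
plot(pl$pmf)    # PMF along lambda'
plot(pl$fel)    # docking free-energy landscape
```

A file-based staged interface (`run_stage()` / `run_pipeline()`) writes
resumable per-stage artifacts (`weight.txt`, `dock.csv`, `clusters.csv`,
`pmf.csv`, `binding.json`, `report.json`), each stamped with the
configuration hash and seed.

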