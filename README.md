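# lhcswitch

Structure-to-energetics analysis of light-harvesting pigment–protein
complexes in R.

Plant light-harvesting complexes such as LHCII bind a dense network of
chlorophylls and xanthophylls whose mutual excitonic couplings set how
excitation energy flows — and how it is dissipated when the complex switches
from its light-harvesting to its photoprotective conformation. Testing
structural hypotheses about that switch requires going from raw coordinates
(a crystal structure, or snapshots of a molecular-dynamics trajectory) to
energetic observables and back: which pigment pair's coupling changed, and
which structural rearrangement tracks it. `lhcswitch` implements that whole
path for structural biologists and photosynthesis modellers:

* **Transition dipoles.** Chlorophyll Qy dipoles along the NB→ND axis
  centered on Mg (configurable), and carotenoid S2←S0 dipoles along the
  central portion of the conjugated polyene chain (principal-axis fit).
* **Excitonic couplings.** Point-dipole couplings
  `V = C·f·κ·μ₁μ₂/R³` with `κ = μ̂₁·μ̂₂ − 3(μ̂₁·r̂)(μ̂₂·r̂)` and
  `C = 5034.1166 cm⁻¹·Å³·D⁻²` (CODATA-derived vacuum constant), and
  extended-dipole couplings (±q = μ/l point charges, default l = 8.7 Å)
  that attenuate correctly at short range — per structure or per frame.
* **Conformational descriptors.** Carotenoid tilt angles against the
  protein pseudo-C2 axis, per-atom B-factors `B = (8π²/3)⟨|Δr|²⟩` after
  iterated superposition, per-domain RMSD with a rigid-core fit, centroid
  distances, and geometric hydrogen-bond occupancies.
* **Switch analysis.** Per-simulation means, deltas against a computed
  crystal baseline, ensemble Pearson fits of (Δstructure, Δcoupling)
  points with the crystal at the origin, and within-trajectory
  synchronization scans.
* **Synthetic ground truth.** A generator of idealized chlorin rings,
  polyene chains, helix bundles and scheduled trajectories whose expected
  analysis outputs are known analytically, so every pipeline stage is
  testable without downloads.

File I/O is deliberately plain: fixed-width PDB for structures and
multi-model PDB for trajectories, plus YAML pigment registries and tidy CSV
outputs.

## Worked example

```r
library(lhcswitch)

# a fully synthetic LHCII-like complex with known geometry
demo <- lhcii_demo_blueprint()
pigment_census(demo$model, demo$registry)
#>          chl_a          chl_b     carotenoid          lipid total_pigments
#>              8              6              4              1             18

# carotenoid tilt against the protein axis (built at 60 degrees)
axis <- protein_axis(demo$model)
crystal_car_tilt(demo$model, "A/623", demo$registry, axis = axis)
#> [1] 60.2  # degrees; inertial axis estimate of the helix bundle

# crystal-reference coupling of the terminal-emitter-like pair
crystal_coupling(demo$model, c("A/611", "A/612"), demo$registry)
#> <CouplingResult> point_dipole: 68.34 cm^-1 (R = 10.72 A, kappa = 1.044, f = 1)

# a short noisy trajectory and its per-frame coupling series
tr <- make_trajectory(demo$model, n_frames = 5, noise_sigma = 0.15,
                      seed = 1)$trajectory
head(coupling_series(tr, c("A/611", "A/612"), demo$registry), 3)
#>   frame time_ns        pair       method kappa   R_A energy_cm
#> 1     1       0 A/611:A/612 point_dipole 1.057 10.92     65.32
#> 2     2       1 A/611:A/612 point_dipole 1.020 10.69     67.21
#> 3     3       2 A/611:A/612 point_dipole 1.075 10.47     75.37

# ensemble correlation of (delta-structure, delta-coupling) points
gen <- make_correlated_ensemble(n_sims = 6, slope = 3, seed = 1)
ensemble_pearson(gen$points)
#> <EnsembleCorrelation> r = 0.997 over 7 points (crystal origin included)
#>   fit: delta_E = 2.936 * delta_x +0.07591
```

The census distinguishes the 8 chlorophyll-a, 6 chlorophyll-b and 4
xanthophyll cofactors plus the lipid ligand; the coupling result reports the
signed interaction energy in cm⁻¹ with its orientation factor κ and
center–center distance; the ensemble fit summarises how strongly a
structural delta (Å or degrees) tracks a coupling delta (cm⁻¹) across
simulations, with the crystal reference pinned at (0, 0).

A thin command-line wrapper is installed as `exec/lhcswitch` with
subcommands `synth`, `couplings`, `angles`, `rmsd`, `distance`, `hbonds`,
`bfactor` and `switch`; see `?lhc_cli`.

## Vignette

`vignettes/structure-energetics.Rmd` documents the models, conventions,
default parameters and their rationale, the synthetic generator's scope,
and known limitations.
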