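---
title: "From coordinates to excitonic couplings: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coordinates to excitonic couplings: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhcswitch)
```

`lhcswitch` turns pigment–protein coordinates into excitonic and
conformational observables. This vignette is the package's account of the
science behind each stage: the models used, the conventions and default
parameters chosen where the field leaves latitude, what the synthetic
generator does and does not emulate, and the numerical decisions that make
the results deterministic.

## Transition dipole models

**Chlorophyll Qy.** The Qy transition of a chlorin ring is modelled as a
point dipole along the axis through two opposing pyrrole nitrogens. The
default is the vector from NB to ND (PDB chlorophyll nomenclature), centered
on the central Mg. Both choices are conventions, not measurements: published
analyses differ on whether the center sits on Mg or on the NB–ND midpoint,
and the ring's own geometry fixes the axis only up to sign. Both the axis
atoms and the center (`"midpoint"` included) are configurable per registry
entry. Default magnitudes are effective values typical of the literature —
4.0 D for chlorophyll *a*, 3.4 D for chlorophyll *b* — and are explicitly
configurable because coupling magnitudes scale with μ₁μ₂: any analysis that
depends on absolute coupling values states which magnitudes it assumed.
Magnitude and geometry are independent: changing μ never changes the
direction, and rigid motions of the pigment transform center and direction
equivariantly.

**Carotenoid S2.** The strongly allowed S2←S0 transition lies along the
conjugated polyene backbone. Because the chain ends of xanthophylls bend —
sometimes strongly, as for neoxanthin protruding out of the protein — the
dipole is fitted to the *central portion* of the chain only: the middle 50%
(configurable) of the registry's ordered chain-atom list. The direction is
the largest-variance principal axis of those atoms' positions, signed from
the first toward the last listed atom, centered on their centroid. An exact
zigzag with an even number of atoms in the window has a small, purely
geometric off-axis covariance; with an odd window the principal axis of the
ideal template is exact. Degenerate inputs (fewer than two atoms, coincident
atoms) are errors, never silently patched.

The carotenoid S1 state is deliberately out of scope: it is optically
forbidden and has no reliable transition dipole to assign.

## Excitonic couplings

**Point dipole.** For two transition dipoles the interaction energy is

$$V = C \, f \, \kappa \, \frac{\mu_1 \mu_2}{R^3}, \qquad
\kappa = \hat\mu_1\cdot\hat\mu_2 - 3(\hat\mu_1\cdot\hat r)(\hat\mu_2\cdot\hat r),$$

with μ in Debye, R (center–center) in Å and V in cm⁻¹. The vacuum
conversion constant is fixed at `C = 5034.1166` cm⁻¹·Å³·D⁻², derived from
CODATA constants ((1 D)² / (4πε₀ (1 Å)³ h c), equivalently
0.2081943² × 14.399645 × 8065.544); it is a unit conversion, not a free
parameter, and the test suite re-derives it from an independent constant
set. Texts quoting ≈5040 in mixed nm/Å unit systems differ only in
rounding. The screening factor `f` defaults to 1 (vacuum): the package
assigns no implicit dielectric, and any screening is the caller's explicit
choice.

**Extended dipole.** At short range — pigment pairs separated by distances
comparable to the chromophore size — the point-dipole approximation
overestimates fluctuations. The extended-dipole model replaces each
transition by two charges ±q = μ/l at center ± (l/2)·direction and sums the
four inter-dipole Coulomb terms in the same unit system. The default charge
separation l = 8.7 Å is a common literature choice for the chlorophyll Qy
transition and is configurable. The model converges monotonically to the
point-dipole value as l/R → 0 and attenuates the coupling when dipole ends
approach each other; both behaviours are asserted in the tests.

**Crystal baselines.** Delta analyses need a crystal reference coupling.
That reference is always *computed* from the crystal coordinates with the
active registry — it is never a typed-in number — so baseline and trajectory
values share every convention by construction.

## Conformational descriptors

**Protein axis and tilt angles.** Tilt angles are measured against the
protein's pseudo-two-fold axis, which doubles as the membrane normal in a
transmembrane light-harvesting fold. Two definitions are provided: the
largest-variance (smallest-inertia) principal axis of a selected backbone
atom set — for a helix bundle, its long axis — with the sign fixed by an
orientation point; or the laboratory z axis, for frames already superposed
onto an axis-aligned reference. Tilt angles are folded to [0°, 90°] because
a transition dipole's sign carries no physics; a crystal-like ~60° tilt and
a strongly kinked ~90° configuration are both representable either way.
Nearly isotropic atom clouds (leading inertia eigenvalues separated by less
than one part in 10⁶) are rejected as degenerate rather than returning an
arbitrary axis.

**B-factors.** Per-atom temperature factors are computed as
B = (8π²/3)·⟨|rᵢ − ⟨rᵢ⟩|²⟩ after removing global rigid-body motion:
frames are first fitted to frame 1 over the fit selection, the mean
structure is formed, and all frames are refitted to that mean — one
refinement pass, which is deterministic and near-converged, instead of an
open-ended convergence loop. Because the superposition absorbs six rigid
degrees of freedom, the recovered B under pure isotropic jitter is biased
low by roughly 6/(3N) for N fitted atoms; validation uses N = 200, where
that bias (~1%) is well inside the 5% recovery tolerance.

**Domain RMSD.** Per-domain RMSD series superpose each frame onto the
reference over a *fit selection* — intended to be the rigid transmembrane
core — and then measure the domain's backbone deviation without refitting
on the domain. This way a mobile peripheral domain (an N-terminal stretch,
a stromal loop) reports genuine displacement relative to the core rather
than being partially absorbed by its own fit. Superposition is delegated to
the Kabsch least-squares implementation in `bio3d` (no reflections);
degenerate fit sets (<3 atoms, collinear) are errors.

**Hydrogen bonds.** The geometric criterion is donor–acceptor distance
≤ 3.5 Å and, when a hydrogen is specified, a hydrogen–donor–acceptor angle
(at the donor) ≤ 30°. These are common molecular-dynamics practice defaults,
configurable per `hbond_spec()`, since published criteria vary and the
specific criteria used alongside any given dataset may differ. Occupancy is
the fraction of frames satisfying the criterion and is monotone in the
distance cutoff by construction.

## Switch analysis

Per-simulation time series are reduced to means (default: over the full
trajectory; an equilibration `discard_fraction` is available but defaults
to 0), converted to deltas against the computed crystal baseline, and
assembled into an ensemble of (Δstructure, ΔE) points fitted by least
squares with a Pearson coefficient.

Two delta conventions are implemented and labelled, because axis-sign
conventions in published switch plots are not always fully specified:
`signed` (sim − crystal, the default) and `magnitude_decrease`
(|crystal| − |sim|, positive when the interaction weakened). They agree
whenever the quantity keeps its sign and diverge when it flips; the package
never guesses which one a given external figure used.

The crystal is included in ensemble fits as the (0, 0) origin point by
default — deltas are defined against it — and excluding it changes the
reported `n_points` by exactly one. Within-trajectory synchronization
(`synchronization_scan`) pairs two time-aligned series frame by frame and
reports a per-trajectory Pearson r; results are deliberately never pooled
across simulations, since pooling can manufacture (or destroy) correlation
that no single trajectory contains.

## The synthetic generator

The generator exists so that every analysis stage can be validated against
analytic ground truth, offline. It emulates:

* idealized chlorin heads (Mg–N 2.05 Å, planar, named Mg/N/formyl atoms)
  and zigzag polyene chains (C–C 1.35 Å, 120° bond angle, optional kink);
* rigid-body orientational drift via per-frame rotation/translation
  schedules, plus i.i.d. Gaussian positional noise of chosen σ;
* hydrogen-bond partners toggled across a cutoff with a known occupancy;
* per-simulation (Δx, ΔE) ensembles with a known linear relation
  (ΔE = slope·Δx + N(0, σ)) and hence a known population correlation.

Templates are ideal geometry, not crystallographic coordinates, so expected
outputs are closed-form. All randomness flows from one explicit seed
through R's Mersenne-Twister/inversion generators, with the caller's RNG
state restored afterwards; identical seeds give byte-identical trajectories
through the file round-trip.

Defaults mirror the study design the package addresses: ensembles default
to six simulations (plus the crystal origin in fits), the default ensemble
noise is 10% of the linear signal's population standard deviation
(population r ≈ 0.995, i.e. a strong-correlation regime), and the
demonstration complex binds 8 + 6 chlorophylls, 4 carotenoids — its
neoxanthin-like chain built at a 60° tilt — and a lipid ligand.

What the generator does **not** emulate is as important: no force-field
physics, no membrane or solvent, no realistic pigment–protein packing, no
microsecond-scale conformational kinetics. Passing ground-truth recovery
tests therefore demonstrates that the *analysis operators* are correct
(angles recovered to ≤0.1°, B = 8π²σ² to 5% at 2000 frames, occupancies
exactly, correlations to the analytic sampling tolerance), not that any
particular biological trajectory would produce particular values.
Quantities that only emerge from long molecular-dynamics sampling — absolute
coupling time courses, solution-state average tilt values, percent-level
average coupling shifts — are out of reach at desk scale and are *not*
claimed by the test suite.

## Problem sizes and determinism

Validation sizes were chosen as the smallest that make the analytic
expectations sharp: 2000 frames × 200 atoms for the B-factor closed form,
1000 frames for Pearson null bands (sd ≈ 1/√n), tens of frames for exact
schedule recoveries, and 40-seed Monte-Carlo loops where a distributional
claim is tested. Structure files carry 3-decimal coordinates, so file
round-trips are exact to 5×10⁻⁴ Å and angle/energy observables are stable
to well below their assertion tolerances. Parsing is deterministic:
alternate locations resolve to the highest occupancy (ties: first record),
insertion codes extend the residue key, and author residue numbering is
preserved as-is — one published domain definition describes a 14–53
N-terminal range as "39 residues" although the inclusive range holds 40;
the range is taken as authoritative.

## Known limitations

* Coupling models are dipole-level only; transition-charge or
  transition-density methods and exciton Hamiltonian diagonalization are
  out of scope, as are site energies.
* Registry defaults for real depositions (het codes CLA/CHL/LUT/NEX/XAT/LHG,
  carotenoid chain atom names in C1–C40 numbering) follow common usage but
  het-code dialects vary; verify them against your coordinate file and edit
  the registry — a missing dipole atom raises a named error rather than
  substituting silently, since crystal structures can lack cofactor atoms
  (e.g. phytol tails).
* The mandatory trajectory format is multi-model PDB; binary formats would
  need external conversion.
* Mass-weighted centroids use a small built-in element table (unknown
  elements fall back to carbon's mass); geometric centroids are the
  default.
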