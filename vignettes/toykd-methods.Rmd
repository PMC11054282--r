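---
title: "Supervised binding and thermal titration on coarse-grained pocket models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised binding and thermal titration on coarse-grained pocket models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

ATP-competitive kinase inhibitors are routinely characterized with two
enhanced-sampling molecular dynamics protocols:

* **SuMD** (supervised molecular dynamics) accelerates the observation of a
  *binding* event. Short unbiased MD windows ("SuMD-steps") are run from an
  unbound ligand; after each window the distance between the ligand's center
  of mass and the binding-site center is fitted linearly against time, and the
  window is kept only when the slope is negative. A rejected window is retried
  from its starting coordinates with freshly randomized thermostat velocities.
  When the distance falls below a threshold (10 Å), supervision is switched
  off and plain MD continues.
* **TTMD** (thermal titration molecular dynamics) ranks the *stability* of a
  bound complex. Classic MD windows ("TTMD-steps") are run at stepwise
  increasing temperature (300 K start, +10 K per step). Each frame is scored
  with the similarity `IFP_CS` between its protein–ligand interaction
  fingerprint and the reference (bound) fingerprint; the ladder stops when
  the window-mean similarity shows the native binding mode is lost. The
  "titration profile" (mean `IFP_CS` per window vs temperature) is summarized
  by the **MS coefficient**, the slope of the straight line joining its first
  and last points: the closer to zero, the more temperature-resistant the
  complex.

The scientific question both protocols address here is the role of a small
polar substituent (a nitrile) that hydrogen-bonds to conserved structural
waters in the pocket: the substituted ligand should resist thermal titration
to higher temperatures than its unsubstituted congener, and the contrast
should disappear when the water sites are removed.

`toykd` re-implements the protocols *exactly* (window logic, accept rule,
thresholds, profiles, scores) but runs them on synthetic coarse-grained
systems, so every claim can be exercised and tested on a desk in seconds
rather than on a GPU cluster in days.

## The synthetic system

`make_pocket_system()` builds a rigid receptor and a mobile ligand:

* **Pocket**: a hemispherical shell (radius 6 Å) opening into bulk along +z
  — a funnel, so approach trajectories have a well-defined target. Eight
  hydrophobic sites line the mid-depth band (the toy analogues of the
  Ile/Ala/Leu cleft lining), two aromatic sites and a buried, tightly paired
  cation/anion salt bridge complete the wall. Wall positions receive a small
  seeded jitter (sd 0.15 Å), so seeds are replicate pockets.
* **Hinge anchor**: a hydrogen-bond donor/acceptor pair 3.0 Å apart at the
  pocket floor, mimicking the kinase hinge backbone that accepts a bidentate
  hydrogen bond from ATP-competitive inhibitors.
* **Structural waters**: two fixed "water" sites on the pocket wall. Each is
  modeled as an oriented dipole — a donating H-end (+0.35 e) facing the
  pocket and an O-end counter charge 1 Å behind it — so a bead in contact
  feels a full hydrogen-bond well while the hinge-anchored ligand 5–6 Å away
  feels a rapidly decaying field. A monopole water would capture the base
  ligand's acceptor bead; the dipole form preserves the intended selectivity.
* **Ligand**: six beads — three hydrophobic, one aromatic, one donor and one
  acceptor (the bidentate pair) — held rigid-ish by stiff harmonic restraints
  (300 kcal mol⁻¹ Å⁻²) on all pairwise distances. The scaffold beads use
  coarse-grained sizes (σ = 4.2 Å) so the pocket is snug: without wall
  contact the scaffold has soft rotational modes and the relaxed pose
  wanders. `make_ligand_pair()` adds a seventh bead to a copy of the ligand:
  a small (σ = 2.2 Å), weakly dispersive, negatively charged (−0.45 e)
  hydrogen-bond acceptor grafted onto the relaxed base scaffold, positioned
  to contact the W295-analogue water. This is the nitrile-analogue; the pair
  is congeneric by construction.

The native pose is produced by relaxing the built-in template with a FIRE
minimizer under the same force field the dynamics use (residual force
< 10⁻⁴ kcal mol⁻¹ Å⁻¹), so it is a genuine local minimum; the generator
verifies that the pose keeps the bidentate anchor, stays centered, and lies
below any outward-translated pose, retrying deterministically derived jitter
sub-seeds if a draw violates those guarantees. The binding-site center is
defined as the native-pose ligand centroid, the toy analogue of defining the
site by the crystallographic ligand's center of mass.

### What the generator does *not* emulate

Receptor flexibility, explicit solvent, angular hydrogen-bond terms,
protonation states, and conformational ligand strain are all absent. Tests
passing on these systems show the *protocols and analyses* are implemented
correctly and that the water-mediated stabilization mechanism behaves as
designed; they say nothing about force-field accuracy on real kinases.

## Energy model

Receptor–ligand interactions are pairwise: a Coulomb term
(k·qᵢqⱼ/r, k = 332.0636 kcal Å mol⁻¹ e⁻², dielectric 1) plus a 12-6
Lennard-Jones term with Lorentz–Berthelot combination, both multiplied by a
cubic smoothstep switching factor that is 1 up to 7.5 Å and 0 beyond 9.0 Å.
The switching function's exact form is a package choice (the protocols it
follows name the scheme but not the polynomial); the cubic smoothstep makes
energies and forces continuous. Electrostatics decompose exactly into
per-receptor-site contributions (`IEele`), the quantity shown in per-residue
heat maps. The hydrophobic term (`IEhyd`) is a dimensionless distance-based
contact weight (full contact ≤ 4.5 Å, smoothstep to zero at 6.0 Å) summed
over hydrophobic pairs — a deliberate, documented stand-in for
surface-contact scoring, with no claim of numerical equivalence to any
proprietary implementation. It is an analysis quantity only and exerts no
force.

## Dynamics

The ligand is propagated with the BAOAB splitting of Langevin dynamics in
the fixed receptor field. Units are kcal/mol, Å and amu, giving an internal
time unit of ~49 fs; the default step `dt = 0.002` and 500 steps per
internal "toy ps" mirror a 2 fs step at 500 steps/ps. Friction is
γ = 1 per toy-ps. The simulation cell is a reflecting cube (half-width
16 Å) standing in for a solvated periodic box. Protocol windows are
expressed in integration steps: 5 000 steps stand in for the 500 ps
SuMD-step, 20 000 for the 10 ns TTMD window and post phase. All protocol
logic depends only on window counts.

The thermostat noise comes from a counter-based splitmix64 generator with an
explicit Box–Muller transform implemented in the package (not
`std::normal_distribution`), so trajectories are bit-reproducible across
platforms for a given seed. Every stage of a protocol run draws its seed
from the global seed through `derive_seed()`, a documented Lehmer step —
a whole SuMD or TTMD run, including rejected attempts, replays exactly.

At the default settings a 20 000-step window takes ~0.1 s on one CPU, which
is what makes ten replicate ladders a test-suite-sized computation. A single
40-toy-ps rung estimates its own kinetic temperature with ~4% statistical
noise (the kinetic energy decorrelates in ~0.5 toy-ps), so thermostat
accuracy is asserted on ladder averages and on a dedicated long window.

## Protocol details and policies

* **SuMD**: slope is an OLS fit of COM distance against frame index (only
  its sign matters); a slope of exactly zero is unproductive. On rejection,
  positions reset to the window start and velocities are redrawn. Budgets —
  20 attempts per step, 200 total steps — are package policy; the protocol
  as published sets none, but unbounded retries would never terminate on a
  pathological system. A step that exhausts its attempts leaves the state
  unchanged and the run continues; a run that exhausts its step budget
  returns a not-bound flag rather than an error. "Bound" means the
  protocol's own supervision-off criterion (COM distance < 10 Å): with a
  9 Å interaction cutoff, the toy funnel exerts no force beyond ~11 Å, so
  the post phase near the pocket mouth is diffusive.
* **TTMD**: the loss criterion is a window-mean `IFP_CS` strictly above
  −0.2. The published protocol states the loss event qualitatively; −0.2
  mirrors the near-zero plateau of a lost profile and is exposed in
  `ttmd_config()`. Each rung continues from the previous rung's final
  coordinates with velocities rescaled by √(T_new/T_prev). The ladder
  ceiling (`t_max`, default 900 K) is policy: the published ramp is bounded
  by protein-fold preservation, which a rigid toy receptor cannot
  reproduce; ladders that complete unbroken are censored at the ceiling.
  `IFP_CS` is the negated cosine similarity of binary fingerprints — an
  algebraic reading inferred from the printed value range (reference ≈ −1,
  loss ≈ 0) rather than from a published formula.
* **Fingerprints**: binary, per (site, channel), with distance-only cutoffs
  — hydrophobic and aromatic 4.5 Å, hydrogen bonds 3.5 Å, ionic 4.0 Å —
  standard PLIF ranges; toy beads carry no angular geometry. The default
  ligand has no formally charged bead, so the ionic channel is exercised in
  tests with constructed geometries.
* **Pharmacophore**: donor + acceptor features on the hinge-bonded beads of
  the reference pose and one feature per aromatic bead, all with 2.0 Å
  spheres; a pose passes only if *every* feature is matched by a bead of
  the right type inside its sphere (the bidentate bond is therefore
  required).

## Numerical choices and degenerate inputs

Zero-distance pairs raise a singularity error; negative distances and
temperatures are contract violations. A non-finite coordinate during
integration aborts with the step index in the message. The fingerprint of
an all-zero frame scores 0 against any reference, and an all-zero
*reference* is rejected. `ms_coefficient()` requires two or more points at
distinct temperatures. XYZ parsing errors name the offending frame and
line; the PDB-subset system file is human-readable while the JSON sidecar
carries full-precision values and is authoritative on read.

## Design decisions that were genuinely open

* **Water representation.** Monopole water sites captured the base ligand's
  acceptor bead at 4–6 Å (the switching function truncates the far
  counter-ion of any distant pair, so neutrality does not protect); fixed
  dipoles with both ends inside the switch-on region restore cancellation.
* **Pair construction.** The variant is relaxed from the base's relaxed
  pose plus the grafted bead (settled first against a frozen scaffold).
  Independent relaxation of the two systems injected ±1 kcal/mol of
  basin-choice noise into the pair gap, swamping the no-water gap.
* **Ensemble statements.** Generator-level claims (the no-water collapse of
  the pair gap to < 10%) are asserted on means over five replicate pockets;
  a single pocket's gap fluctuates with the wall jitter.
* **Problem sizes.** The test suite and the acceptance script use 10
  replicate SuMD runs (40-step budget), 10 or 5 replicate TTMD ladders and
  500-configuration oracle sweeps — sizes chosen so the complete suite runs
  in a few minutes on one CPU while keeping binomial bounds meaningful.

## Known limitations

The unsupervised-binding baseline usually exhausts its budget (free
diffusion to the pocket mouth is slow in a 16 Å half-width box), so the
SuMD-vs-classic comparison treats those runs as censored; the reported
speedup is therefore a lower bound. Unbinding temperatures are first-passage
quantities with large replicate variance (~±100 K); stability claims are
made on paired replicates and means, never single ladders. The hydrophobic
score is not comparable across packages. No claim is made that toy
unbinding temperatures map onto physical residence times.
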