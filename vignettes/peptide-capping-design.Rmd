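---
title: "Designing peptide capping agents on FCC(111): models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing peptide capping agents on FCC(111): models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsurf)
```

## The problem

Nanoparticle shape control hinges on capping agents: molecules that
adsorb selectively on one crystal facet and suppress growth there.
Screening candidate peptide sequences experimentally is slow, so the
computational loop implemented here ranks sequences by how stably and
how specifically they adsorb on the FCC metal (111) facet. The
pipeline is: build the capped peptide from sequence, search globally
for its low-lying adsorption configurations in vacuum, relax the best
candidates with MD (optionally in explicit water), and compare
adsorption energies and binding geometry across environments and
sequences.

The quantity everything revolves around is the adsorption (binding)
energy

$$E_\mathrm{BE} = E_\mathrm{peptide/surface} - E_\mathrm{peptide} - E_\mathrm{substrate},$$

computed as a *single-point* decomposition: the fragments are evaluated
at exactly the coordinates they hold in the complex, so
$E_\mathrm{BE}$ reduces to the peptide–surface interaction energy.
Relaxation enters separately, because every configuration is locally
minimized before $E_\mathrm{BE}$ is evaluated. Lower (more negative)
is more stable. When the peptide sits beyond the nonbonded cutoff the
three terms cancel exactly and $E_\mathrm{BE} = 0$; the test suite
asserts this identity.

## The energy model

`pepsurf` ships an embedded, reduced force field with Amber-class
functional forms:

* harmonic bonds $k(r-r_0)^2$ and angles $k(\theta-\theta_0)^2$
  (note: no factor $\tfrac12$ — the same convention is used for the
  positional restraints, which is why the equipartition check below
  expects $\langle \Delta r^2\rangle = 3k_BT/2k$);
* proper cosine dihedrals $k(1+\cos(n\phi - \phi_0))$;
* 12-6 Lennard-Jones plus Coulomb, Lorentz–Berthelot mixing, 1-2/1-3
  exclusions and Amber-style 1-4 scaling (LJ × 0.5, Coulomb × 1/1.2);
* a 12 Å cutoff on both LJ and short-range electrostatics with a
  quintic-smoothstep switching window (default 10–12 Å); no Ewald
  summation, matching the short-range-only treatment of the published
  protocol.

The representation is **heavy-atom (united-atom)**: nonpolar hydrogens
are folded into their parent carbon's mass and charge; polar groups
(backbone NH, Ser OH, the Gln/Asn amides) are single charged heavy
sites. Residue templates exist for Ser, Phe, Pro, Gln, Asn and the
acetyl/amide caps — exactly the chemistry of the sequences this
package targets. The metal is a lattice of uncharged LJ sites with a
deep well (ε = 5.29 kcal/mol, σ = 2.63 Å for Au), the standard way a
dispersion-dominated metal surface is represented in fixed-charge
force fields. The slab is rigid: its internal pair energy is constant
and taken as the zero of energy, which leaves every binding-energy
difference unchanged.

This is deliberately *not* any published parameter set. The absolute
published adsorption energies depend on full
Amber99sb-ILDN/CHARMM-METAL/TIP3P parameters and multi-nanosecond MD
and are out of reach at desk scale; what this package preserves is the
functional forms, the workflow, and every structural/ordering claim,
which is also all the test suite asserts about energies. Molecular
weights, by contrast, use a standard average-mass table and are exact:
`molecular_weight("Ac-SSFPQPN-NH2")` gives 816.87 Da. For the two
published 8-mers the printed masses are mutually swapped relative to
their sequences (the 3-Pro/3-Phe/2-Ser peptide computes to ≈966.10 Da,
the 4-Phe/4-Ser one to ≈996.09 Da); the package always computes from
the sequence and does not force agreement.

### Units and conventions

Å, kcal/mol, elementary charges, g/mol; time in fs at the interface
(internally the Amber time unit, 48.8882 fs). The surface normal is
+z, the top metal layer sits at z = 0, the peptide above it. The slab
is periodic in-plane (hexagonal cell) and open along z. Atom indices
are 0-based only inside the compiled kernel; everything user-facing is
1-based, and PDB output follows PDB v3.3 (caps as ACE/NH2 residues,
cell in a CRYST1 record with the open direction written as a large
vacuum c-axis).

Nonbonded periodicity is an explicit **image sum**: every periodic
image of a pair that falls inside the cutoff contributes, not just the
nearest. With cells smaller than twice the cutoff (every desk-scale
slab), nearest-image-only evaluation makes the energy non-smooth when
the nearest image changes identity, which shows up as secular drift in
NVE; the image sum removes that artifact and makes the energy exactly
invariant under surface-lattice translations. Consequently a peptide
longer than the cell genuinely interacts with its own image — the
default 13 × 13 slab (37.5 Å) is sized so an extended 7-mer
(≈25 Å) plus the 12 Å cutoff fits without self-interaction.

## Building peptides and slabs

Conformations are built from internal coordinates (standard backbone
bond geometry, ω = 180°, φ/ψ presets — `"extended"` by default) with
side chains placed by per-residue z-matrices; the proline ring is
closed geometrically in the plane of N/CA/CB so every ring bond takes
its ideal length. All residues are L-enantiomers, enforced by the CB
placement dihedral and checked by a chirality test. The equilibrium
bond lengths and angles of the reduced force field are read off the
as-built geometry, so a fresh peptide sits exactly at its bonded
minimum — torsions and nonbonded terms are the only strain a build
carries.

`build_fcc_slab()` generates ABC-stacked (111) layers (interlayer
spacing $a/\sqrt3$, in-plane nearest neighbour $a/\sqrt2$; 2.3556 Å
and 2.8850 Å for Au's $a = 4.08$ Å). Only (111) is supported: the
peptides in scope show no adsorption preference on the (100)/(110)
facets, so those builders are deliberately rejected rather than
half-supported. `surface_registry()` exposes the three lateral site
classes of the (111) surface — `top`, `hcp` (above a second-layer
atom), `fcc` (above a third-layer atom) — as a periodic classifier,
which is what the lock-and-key analysis consumes.

## The STUN-BH search

Basin hopping explores the space of local minima: perturb, minimize,
accept/reject. Stochastic tunneling replaces the raw energy in the
acceptance rule with

$$f(E) = 1 - \exp(-\gamma\,(E - E_\mathrm{ref})),$$

where $E_\mathrm{ref}$ is the best energy found so far. $f$ is
strictly increasing (so minima keep their order — a tested property)
and bounded above by 1, so barriers far above the current best are
flattened and the walker can cross them. Design choices the published
protocol leaves open, resolved here:

* **Transform form and γ.** The exponential form above, with γ
  auto-calibrated per start: the energy spread of the first ten moves
  is mapped to $f \approx 0.9$ and γ is then frozen. A fixed γ can be
  supplied instead. Below $E_\mathrm{ref}$ the transform is left
  unclamped (it goes negative); since $E_\mathrm{ref}$ tracks the
  running best this occurs only in the instant before the reference is
  updated, and keeping it monotone everywhere is what preserves
  ordering.
* **Acceptance temperature.** Metropolis on the dimensionless
  transformed surface with inverse temperature β (default 5), which
  gives mid-range acceptance on the bundled fixtures; exposed in
  `stunbh_config()`.
* **Objective.** Local minimization acts on the total potential energy
  of the complex (with a rigid slab this equals minimizing
  $E_\mathrm{peptide} + E_\mathrm{cross}$); acceptance and ranking use
  the single-point $E_\mathrm{BE}$ evaluated after each minimization.
  Both values are reported.
* **Reference scope.** $E_\mathrm{ref}$ is per start — starts are
  independent and reproducible in isolation, and the multistart driver
  seeds each from the master seed.
* **Moves.** Only high-temperature MD kicks (default 500 K, 300 steps,
  2 fs, Nosé–Hoover); dihedral space is explored through the dynamics
  rather than enumerated.
* **Iteration accounting.** Iteration 1 of a start is the initial
  minimization; each further iteration is one perturb → minimize →
  accept cycle. A schedule of 1000 starts × 200 iterations therefore
  plans exactly 200,000 iterations, and `iterations = 1` degenerates
  to a single conjugate-gradient minimization — both are tested.
* **Deduplication.** Two per-start minima are the same state when
  their energies differ by < 0.1 kcal/mol *and* their mobile-atom RMSD
  after optimal (Kabsch) superposition is < 0.5 Å; first found wins.
* **Placement.** Uniform random rigid rotation, uniform lateral
  position in the cell, base height of the lowest peptide atom drawn
  from 3–8 Å above the top layer, lifted in 0.5 Å steps until no
  peptide–slab contact is closer than 2.5 Å.

The local minimizer is conjugate gradients bracketed by short
quasi-Newton (L-BFGS-B) stages: CG line searches overshoot on the
steep $r^{-12}$ wall of clashed starts and can eject atoms, so a
capped quasi-Newton capture runs first and a polish pass afterwards
drives the gradient max-norm below tolerance. The search engine itself
is objective-agnostic (`stunbh_core()`), so the same production code
path is validated against brute-force oracles on an analytic 1-D
double well and on small LJ clusters whose global minima are known
(−3ε, −6ε, …).

## Molecular dynamics

Velocity-Verlet integration with three thermostat modes:

* **NVE** — validation mode. Energy conservation is measured as the
  *secular* drift (linear-regression slope of total energy over the
  run, relative, per ps), the standard definition; the bounded
  fluctuation of the shadow Hamiltonian scales as $\Delta t^2$ and is
  tested separately via the timestep-halving check.
* **Nosé–Hoover** (default NVT) — single thermostat variable, coupling
  time constant τ (default 25 fs). Used for production and for the
  perturbation moves.
* **Langevin** (BAOAB splitting) — selected explicitly by config,
  never silently. It exists because a single Nosé–Hoover chain is not
  ergodic on very small systems; the equipartition test (one restrained
  atom) uses it for exactly that reason.

The integration step is 0.5 fs for production. The 2 fs step is used
only for the high-temperature perturbation moves, where the kick's
purpose is configurational displacement and energy conservation is
irrelevant — the thermostat absorbs integration error; no separate
stability flag is raised for it. Positional restraints (the
equilibration stage before releasing a peptide in water) are harmonic
with $k = 10$ kcal/mol/Å² by default; the published spring-constant unit (per Å) is read as the conventional per-Å² spring constant.
Degrees of freedom count $3N_\mathrm{mobile}$ when anything external
(fixed slab, restraint) acts on the mobile atoms and
$3N_\mathrm{mobile}-3$ otherwise.

Water is a **flexible 3-site model** (TIP3P-like charges and LJ on
oxygen, stiff internal harmonics) rather than rigid water: at 0.5 fs no
constraint solver is needed, at the price of intramolecular water
vibrations in the spectrum — a documented deviation. `solvate()`
fills a box on a jittered grid at liquid density (0.997 g/cm³) or to a
requested count, keeps water oxygens ≥ 2.4 Å from solute heavy atoms,
and is exactly inverted by `delete_waters()`. Water-environment and
vacuum runs share every code path except solvation.

## Adsorption analysis

A flat aromatic ring on (111) can enclose a top-layer metal atom while
its ring atoms line up with the subsurface lattice — the lock-and-key
(LAK) geometry that strengthens the dispersion contact. The original
evidence for this is visual; this package operationalizes it with
explicit, config-exposed thresholds (`analysis_thresholds()`):

* tilt = angle between the least-squares ring normal and the surface
  normal, folded to [0°, 90°];
* **flat-on**: tilt ≤ 20° with the centroid ≤ 4.5 Å above the top
  layer; **stand-up**: tilt ≥ 60° with the lowest ring atom in
  contact; **detached**: centroid > 6 Å; anything else (and any ring
  beyond the 0.3 Å planarity tolerance) is **intermediate**;
* **LAK**: a flat-on ring whose centroid projects within 0.8 Å
  laterally of a top-layer atom; the report also lists the site class
  under every ring atom.

These numbers are interpretive definitions, not measured constants;
outputs should be read with that in mind. The environment-comparison
table reports per-configuration vacuum/water energies and pairwise
percent differences $100\,(E_a - E_b)/E_b$ with the reference stated
per row; fed with the published S7 adsorption energies it returns the
1.1% (vacuum) and 11.88% (water) contrasts (the originally printed
11.89% reflects rounding of the table energies). Water-phase
adsorption energies from trajectories are time-averages of the
peptide–surface interaction over the final half of the production run,
since the published values state no averaging window.
On-surface mobility is the in-plane center-of-mass displacement from
the first frame, with frame-to-frame increments minimum-image
corrected so wrapped trajectories unwrap correctly.

## What the fixtures emulate — and what passing tests show

The bundled fixtures (`make_fixture()`) are designed so every module is
testable against an oracle without external data: LJ clusters with
known global minima, an analytic double well with a grid-search oracle,
a harmonic dimer with a closed-form period, a 175-atom tripeptide on
Au(111), and flat/stand-up aromatic-ring probes built directly from the
surface-registry geometry. They emulate the *structure* of the real
problem — a flexible adsorbate over a rigid periodic metal, ring/site
registry, thermal perturbation — at sizes where brute force is
possible. They do not emulate real aqueous electrolytes, peptide
concentration effects, metal polarization, or nanosecond relaxation
times; a green suite therefore validates the machinery and its
contracts, not the experimental adsorption energies of any specific
peptide.

Problem sizes used by the suite and the acceptance script are the
package's own desk-scale choices: searches of 10 starts × 6 iterations
on LJ3/LJ4, 50 seeded double-well runs, 2 ps NVE and NVT runs on the
175-atom fixture and a 163-atom solvated box (45 waters), 4000 steps at
0.5 fs. Study-scale settings (1000 × 200, 6-layer 13 × 13 slabs, 2350
waters, nanoseconds) remain reachable through `default_run_config()`.

## Other design choices

* Run configuration is a single YAML file; all physics constants (12 Å
  cutoff, 10 kcal/mol/Å² spring, 300/500 K, 0.5/2 fs, 6 layers,
  $a = 4.08$ Å, 2350 waters) live in `default_run_config()` and every
  run echoes its fully merged configuration, so any output can be
  regenerated from the echo plus the seed.
* Kabsch superposition is implemented directly on coordinate matrices
  (via SVD) for the deduplication RMSD.
* PDB and XYZ readers/writers are implemented in-package with
  line-number diagnostics; the test suite cross-checks PDB round trips
  against an independent reader (bio3d).
* Per-residue binding energies are defined as peptide–surface nonbonded
  terms only (no intra-peptide contributions), so the profile sums
  exactly to the surface-interaction total; caps appear as their own
  ACE/NH2 rows.

## Known limitations

Reduced parameter set (orderings and contrasts, not absolute published
energies); rigid uncharged metal with no image-charge/polarization
response; no Ewald electrostatics; flexible rather than rigid water; no
free-energy estimates (ranking is by interaction energy, as the published workflow does, deferring binding free energies); vacuum-only
global search (water enters through MD relaxation of the best vacuum
configurations — searching in explicit water is computationally out of
reach for this iteration count); residues outside
{Ser, Phe, Pro, Gln, Asn} and D-amino acids are rejected.
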