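# pepsurf

Computer-aided screening of **peptide capping agents** for metal
nanoparticles. A capping agent is a molecule that adsorbs selectively on
one crystallographic facet of a growing nanoparticle, suppressing growth
there and steering the final particle shape. `pepsurf` implements the
simulation side of that design loop for small capped peptides on the FCC
metal (111) facet: it builds peptides from sequence, generates the slab,
searches globally for low-lying adsorption configurations, relaxes them
with molecular dynamics (optionally in explicit water), and produces the
interpretive analyses — per-residue binding profiles, ring orientation
classes and lock-and-key (LAK) registry detection — used to rank
candidate sequences such as Ac-SSFPQPN-NH2 ("S7") and the designed
8-mers Ac-PFSPFSPF-NH2 and Ac-FSFSFSFS-NH2.

## The method

The central quantity is the adsorption (binding) energy

```
E_BE = E_peptide/surface − E_peptide − E_substrate
```

evaluated as a single-point decomposition (all three terms at the same
coordinates); more negative means more stable adsorption. Configurations
are found with **STUN-BH** — basin hopping whose Metropolis acceptance
acts on a stochastically *tunneled* energy surface

```
f(E) = 1 − exp(−γ (E − E_ref)),    E_ref = best energy found so far
```

which compresses barriers above the current best toward 1 while
preserving the location and ordering of all minima. Each iteration:

1. perturb the current configuration with a short high-temperature MD
   run (500 K, 300 steps, 2 fs);
2. minimize it with conjugate gradients (quasi-Newton bracketed for
   robustness);
3. accept or reject by Metropolis on `f(E_BE)`.

Production runs schedule many independent starts (the study-scale
default is 1000 starts × 200 iterations = 200,000 iterations) with
random rigid-body placements of the peptide above the slab. Energies
come from an embedded, reduced heavy-atom force field with Amber-class
functional forms (harmonic bonds/angles, cosine dihedrals, 12-6 LJ +
Coulomb with a switched 12 Å cutoff, Lorentz–Berthelot mixing, Amber 1-4
scaling); the metal is a lattice of uncharged LJ sites and the slab is
rigid. See the vignette (`vignettes/peptide-capping-design.Rmd`) for the
full model description and its limitations.

## Worked example

```r
library(pepsurf)

molecular_weight("Ac-SSFPQPN-NH2")
#> [1] 816.8682

pep  <- build_conformation("Ac-SSFPQPN-NH2")      # 58 heavy atoms
slab <- build_fcc_slab("Au", a = 4.08, n_layers = 6)
slab$slab$spacing                                  # 2.355589  (= 4.08/sqrt(3))

fx  <- make_fixture("tripeptide_on_slab")          # Ac-SFP-NH2 on Au(111)
min <- local_minimize(fx$system, tol = 1e-3, max_iter = 800)
min$e_be
#> [1] -102.9742

per_residue_binding(min$system)
#>   resid resname     e_bind
#> 1     1     ACE -14.206450
#> 2     2     SER -24.195519
#> 3     3     PHE -44.174455
#> 4     4     PRO -14.924850
#> 5     5     NH2  -5.472883

environment_comparison(
  vacuum = c(`S7-1` = -250.06, `S7-2` = -252.84),
  water  = c(`S7-1` = -235.23, `S7-2` = -210.26))$contrasts
#>  environment    a    b percent_difference reference
#>       vacuum S7-1 S7-2          -1.099510      S7-2
#>        water S7-1 S7-2          11.875773      S7-2
```

The last call reproduces the two published S7 contrasts: in vacuum the
two best configurations differ by ~1.1%, while in water the
LAK-stabilized configuration binds ~11.9% more strongly — the signature
used to pick capping candidates.

A small global search on a bundled cluster fixture:

```r
fx  <- make_fixture("lj4")
res <- multistart_search(fx$system, NULL,
                         stunbh_config(n_starts = 10, iterations = 6, seed = 42,
                                       perturb_md = list(n_steps = 100,
                                                         temperature = 400)))
res$minima[[1]]$e_be   # -6  (the LJ4 tetrahedron, in units of eps)
```

A thin CLI wraps the same functions
(`inst/scripts/pepsurf-cli.R`): subcommands `build`, `slab`, `search`,
`md`, `analyze`, `report`, `fixtures`.

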