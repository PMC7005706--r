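Package: pepsurf
Title: Peptide Adsorption on FCC Metal Facets by Stochastic-Tunneling Basin Hopping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided design of peptide capping agents for
    metal nanoparticles. Builds capped peptides (acetyl/amide termini) from
    sequence with an embedded reduced Amber-class force field, generates FCC
    (111) metal slabs, evaluates molecular-mechanics energies, analytic
    forces and peptide-surface binding energies, and searches for low-lying
    adsorption configurations with a stochastic-tunneling basin-hopping
    (STUN-BH) global optimizer whose moves are short high-temperature
    molecular-dynamics runs. Includes NVT/NVE dynamics with Nose-Hoover and
    Langevin thermostats, positional restraints and explicit 3-site water,
    plus adsorption analysis: lock-and-key ring-registry detection,
    flat-on/stand-up ring classification, per-residue binding-energy
    profiles, vacuum/water comparison tables and on-surface mobility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
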