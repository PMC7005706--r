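# Embedded reduced force-field tables for the residues handled by the
# package: Ser, Phe, Pro, Gln, Asn plus acetyl/amide caps, a 3-site water
# and the metal LJ site.  The representation is heavy-atom ("united-atom"):
# nonpolar hydrogens are folded into their carbon (mass and charge), polar
# groups appear as single charged heavy sites.  Functional forms are
# Amber-class (harmonic bonds/angles, cosine dihedrals, 12-6 LJ +
# Coulomb with Lorentz-Berthelot mixing and 1-4 scaling); the numerical
# values are the package's own reduced set, not any published parameter
# file.

# ---- average residue masses (Da), for molecular weights ----------------
# Standard average masses of the residue (amino acid minus water).
.residue_masses <- c(
  S = 87.0782, F = 147.1766, P = 97.1167, Q = 128.1307, N = 114.1038
)
.mass_water <- 18.01528
.mass_acetyl_delta <- 42.0367   # acetyl cap adds C2H2O
.mass_amide_delta <- -0.9847    # C-terminal amide replaces OH with NH2

.three_to_one <- c(SER = "S", PHE = "F", PRO = "P", GLN = "Q", ASN = "N")
.one_to_three <- c(S = "SER", F = "PHE", P = "PRO", Q = "GLN", N = "ASN")

# ---- Lennard-Jones atom-type table (eps kcal/mol, sigma A) -------------
# CT  sp3 united carbon (CH/CH2/CH3)   CAro aromatic united CH carbon
# C   carbonyl carbon                  O    carbonyl oxygen
# OH  hydroxyl oxygen (united OH)      N    amide/amine nitrogen (united)
# AU  gold LJ site (uncharged, CHARMM-METAL-style 12-6 well)
# OW/HW flexible 3-site water
.lj_types <- data.frame(
  type  = c("CT", "CAro", "C", "O", "OH", "N", "AU", "OW", "HW", "LJ"),
  eps   = c(0.1094, 0.0860, 0.0860, 0.2100, 0.2104, 0.1700, 5.2900,
            0.1521, 0.0000, 1.0000),
  sigma = c(3.40, 3.55, 3.40, 2.96, 3.07, 3.25, 2.629, 3.1507, 1.00, 3.00),
  stringsAsFactors = FALSE
)

# ---- residue templates -------------------------------------------------
# Each template: atoms (name/element/type/charge/mass), the side-chain
# z-matrix rows used by the builder, bond list (within-residue, by name),
# and ring membership.  Backbone atoms N, CA, C, O are shared by all
# residues; caps have their own atom sets.  Charges sum to the formal
# charge (0 for every supported residue).

.bb_atoms <- function(pro = FALSE) {
  data.frame(
    name = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    type = c("N", "CT", "C", "O"),
    charge = c(if (pro) -0.20 else -0.10, 0.10, 0.45, -0.45),
    mass = c(if (pro) 14.007 else 15.015, 13.019, 12.011, 15.999),
    stringsAsFactors = FALSE
  )
}

.sc <- function(name, element, type, charge, mass) {
  data.frame(name = name, element = element, type = type,
             charge = charge, mass = mass, stringsAsFactors = FALSE)
}

.bb_bonds <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))

# z-matrix row: place `atom` bonded to `c` with bond length r, angle
# (b, c, atom) = theta (deg), dihedral (a, b, c, atom) = phi (deg).
.z <- function(atom, a, b, c, r, theta, phi) {
  list(atom = atom, a = a, b = b, c = c, r = r, theta = theta, phi = phi)
}

.residue_table <- list(
  S = list(
    code3 = "SER",
    atoms = rbind(.bb_atoms(),
                  .sc(c("CB", "OG"), c("C", "O"), c("CT", "OH"),
                      c(0.25, -0.25), c(14.027, 17.007))),
    zmat = list(
      .z("OG", "N", "CA", "CB", 1.417, 110.8, 180)
    ),
    bonds = rbind(.bb_bonds, c("CA", "CB"), c("CB", "OG")),
    ring = character(0)
  ),
  F = list(
    code3 = "PHE",
    atoms = rbind(.bb_atoms(),
                  .sc(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      rep("C", 7),
                      c("CT", rep("CAro", 6)),
                      rep(0, 7),
                      c(14.027, 12.011, rep(13.019, 5)))),
    zmat = list(
      .z("CG",  "N",  "CA", "CB", 1.510, 114.0, 180),
      .z("CD1", "CA", "CB", "CG", 1.390, 120.0, 90),
      .z("CD2", "CA", "CB", "CG", 1.390, 120.0, -90),
      .z("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
      .z("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
      .z("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0)
    ),
    bonds = rbind(.bb_bonds, c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                  c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
                  c("CE1", "CZ"), c("CE2", "CZ")),
    ring = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ),
  P = list(
    code3 = "PRO",
    atoms = rbind(.bb_atoms(pro = TRUE),
                  .sc(c("CB", "CG", "CD"), rep("C", 3), rep("CT", 3),
                      c(0, 0, 0.10), rep(14.027, 3))),
    # ring atoms CG, CD are closed geometrically by the builder
    zmat = list(),
    bonds = rbind(.bb_bonds, c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                  c("CD", "N")),
    ring = c("N", "CA", "CB", "CG", "CD")
  ),
  Q = list(
    code3 = "GLN",
    atoms = rbind(.bb_atoms(),
                  .sc(c("CB", "CG", "CD", "OE1", "NE2"),
                      c("C", "C", "C", "O", "N"),
                      c("CT", "CT", "C", "O", "N"),
                      c(0, 0, 0.55, -0.47, -0.08),
                      c(14.027, 14.027, 12.011, 15.999, 16.023))),
    zmat = list(
      .z("CG",  "N",  "CA", "CB", 1.530, 111.0, 180),
      .z("CD",  "CA", "CB", "CG", 1.520, 112.0, 180),
      .z("OE1", "CB", "CG", "CD", 1.230, 121.0, 0),
      .z("NE2", "CB", "CG", "CD", 1.330, 116.5, 180)
    ),
    bonds = rbind(.bb_bonds, c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                  c("CD", "OE1"), c("CD", "NE2")),
    ring = character(0)
  ),
  N = list(
    code3 = "ASN",
    atoms = rbind(.bb_atoms(),
                  .sc(c("CB", "CG", "OD1", "ND2"),
                      c("C", "C", "O", "N"),
                      c("CT", "C", "O", "N"),
                      c(0, 0.55, -0.47, -0.08),
                      c(14.027, 12.011, 15.999, 16.023))),
    zmat = list(
      .z("CG",  "N",  "CA", "CB", 1.520, 112.5, 180),
      .z("OD1", "CA", "CB", "CG", 1.230, 121.0, 0),
      .z("ND2", "CA", "CB", "CG", 1.330, 116.5, 180)
    ),
    bonds = rbind(.bb_bonds, c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"),
                  c("CG", "ND2")),
    ring = character(0)
  )
)

.cap_ace <- list(
  code3 = "ACE",
  atoms = .sc(c("CH3", "C", "O"), c("C", "C", "O"), c("CT", "C", "O"),
              c(0, 0.45, -0.45), c(15.035, 12.011, 15.999)),
  bonds = rbind(c("CH3", "C"), c("C", "O"))
)

.cap_nh2 <- list(
  code3 = "NH2",
  atoms = .sc("N", "N", "N", 0, 16.023),
  bonds = matrix(character(0), ncol = 2)
)

.water_template <- list(
  code3 = "HOH",
  atoms = .sc(c("OW", "HW1", "HW2"), c("O", "H", "H"),
              c("OW", "HW", "HW"), c(-0.834, 0.417, 0.417),
              c(15.999, 1.008, 1.008)),
  bonds = rbind(c("OW", "HW1"), c("OW", "HW2")),
  bond_k = 450, bond_r0 = 0.9572,
  angle_k = 55, angle_theta0 = 104.52 * pi / 180
)

#' Residue and cap templates of the embedded force field
#'
#' Returns the reduced heavy-atom templates used to build peptides:
#' atom names, elements, MM types, partial charges (e), united-atom
#' masses, within-residue bonds and ring membership, for Ser, Phe, Pro,
#' Gln, Asn and the acetyl / amide caps.
#'
#' @param code Optional one- or three-letter residue code; if missing the
#'   full table is returned.
#' @return A template list (or list of templates) with elements `atoms`,
#'   `bonds`, `ring`, `code3`.
#' @export
residue_templates <- function(code) {
  if (missing(code)) return(.residue_table)
  code1 <- .normalize_code(code)
  .residue_table[[code1]]
}

#' @keywords internal
.normalize_code <- function(code) {
  code <- toupper(code)
  if (nchar(code) == 3) {
    if (!code %in% names(.three_to_one))
      stop("unsupported residue code: ", code, call. = FALSE)
    return(unname(.three_to_one[code]))
  }
  if (!code %in% names(.residue_table))
    stop("unsupported residue code: ", code, call. = FALSE)
  code
}

#' Lennard-Jones parameters of the embedded atom types
#'
#' @return Data frame with columns `type`, `eps` (kcal/mol), `sigma`
#'   (Angstrom). Metal sites (`AU`) carry zero charge and interact only
#'   through the 12-6 well; mixing is Lorentz-Berthelot.
#' @export
lj_type_table <- function() .lj_types
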