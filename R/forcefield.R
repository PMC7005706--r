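# Molecular-mechanics energy evaluation: R wrappers around the compiled
# kernel, the adsorption (binding) energy of Eq.-style single-point
# decomposition, and the per-residue surface-interaction profile.

#' Default force-field parameters
#'
#' @param cutoff Nonbonded cutoff in Angstrom (default 12, applied to
#'   both LJ and short-range electrostatics).
#' @param switch_on Start of the switching window (default `cutoff - 2`);
#'   energies go C1-continuously to zero across `[switch_on, cutoff]`.
#' @param scale_lj14,scale_coul14 Amber-style 1-4 scale factors.
#' @param types LJ type table; defaults to the embedded table
#'   ([lj_type_table()]).
#' @return Object of class `ff_params`.
#' @export
default_forcefield <- function(cutoff = 12, switch_on = cutoff - 2,
                               scale_lj14 = 0.5, scale_coul14 = 1 / 1.2,
                               types = lj_type_table()) {
  stopifnot(cutoff > 0, switch_on > 0, switch_on < cutoff,
            all(types$eps >= 0), all(types$sigma > 0))
  structure(list(cutoff = cutoff, switch_on = switch_on,
                 scale_lj14 = scale_lj14, scale_coul14 = scale_coul14,
                 types = types),
            class = "ff_params")
}

#' @keywords internal
.resolve_lj <- function(system, params) {
  m <- match(system$atoms$type, params$types$type)
  if (anyNA(m)) {
    bad <- unique(system$atoms$type[is.na(m)])
    stop("missing LJ parameters for atom type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(eps = params$types$eps[m], sigma = params$types$sigma[m])
}

#' @keywords internal
.kernel_eval <- function(system, params) {
  lj <- .resolve_lj(system, params)
  topo <- system$topology
  group_chr <- system$atoms$group
  glevels <- c("peptide", "surface", "water", "other")
  gint <- match(group_chr, glevels) - 1L
  surface_group <- if (any(group_chr == "surface")) 1L else -1L
  z <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m - 1L
  }
  .ff_eval_cpp(system$coords,
               z(topo$bonds), topo$bond_k, topo$bond_r0,
               z(topo$angles), topo$angle_k, topo$angle_theta0,
               z(topo$dihedrals), topo$dihedral_k,
               as.integer(topo$dihedral_n), topo$dihedral_phi0,
               system$atoms$charge, lj$eps, lj$sigma,
               z(topo$excl), z(topo$pairs14),
               params$scale_lj14, params$scale_coul14,
               system$cell,
               params$cutoff, params$switch_on,
               gint, surface_group)
}

#' @keywords internal
.restraint_energy <- function(coords, restraints) {
  if (is.null(restraints)) return(list(e = 0, f = NULL))
  dx <- coords[restraints$idx, , drop = FALSE] - restraints$anchors
  list(e = restraints$k * sum(dx^2), f = -2 * restraints$k * dx)
}

#' Total molecular-mechanics energy
#'
#' Evaluates harmonic bonds and angles, cosine proper dihedrals, and
#' switched 12-6 LJ + Coulomb nonbonded terms (1-2/1-3 excluded, 1-4
#' scaled, minimum image in-plane when a cell is present).  Pairs
#' internal to the rigid `"surface"` group are skipped: the substrate's
#' internal energy is constant and taken as the zero of energy.
#'
#' @param system A `molsys`.
#' @param params `ff_params` from [default_forcefield()].
#' @param restraints Optional positional restraints: list with `idx`
#'   (atom indices), `anchors` (matching coordinates), `k`
#'   (kcal/mol/A^2; energy `k * |dx|^2`).
#' @return `energy_breakdown`: components `e_bond`, `e_angle`,
#'   `e_dihedral`, `e_lj`, `e_coul`, `e_restraint` (kcal/mol), their sum
#'   `total`, the peptide/adsorbate-surface subtotal `e_surface`
#'   (contained in `e_lj + e_coul`), and `surface_per_atom`.
#' @export
total_energy <- function(system, params = default_forcefield(),
                         restraints = NULL) {
  k <- .kernel_eval(system, params)
  r <- .restraint_energy(system$coords, restraints)
  total <- k$e_bond + k$e_angle + k$e_dihedral + k$e_lj + k$e_coul + r$e
  structure(list(e_bond = k$e_bond, e_angle = k$e_angle,
                 e_dihedral = k$e_dihedral, e_lj = k$e_lj,
                 e_coul = k$e_coul, e_restraint = r$e,
                 e_surface = k$e_surface, total = total,
                 surface_per_atom = k$surface_per_atom),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (kcal/mol)\n")
  for (nm in c("e_bond", "e_angle", "e_dihedral", "e_lj", "e_coul",
               "e_restraint", "e_surface", "total"))
    cat(sprintf("  %-11s %14.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' Analytic forces
#'
#' Negative gradient of [total_energy()]; atoms flagged fixed are
#' reported with zero force.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix, kcal/mol/A.
#' @export
forces <- function(system, params = default_forcefield(),
                   restraints = NULL) {
  k <- .kernel_eval(system, params)
  f <- k$forces
  r <- .restraint_energy(system$coords, restraints)
  if (!is.null(r$f)) f[restraints$idx, ] <- f[restraints$idx, ] + r$f
  f[system$atoms$fixed, ] <- 0
  f
}

#' Binding-energy arithmetic
#'
#' `E_BE = E_complex - E_peptide - E_substrate`; lower (more negative)
#' values mean more stable adsorption.
#' @param e_complex,e_peptide,e_substrate Potential energies (kcal/mol).
#' @return E_BE in kcal/mol.
#' @export
eq_binding <- function(e_complex, e_peptide, e_substrate) {
  e_complex - e_peptide - e_substrate
}

#' Adsorption (binding) energy of a peptide-surface complex
#'
#' Single-point decomposition: the peptide and substrate fragments are
#' evaluated at exactly the coordinates they hold inside the complex,
#' and `E_BE = E_complex - E_peptide - E_substrate`.  When the peptide
#' sits beyond the nonbonded cutoff from the slab, E_BE is exactly 0.
#'
#' @param complex A `molsys` containing the peptide and the surface
#'   (groups `"peptide"` and `"surface"`); water, if present, is not
#'   allowed on this code path -- pass explicit fragments instead.
#' @param peptide,substrate Optional explicit fragment systems; by
#'   default they are subset out of `complex` by group.
#' @param params `ff_params`.
#' @return List with `e_be`, `e_complex`, `e_peptide`, `e_substrate`
#'   (kcal/mol).
#' @export
binding_energy <- function(complex, peptide = NULL, substrate = NULL,
                           params = default_forcefield()) {
  if (is.null(peptide) || is.null(substrate)) {
    if (any(complex$atoms$group == "water"))
      stop("complex contains water; pass explicit peptide/substrate ",
           "fragments", call. = FALSE)
    peptide <- subset_system(complex, complex$atoms$group != "surface")
    substrate <- subset_system(complex, complex$atoms$group == "surface")
  }
  if (n_atoms(peptide) + n_atoms(substrate) != n_atoms(complex))
    stop("fragment/complex atom count mismatch", call. = FALSE)
  el <- c(peptide$atoms$element, substrate$atoms$element)
  if (!identical(sort(el), sort(complex$atoms$element)))
    stop("fragment/complex element mismatch", call. = FALSE)
  ec <- total_energy(complex, params)$total
  ep <- total_energy(peptide, params)$total
  es <- total_energy(substrate, params)$total
  list(e_be = eq_binding(ec, ep, es), e_complex = ec, e_peptide = ep,
       e_substrate = es)
}

#' Per-residue binding-energy profile
#'
#' Splits the peptide-surface nonbonded interaction by the peptide
#' residue each atom belongs to (caps appear as their own ACE/NH2 rows).
#' The profile rows sum to the `e_surface` total of [total_energy()].
#'
#' @param complex A `molsys` with groups `"peptide"` and `"surface"`.
#' @param params `ff_params`.
#' @return Data frame `resid`, `resname`, `e_bind` (kcal/mol), ordered N
#'   to C.
#' @export
per_residue_binding <- function(complex, params = default_forcefield()) {
  pep <- complex$atoms$group == "peptide"
  if (!any(pep)) stop("no peptide atoms in complex", call. = FALSE)
  if (any(is.na(complex$atoms$resid[pep])))
    stop("unlabeled peptide atoms (missing resid)", call. = FALSE)
  e <- total_energy(complex, params)
  per_atom <- e$surface_per_atom[pep]
  rid <- complex$atoms$resid[pep]
  agg <- tapply(per_atom, rid, sum)
  ord <- order(as.integer(names(agg)))
  resname <- complex$atoms$resname[pep][match(names(agg)[ord], rid)]
  data.frame(resid = as.integer(names(agg)[ord]),
             resname = resname,
             e_bind = as.numeric(agg[ord]))
}
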