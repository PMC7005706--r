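# The molecular-system container shared by every module: an atom table,
# coordinates in Angstrom, a bonded topology with nonbonded exclusions,
# an optional in-plane periodic cell and an optional slab record.

#' Construct a molecular system
#'
#' @param atoms Data frame with columns `name`, `element`, `resid`,
#'   `resname`, `type`, `charge`, `mass`, `group` (one of `"peptide"`,
#'   `"surface"`, `"water"`, `"other"`), `fixed` (logical).
#' @param coords Numeric n x 3 matrix (Angstrom).
#' @param topology List with integer matrices `bonds`, `angles`,
#'   `dihedrals` (1-based atom indices) and parameter vectors
#'   `bond_k`, `bond_r0`, `angle_k`, `angle_theta0`, `dihedral_k`,
#'   `dihedral_n`, `dihedral_phi0`; see [build_conformation()].
#' @param cell Optional 2 x 2 matrix whose columns are the in-plane
#'   lattice vectors (x, y components); the surface normal (+z) is open.
#' @param slab Optional slab metadata (see [build_fcc_slab()]).
#' @return Object of class `molsys`.
#' @export
molecular_system <- function(atoms, coords, topology = empty_topology(),
                             cell = NULL, slab = NULL) {
  coords <- as.matrix(coords)
  stopifnot(is.data.frame(atoms), ncol(coords) == 3,
            nrow(coords) == nrow(atoms))
  needed <- c("name", "element", "resid", "resname", "type", "charge",
              "mass", "group", "fixed")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    stopifnot(nrow(cell) == 2, ncol(cell) == 2)
  }
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, topology = topology,
                 cell = cell, slab = slab),
            class = "molsys")
}

#' @export
print.molsys <- function(x, ...) {
  g <- table(x$atoms$group)
  cat("<molsys> ", nrow(x$atoms), " atoms (",
      paste(names(g), g, sep = ":", collapse = ", "), "), ",
      nrow(x$topology$bonds), " bonds",
      if (!is.null(x$cell)) ", periodic in-plane" else "", "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system
#' @param system A `molsys`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' @keywords internal
empty_topology <- function() {
  im <- function(k) matrix(integer(0), ncol = k)
  list(bonds = im(2), bond_k = numeric(0), bond_r0 = numeric(0),
       angles = im(3), angle_k = numeric(0), angle_theta0 = numeric(0),
       dihedrals = im(4), dihedral_k = numeric(0),
       dihedral_n = integer(0), dihedral_phi0 = numeric(0),
       excl = im(2), pairs14 = im(2))
}

# ---- topology derivation ----------------------------------------------

# Enumerate angles (i-j-k) and proper dihedrals (i-j-k-l) from the bond
# graph, and the 1-2/1-3 exclusion and 1-4 pair lists.
#' @keywords internal
derive_connectivity <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  angles <- list(); dihedrals <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (c1 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, c1], j, cmb[2, c1])
    }
  }
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      j <- bonds[b, 1]; k <- bonds[b, 2]
      for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
        if (i == l) next  # 4-ring degenerate torsion
        dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
      }
    }
  }
  ang <- if (length(angles)) do.call(rbind, angles) else matrix(integer(0), ncol = 3)
  dih <- if (length(dihedrals)) do.call(rbind, dihedrals) else matrix(integer(0), ncol = 4)
  # canonical orientation + dedup for dihedrals
  if (nrow(dih)) {
    flip <- dih[, 2] > dih[, 3]
    dih[flip, ] <- dih[flip, 4:1]
    dih <- unique(dih)
  }
  list(adj = adj, angles = ang, dihedrals = dih)
}

#' @keywords internal
nonbonded_pairs_from_topology <- function(bonds, angles, dihedrals) {
  key <- function(m, i, j) {
    a <- pmin(m[, i], m[, j]); b <- pmax(m[, i], m[, j])
    cbind(a, b)
  }
  excl <- rbind(
    if (nrow(bonds)) key(bonds, 1, 2),
    if (nrow(angles)) key(angles, 1, 3)
  )
  excl <- if (is.null(excl)) matrix(integer(0), ncol = 2) else unique(excl)
  p14 <- if (nrow(dihedrals)) unique(key(dihedrals, 1, 4)) else
    matrix(integer(0), ncol = 2)
  # a 1-4 pair that is also 1-2/1-3 (rings) stays excluded
  if (nrow(p14) && nrow(excl)) {
    ek <- paste(excl[, 1], excl[, 2])
    p14 <- p14[!paste(p14[, 1], p14[, 2]) %in% ek, , drop = FALSE]
  }
  list(excl = excl, pairs14 = p14)
}

# Parameter assignment for derived terms: equilibrium values are taken
# from the as-built geometry (the template geometry defines the bonded
# minimum of the reduced force field); force constants and torsion
# barriers are assigned by type class.
#' @keywords internal
assign_bonded_params <- function(atoms, coords, bonds, angles, dihedrals) {
  dist1 <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  bond_r0 <- vapply(seq_len(nrow(bonds)), function(b)
    dist1(bonds[b, 1], bonds[b, 2]), numeric(1))
  bond_k <- rep(300, nrow(bonds)) # kcal/mol/A^2

  angle_theta0 <- vapply(seq_len(nrow(angles)), function(a) {
    v1 <- coords[angles[a, 1], ] - coords[angles[a, 2], ]
    v2 <- coords[angles[a, 3], ] - coords[angles[a, 2], ]
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }, numeric(1))
  angle_k <- rep(60, nrow(angles)) # kcal/mol/rad^2

  ndih <- nrow(dihedrals)
  dihedral_k <- numeric(ndih); dihedral_n <- integer(ndih)
  dihedral_phi0 <- numeric(ndih)
  for (t in seq_len(ndih)) {
    j <- dihedrals[t, 2]; k <- dihedrals[t, 3]
    tj <- atoms$type[j]; tk <- atoms$type[k]
    if (tj == "CAro" && tk == "CAro") {          # aromatic ring planarity
      dihedral_k[t] <- 5; dihedral_n[t] <- 2L; dihedral_phi0[t] <- pi
    } else if ((tj == "C" && tk == "N") || (tj == "N" && tk == "C")) {
      dihedral_k[t] <- 10; dihedral_n[t] <- 2L; dihedral_phi0[t] <- pi
    } else {                                     # generic sp3 torsion
      dihedral_k[t] <- 0.3; dihedral_n[t] <- 3L; dihedral_phi0[t] <- 0
    }
  }
  list(bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
       angles = angles, angle_k = angle_k, angle_theta0 = angle_theta0,
       dihedrals = dihedrals, dihedral_k = dihedral_k,
       dihedral_n = dihedral_n, dihedral_phi0 = dihedral_phi0)
}

#' @keywords internal
finalize_topology <- function(atoms, coords, bonds) {
  conn <- derive_connectivity(bonds, nrow(atoms))
  topo <- assign_bonded_params(atoms, coords, bonds, conn$angles,
                               conn$dihedrals)
  nb <- nonbonded_pairs_from_topology(bonds, conn$angles, conn$dihedrals)
  topo$excl <- nb$excl
  topo$pairs14 <- nb$pairs14
  topo
}

# ---- combine / subset --------------------------------------------------

#' Merge two molecular systems
#'
#' Concatenates atoms, coordinates and topologies (indices of the second
#' system are shifted).  Cell and slab metadata are taken from whichever
#' input has them (the first wins on conflict).
#' @param a,b `molsys` objects.
#' @export
merge_systems <- function(a, b) {
  off <- n_atoms(a)
  shift <- function(m) if (nrow(m)) m + off else m
  ta <- a$topology; tb <- b$topology
  topo <- list(
    bonds = rbind(ta$bonds, shift(tb$bonds)),
    bond_k = c(ta$bond_k, tb$bond_k), bond_r0 = c(ta$bond_r0, tb$bond_r0),
    angles = rbind(ta$angles, shift(tb$angles)),
    angle_k = c(ta$angle_k, tb$angle_k),
    angle_theta0 = c(ta$angle_theta0, tb$angle_theta0),
    dihedrals = rbind(ta$dihedrals, shift(tb$dihedrals)),
    dihedral_k = c(ta$dihedral_k, tb$dihedral_k),
    dihedral_n = c(ta$dihedral_n, tb$dihedral_n),
    dihedral_phi0 = c(ta$dihedral_phi0, tb$dihedral_phi0),
    excl = rbind(ta$excl, shift(tb$excl)),
    pairs14 = rbind(ta$pairs14, shift(tb$pairs14))
  )
  atoms <- rbind(a$atoms, b$atoms)
  rownames(atoms) <- NULL
  molecular_system(atoms, rbind(a$coords, b$coords), topo,
                   cell = if (!is.null(a$cell)) a$cell else b$cell,
                   slab = if (!is.null(a$slab)) a$slab else b$slab)
}

#' Subset a molecular system by atom indices
#'
#' Keeps only bonded terms, exclusions and 1-4 pairs fully inside the
#' selection; indices are remapped.
#' @param system A `molsys`.
#' @param idx Integer atom indices (or logical mask).
#' @export
subset_system <- function(system, idx) {
  if (is.logical(idx)) idx <- which(idx)
  map <- integer(n_atoms(system)); map[idx] <- seq_along(idx)
  keep_terms <- function(m, pars) {
    if (!nrow(m)) return(list(m = m, keep = logical(0)))
    keep <- rowSums(matrix(m %in% idx, nrow = nrow(m))) == ncol(m)
    list(m = matrix(map[m[keep, , drop = FALSE]], ncol = ncol(m)),
         keep = keep)
  }
  t0 <- system$topology
  kb <- keep_terms(t0$bonds); ka <- keep_terms(t0$angles)
  kd <- keep_terms(t0$dihedrals)
  ke <- keep_terms(t0$excl); k14 <- keep_terms(t0$pairs14)
  topo <- list(
    bonds = kb$m, bond_k = t0$bond_k[kb$keep], bond_r0 = t0$bond_r0[kb$keep],
    angles = ka$m, angle_k = t0$angle_k[ka$keep],
    angle_theta0 = t0$angle_theta0[ka$keep],
    dihedrals = kd$m, dihedral_k = t0$dihedral_k[kd$keep],
    dihedral_n = t0$dihedral_n[kd$keep],
    dihedral_phi0 = t0$dihedral_phi0[kd$keep],
    excl = ke$m, pairs14 = k14$m
  )
  atoms <- system$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  molecular_system(atoms, system$coords[idx, , drop = FALSE], topo,
                   cell = system$cell, slab = system$slab)
}

# ---- geometry helpers --------------------------------------------------

#' @keywords internal
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
.unit <- function(v) v / sqrt(sum(v^2))

# Internal-coordinate (NERF) placement: position of atom d bonded to c,
# with |cd| = r, angle(b, c, d) = theta and dihedral(a, b, c, d) = phi
# (radians).
#' @keywords internal
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi),
          r * sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  m <- .cross3(b1, b2); n <- .cross3(b2, b3)
  x <- sum(m * n)
  y <- sum(m * b3) * sqrt(sum(b2^2))
  atan2(y, x)
}

#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}

# Kabsch optimal-superposition RMSD between two n x 3 coordinate sets.
#' @keywords internal
rmsd_superposed <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((yc %*% rot - xc)^2)))
}
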