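# Build 3-D conformations of capped peptides from internal coordinates.
# Backbone atoms are placed by standard bond geometry with a phi/psi
# preset; side chains follow per-residue z-matrix rows; the proline ring
# is closed geometrically in the plane of N, CA, CB.

.deg <- function(x) x * pi / 180

.bb_geom <- list(
  r_CN = 1.335, r_NCA = 1.458, r_CAC = 1.525, r_CO = 1.231, r_CACB = 1.530,
  a_CACN = 116.6, a_CNCA = 121.7, a_NCAC = 111.1, a_CACO = 120.5,
  a_NCACB = 110.5, a_NCACB_pro = 103.3,
  d_CB = -122.6,   # dihedral(C_prev, N, CA, CB) - phi; fixes L chirality
  omega = 180
)

.backbone_presets <- list(
  extended = list(phi = -140, psi = 140),
  alpha = list(phi = -57, psi = -47)
)

#' Build a 3-D conformation of a capped peptide
#'
#' Places backbone and side-chain heavy atoms from standard internal
#' coordinates at the requested phi/psi preset (omega fixed at 180), then
#' derives the full molecular-mechanics topology (bonds, angles, proper
#' dihedrals, 1-2/1-3 exclusions, scaled 1-4 pairs).  Equilibrium bond
#' lengths and angles of the reduced force field are taken from the
#' as-built geometry, so a freshly built peptide sits at its bonded
#' minimum.  All residues are built as L-enantiomers.
#'
#' @param seq A `peptide_sequence` or sequence string.
#' @param backbone `"extended"` (default), `"alpha"`, or a list with
#'   numeric vectors `phi`, `psi` in degrees (length 1 or one per residue).
#' @return A `molsys` with group `"peptide"`.
#' @examples
#' pep <- build_conformation("Ac-SSFPQPN-NH2")
#' n_atoms(pep)
#' @export
build_conformation <- function(seq, backbone = "extended") {
  if (is.character(seq)) seq <- parse_capped_sequence(seq)
  stopifnot(inherits(seq, "peptide_sequence"))
  nres <- length(seq$residues)
  if (is.character(backbone)) {
    if (!backbone %in% names(.backbone_presets))
      stop("unknown backbone preset: ", backbone, call. = FALSE)
    backbone <- .backbone_presets[[backbone]]
  }
  phi <- rep_len(backbone$phi, nres)
  psi <- rep_len(backbone$psi, nres)

  g <- .bb_geom
  atoms <- list(); coords <- list(); bonds_named <- list()
  unit_id <- 0L

  add_unit <- function(resname, tbl, pos, bonds) {
    unit_id <<- unit_id + 1L
    tbl$resid <- unit_id
    tbl$resname <- resname
    atoms[[unit_id]] <<- tbl
    coords[[unit_id]] <<- pos
    bonds_named[[unit_id]] <<- bonds
  }

  # references carried along the chain
  prevC <- prevCA <- prevN_or_CH3 <- prevO <- NULL

  if (seq$n_cap == "Ac") {
    ch3 <- c(0, 0, 0)
    cc <- c(1.520, 0, 0)
    th <- .deg(121)
    oo <- cc + 1.231 * c(-cos(th), sin(th), 0)
    add_unit("ACE", .cap_ace$atoms, rbind(ch3, cc, oo), .cap_ace$bonds)
    prevC <- cc; prevCA <- ch3; prevN_or_CH3 <- ch3; prevO <- oo
    prev_psi_refs <- list(a = oo, b = ch3, c = cc, phi = .deg(180))
  } else {
    prev_psi_refs <- NULL
  }

  for (i in seq_len(nres)) {
    tmpl <- .residue_table[[seq$residues[i]]]
    is_pro <- seq$residues[i] == "P"
    pos <- matrix(NA_real_, nrow(tmpl$atoms), 3)
    rownames(pos) <- tmpl$atoms$name

    if (is.null(prevC)) {
      # free N-terminus bootstrap in the xy plane
      pos["N", ] <- c(0, 0, 0)
      pos["CA", ] <- c(g$r_NCA, 0, 0)
      th <- .deg(g$a_NCAC)
      pos["C", ] <- pos["CA", ] + g$r_CAC * c(-cos(th), sin(th), 0)
    } else {
      pos["N", ] <- place_atom(prev_psi_refs$a, prev_psi_refs$b,
                               prev_psi_refs$c, g$r_CN,
                               .deg(g$a_CACN), prev_psi_refs$phi)
      pos["CA", ] <- place_atom(prevCA, prevC, pos["N", ], g$r_NCA,
                                .deg(g$a_CNCA), .deg(g$omega))
      pos["C", ] <- place_atom(prevC, pos["N", ], pos["CA", ], g$r_CAC,
                               .deg(g$a_NCAC), .deg(phi[i]))
    }
    pos["O", ] <- place_atom(pos["N", ], pos["CA", ], pos["C", ], g$r_CO,
                             .deg(g$a_CACO), .deg(psi[i] + 180))

    # CB: dihedral relative to the placed C keeps all residues L
    if ("CB" %in% tmpl$atoms$name) {
      aref <- if (!is.null(prevC)) prevC else pos["O", ]
      dref <- dihedral_angle(aref, pos["N", ], pos["CA", ], pos["C", ])
      th_cb <- .deg(if (is_pro) g$a_NCACB_pro else g$a_NCACB)
      pos["CB", ] <- place_atom(aref, pos["N", ], pos["CA", ], g$r_CACB,
                                th_cb, dref + .deg(g$d_CB))
    }

    if (is_pro) {
      pos <- .close_proline_ring(pos)
    } else {
      for (zr in tmpl$zmat) {
        pos[zr$atom, ] <- place_atom(pos[zr$a, ], pos[zr$b, ], pos[zr$c, ],
                                     zr$r, .deg(zr$theta), .deg(zr$phi))
      }
    }
    add_unit(tmpl$code3, tmpl$atoms, pos, tmpl$bonds)
    prev_psi_refs <- list(a = pos["N", ], b = pos["CA", ], c = pos["C", ],
                          phi = .deg(psi[i]))
    prevC <- pos["C", ]; prevCA <- pos["CA", ]; prevO <- pos["O", ]
  }

  if (seq$c_cap == "NH2") {
    ncap <- place_atom(prev_psi_refs$a, prev_psi_refs$b, prev_psi_refs$c,
                       g$r_CN, .deg(g$a_CACN), prev_psi_refs$phi)
    add_unit("NH2", .cap_nh2$atoms, matrix(ncap, 1, 3), .cap_nh2$bonds)
  }

  atom_tab <- do.call(rbind, atoms)
  atom_tab$group <- "peptide"
  atom_tab$fixed <- FALSE
  rownames(atom_tab) <- NULL
  xyz <- do.call(rbind, coords)
  rownames(xyz) <- NULL

  # name -> global index, then bond lists to indices (+ peptide bonds)
  gidx <- function(resid, name)
    which(atom_tab$resid == resid & atom_tab$name == name)
  bond_idx <- list()
  for (u in seq_len(unit_id)) {
    bn <- bonds_named[[u]]
    if (length(bn))
      for (b in seq_len(nrow(bn)))
        bond_idx[[length(bond_idx) + 1L]] <- c(gidx(u, bn[b, 1]),
                                               gidx(u, bn[b, 2]))
  }
  units <- unique(atom_tab$resid)
  for (u in units[-length(units)]) {
    ci <- gidx(u, "C")
    ni <- gidx(u + 1L, "N")
    bond_idx[[length(bond_idx) + 1L]] <- c(ci, ni)
  }
  bonds <- do.call(rbind, bond_idx)

  topo <- finalize_topology(atom_tab, xyz, bonds)
  sys <- molecular_system(atom_tab, xyz, topo)
  .check_clashes(sys)
  sys
}

# Close the proline ring: CG and CD are placed in the plane of N, CA, CB
# so that every ring bond takes its ideal length exactly.
#' @keywords internal
.close_proline_ring <- function(pos) {
  r_bg <- 1.495; r_gd <- 1.507; r_dn <- 1.473
  N <- pos["N", ]; CA <- pos["CA", ]; CB <- pos["CB", ]
  e1 <- .unit(CA - CB)
  nrm <- .unit(.cross3(CA - CB, N - CB))
  e2 <- .cross3(nrm, e1)
  # CG at 103.5 deg from CA about CB, in-plane, on the side of N
  th <- .deg(103.5)
  for (s in c(1, -1)) {
    cg <- CB + r_bg * (cos(th) * e1 + s * sin(th) * e2)
    if (sum((cg - N)^2) < sum((CB + r_bg * (cos(th) * e1 - s * sin(th) * e2) - N)^2))
      break
  }
  # CD: intersection of in-plane circles around CG (r_gd) and N (r_dn)
  to2d <- function(p) c(sum((p - CB) * e1), sum((p - CB) * e2))
  g2 <- to2d(cg); n2 <- to2d(N)
  d <- sqrt(sum((g2 - n2)^2))
  if (d > r_gd + r_dn || d < abs(r_gd - r_dn))
    stop("proline ring closure failed", call. = FALSE)
  a <- (r_gd^2 - r_dn^2 + d^2) / (2 * d)
  h <- sqrt(max(0, r_gd^2 - a^2))
  u <- (n2 - g2) / d
  perp <- c(-u[2], u[1])
  cand <- list(g2 + a * u + h * perp, g2 + a * u - h * perp)
  ca2 <- to2d(CA)
  pick <- if (sum((cand[[1]] - ca2)^2) >= sum((cand[[2]] - ca2)^2))
    cand[[1]] else cand[[2]]
  cd <- CB + pick[1] * e1 + pick[2] * e2
  pos["CG", ] <- cg
  pos["CD", ] <- cd
  pos
}

# Fail on nonbonded contacts closer than 1 A (1-2/1-3 pairs exempt).
#' @keywords internal
.check_clashes <- function(sys, tol = 1.0) {
  n <- n_atoms(sys)
  if (n < 2) return(invisible(TRUE))
  d <- as.matrix(stats::dist(sys$coords))
  excl <- sys$topology$excl
  if (nrow(excl)) d[cbind(excl[, 1], excl[, 2])] <-
      d[cbind(excl[, 2], excl[, 1])] <- Inf
  diag(d) <- Inf
  if (any(d < tol)) {
    w <- which(d < tol, arr.ind = TRUE)[1, ]
    stop(sprintf("steric clash after placement: atoms %d and %d at %.2f A",
                 w[1], w[2], d[w[1], w[2]]), call. = FALSE)
  }
  invisible(TRUE)
}
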