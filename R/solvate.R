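# Explicit solvation with a flexible 3-site water model (stiff internal
# harmonics; no constraint solver, which the 0.5 fs production step
# tolerates).

#' @keywords internal
.water_coords <- function(origin, theta_axis = NULL) {
  r0 <- .water_template$bond_r0
  a0 <- .water_template$angle_theta0
  h1 <- c(r0 * sin(a0 / 2), r0 * cos(a0 / 2), 0)
  h2 <- c(-r0 * sin(a0 / 2), r0 * cos(a0 / 2), 0)
  base <- rbind(c(0, 0, 0), h1, h2)
  if (!is.null(theta_axis)) {
    # random rigid rotation (axis-angle)
    ax <- .unit(theta_axis[1:3]); th <- theta_axis[4]
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    base <- base %*% t(R)
  }
  sweep(base, 2, origin, `+`)
}

#' @keywords internal
.water_system <- function(positions, rotations, first_resid = 1L) {
  nw <- nrow(positions)
  atoms <- list(); coords <- list()
  topo <- empty_topology()
  for (w in seq_len(nw)) {
    tbl <- .water_template$atoms
    tbl$resid <- first_resid + w - 1L
    tbl$resname <- "HOH"
    tbl$group <- "water"
    tbl$fixed <- FALSE
    atoms[[w]] <- tbl
    coords[[w]] <- .water_coords(positions[w, ], rotations[w, ])
    off <- (w - 1L) * 3L
    topo$bonds <- rbind(topo$bonds, off + rbind(c(1L, 2L), c(1L, 3L)))
    topo$angles <- rbind(topo$angles, off + matrix(c(2L, 1L, 3L), 1))
  }
  nb <- length(atoms) * 2L
  topo$bond_k <- rep(.water_template$bond_k, nb)
  topo$bond_r0 <- rep(.water_template$bond_r0, nb)
  topo$angle_k <- rep(.water_template$angle_k, nw)
  topo$angle_theta0 <- rep(.water_template$angle_theta0, nw)
  nbp <- nonbonded_pairs_from_topology(topo$bonds, topo$angles,
                                       topo$dihedrals)
  topo$excl <- nbp$excl
  topo$pairs14 <- nbp$pairs14
  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  molecular_system(at, do.call(rbind, coords), topo)
}

#' Solvate a system with 3-site water
#'
#' Fills the given box with water molecules on a jittered grid at the
#' requested count (or at liquid density, 0.997 g/cm^3), skipping
#' positions whose oxygen would come within 2.4 A of a solute heavy
#' atom, and gives each molecule a random orientation.
#'
#' @param system A `molsys` (may be empty: `NULL`).
#' @param count Number of waters; if `NULL`, derived from the box volume
#'   at liquid density.
#' @param box List with `origin` (length 3) and `lengths` (length 3), A.
#' @param min_dist Solute clearance for water oxygens (A, default 2.4).
#' @param seed RNG seed for orientations.
#' @return The merged system; attribute `"n_water_placed"` reports the
#'   achieved count.  If the requested count cannot be placed the
#'   function errors with the achievable number.
#' @export
solvate <- function(system, count = NULL, box, min_dist = 2.4, seed = 1) {
  stopifnot(is.list(box), length(box$origin) == 3, length(box$lengths) == 3)
  set.seed(seed)
  vol <- prod(box$lengths)
  n_target <- as.integer(if (is.null(count))
    round(WATER_NUMBER_DENSITY * vol) else count)
  # waters cannot pack closer than the clearance distance
  n_max <- prod(pmax(1, floor(box$lengths / min_dist)))
  if (n_target > n_max)
    stop(sprintf("box too small: requested %d waters, only %d positions fit",
                 n_target, n_max), call. = FALSE)
  if (n_target == 0) {
    if (is.null(system)) stop("nothing to do: empty system, zero waters",
                              call. = FALSE)
    attr(system, "n_water_placed") <- 0L
    return(system)
  }
  # grid fine enough to offer at least the target count
  ngrid <- ceiling(n_target^(1 / 3))
  repeat {
    sp <- box$lengths / ngrid
    gx <- box$origin[1] + (seq_len(ngrid) - 0.5) * sp[1]
    gy <- box$origin[2] + (seq_len(ngrid) - 0.5) * sp[2]
    gz <- box$origin[3] + (seq_len(ngrid) - 0.5) * sp[3]
    pts <- as.matrix(expand.grid(gx, gy, gz))
    colnames(pts) <- NULL
    if (!is.null(system) && n_atoms(system) > 0) {
      heavy <- system$coords[system$atoms$element != "H", , drop = FALSE]
      keep <- rep(TRUE, nrow(pts))
      for (d in seq_len(nrow(heavy))) {
        dd <- sqrt(rowSums(sweep(pts, 2, heavy[d, ])^2))
        keep <- keep & dd >= min_dist
      }
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) >= n_target || ngrid > 4 * ceiling(n_target^(1 / 3)))
      break
    ngrid <- ngrid + 1
  }
  if (nrow(pts) < n_target)
    stop(sprintf("box too small: requested %d waters, only %d positions fit",
                 n_target, nrow(pts)), call. = FALSE)
  pts <- pts[seq_len(n_target), , drop = FALSE]
  rot <- cbind(matrix(stats::rnorm(3 * n_target), ncol = 3),
               stats::runif(n_target, 0, 2 * pi))
  first_resid <- if (is.null(system)) 1L else
    max(system$atoms$resid, 0L) + 1L
  wat <- .water_system(pts, rot, first_resid)
  out <- if (is.null(system)) wat else merge_systems(system, wat)
  attr(out, "n_water_placed") <- n_target
  out
}

#' Remove all water molecules from a system
#'
#' Inverse of [solvate()]: drops every atom in group `"water"`.
#' @param system A `molsys`.
#' @export
delete_waters <- function(system) {
  subset_system(system, system$atoms$group != "water")
}
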