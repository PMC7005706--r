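# Named toy systems with documented oracle values; every other module's
# tests (and the worked examples) are built from these, so no external
# data is needed.

.lj_cluster_minima <- c(lj3 = -3, lj4 = -6, lj5 = -9.103852,
                        lj6 = -12.712062, lj7 = -16.505384) # units of eps

#' Built-in toy fixtures
#'
#' @param name One of:
#'   \describe{
#'     \item{`lj3` .. `lj7`}{Lennard-Jones clusters (eps = 1 kcal/mol,
#'       sigma = 3 A, unbonded); oracle: the known global minima -3,
#'       -6, -9.103852, -12.712062, -16.505384 eps.}
#'     \item{`double_well`}{1-D quartic `(x^2-1)^2 + 0.2 x` wrapped as a
#'       STUN-BH objective; two minima near x = -1 (global) and x = +1.}
#'     \item{`harmonic_dimer`}{Two bonded atoms (k = 100 kcal/mol/A^2,
#'       r0 = 1.5 A, m = 12); oracle vibration period
#'       `2*pi*sqrt(mu/(2k))` (the bond energy is `k (r-r0)^2`).}
#'     \item{`tripeptide_on_slab`}{Ac-SFP-NH2 placed 3.5 A above a
#'       7 x 7 x 3 Au(111) slab (175 atoms).}
#'     \item{`benzene_flat_on_au`}{Six-membered aromatic ring lying flat
#'       3.5 A over a top-layer Au atom with its carbons over the
#'       second/third-layer sites: a LAK-positive probe.}
#'     \item{`benzene_standup_on_au`}{The same ring rotated 90 degrees:
#'       a stand-up probe.}
#'   }
#' @param seed Seed for the stochastic fixtures (cluster coordinates).
#' @return List with `system` (or `objective`), `oracle`, `description`.
#' @export
make_fixture <- function(name, seed = 1) {
  fixtures <- c(names(.lj_cluster_minima), "double_well", "harmonic_dimer",
                "tripeptide_on_slab", "benzene_flat_on_au",
                "benzene_standup_on_au")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  set.seed(seed)
  if (name %in% names(.lj_cluster_minima)) {
    n <- as.integer(substr(name, 3, 3))
    sys <- .lj_cluster(n)
    return(list(system = sys, oracle = .lj_cluster_minima[[name]],
                description = sprintf(
                  "LJ%d cluster; global minimum %g eps (eps = 1 kcal/mol)",
                  n, .lj_cluster_minima[[name]])))
  }
  switch(name,
    double_well = {
      fn <- function(x) (x^2 - 1)^2 + 0.2 * x
      grid <- seq(-2, 2, by = 1e-4)
      gmin <- grid[which.min(fn(grid))]
      objective <- list(
        minimize = function(state) {
          o <- stats::optim(state, fn, method = "BFGS")
          list(state = o$par, energy = o$value)
        },
        perturb = function(state, seed) {
          set.seed(seed)
          state + stats::rnorm(1, sd = 0.8)
        })
      list(objective = objective, fn = fn,
           oracle = list(global_x = gmin, global_f = fn(gmin)),
           description = "1-D double well (x^2-1)^2 + 0.2 x; global minimum near x = -1")
    },
    harmonic_dimer = {
      atoms <- data.frame(name = c("X1", "X2"), element = "C",
                          resid = 1L, resname = "UNK", type = "LJ",
                          charge = 0, mass = 12, group = "other",
                          fixed = FALSE, stringsAsFactors = FALSE)
      topo <- empty_topology()
      topo$bonds <- matrix(c(1L, 2L), 1)
      topo$bond_k <- 100; topo$bond_r0 <- 1.5
      nb <- nonbonded_pairs_from_topology(topo$bonds, topo$angles,
                                          topo$dihedrals)
      topo$excl <- nb$excl; topo$pairs14 <- nb$pairs14
      sys <- molecular_system(atoms, rbind(c(0, 0, 0), c(1.5, 0, 0)), topo)
      mu <- 6
      period_fs <- 2 * pi * sqrt(mu / (2 * 100)) * TIME_UNIT_FS
      list(system = sys, oracle = list(period_fs = period_fs),
           description = "harmonic dimer, k = 100 kcal/mol/A^2, r0 = 1.5 A")
    },
    tripeptide_on_slab = {
      pep <- build_conformation("Ac-SFP-NH2")
      slab <- build_fcc_slab("Au", 4.08, n_layers = 3, repeats = c(7, 7))
      xyz <- pep$coords
      ctr <- 0.5 * (slab$cell[, 1] + slab$cell[, 2])
      xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + ctr[1]
      xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + ctr[2]
      xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + 3.5
      pep$coords <- xyz
      list(system = merge_systems(pep, slab), oracle = NULL,
           description = "Ac-SFP-NH2 3.5 A above Au(111), 7x7x3 slab")
    },
    benzene_flat_on_au = .benzene_probe(flat = TRUE),
    benzene_standup_on_au = .benzene_probe(flat = FALSE)
  )
}

#' @keywords internal
.lj_cluster <- function(n) {
  atoms <- data.frame(name = paste0("X", seq_len(n)), element = "Ar",
                      resid = 1L, resname = "UNK", type = "LJ",
                      charge = 0, mass = 12, group = "other",
                      fixed = FALSE, stringsAsFactors = FALSE)
  # random compact cluster: every atom stays inside the attractive range
  # of its neighbours (no contact below 0.8 sigma, no atom beyond
  # 2 sigma of the rest), so the start is a bound cluster, not a gas
  sigma <- 3
  repeat {
    xyz <- matrix(stats::rnorm(3 * n, sd = 0.5 * sigma), ncol = 3)
    if (n < 2) break
    d <- stats::dist(xyz)
    if (min(d) > 0.8 * sigma && max(d) < 2 * sigma) break
  }
  molecular_system(atoms, xyz)
}

#' @keywords internal
.benzene_probe <- function(flat = TRUE) {
  slab <- build_fcc_slab("Au", 4.08, n_layers = 3, repeats = c(6, 6))
  meta <- slab$slab
  # a top-layer atom near the cell center
  top_idx <- which(meta$layer == 1)
  ctr <- 0.5 * (slab$cell[, 1] + slab$cell[, 2])
  d2 <- rowSums(sweep(slab$coords[top_idx, 1:2, drop = FALSE], 2, ctr)^2)
  anchor <- slab$coords[top_idx[which.min(d2)], ]
  # ring vertices at the hcp/fcc azimuths (30 deg + k*60)
  az <- (30 + 60 * (0:5)) * pi / 180
  ring <- cbind(anchor[1] + 1.39 * cos(az), anchor[2] + 1.39 * sin(az),
                rep(anchor[3] + 3.5, 6))
  if (!flat) {
    cen <- colMeans(ring)
    rel <- sweep(ring, 2, cen)
    rot <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
    ring <- sweep(rel %*% t(rot), 2, cen, `+`)
    ring[, 3] <- ring[, 3] - min(ring[, 3]) + anchor[3] + 2.8
  }
  names6 <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  atoms <- data.frame(name = names6, element = "C", resid = 1L,
                      resname = "PHE", type = "CAro", charge = 0,
                      mass = 13.019, group = "peptide", fixed = FALSE,
                      stringsAsFactors = FALSE)
  # ring order for bonds is the cycle CG-CD1-CE1-CZ-CE2-CD2
  bonds <- cbind(1:6, c(2:6, 1))
  ring_sys <- molecular_system(atoms, ring,
                               finalize_topology(atoms, ring, bonds))
  list(system = merge_systems(ring_sys, slab),
       oracle = list(lak = flat,
                     orientation = if (flat) "flat-on" else "stand-up"),
       description = if (flat)
         "aromatic six-ring flat over a top Au atom (LAK positive)"
       else "aromatic six-ring standing upright on Au(111)")
}
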