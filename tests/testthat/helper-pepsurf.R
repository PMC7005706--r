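# Shared helpers: finite-difference force checks and small bespoke
# systems used across the suite.

fd_force_mismatch <- function(sys, params = default_forcefield(),
                              h = 1e-6, atoms = seq_len(n_atoms(sys))) {
  f <- forces(sys, params)
  worst <- 0
  for (i in atoms) {
    if (sys$atoms$fixed[i]) next
    for (k in 1:3) {
      p1 <- sys; p1$coords[i, k] <- p1$coords[i, k] + h
      p2 <- sys; p2$coords[i, k] <- p2$coords[i, k] - h
      num <- -(total_energy(p1, params)$total -
                 total_energy(p2, params)$total) / (2 * h)
      worst <- max(worst, abs(num - f[i, k]) / max(1, abs(num)))
    }
  }
  worst
}

# n free LJ sites (eps = 1 kcal/mol, sigma = 3 A), optionally charged
toy_lj_system <- function(coords, charge = 0, group = "other") {
  n <- nrow(coords)
  atoms <- data.frame(name = paste0("X", seq_len(n)), element = "Ar",
                      resid = seq_len(n), resname = "UNK", type = "LJ",
                      charge = charge, mass = 12, group = group,
                      fixed = FALSE, stringsAsFactors = FALSE)
  molecular_system(atoms, coords)
}

# independent oracle: plain R sum over LJ pairs (no cutoff)
lj_cluster_energy_oracle <- function(coords, eps = 1, sigma = 3) {
  e <- 0
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e <- e + 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  }
  e
}

lj_min_dist <- function(sigma = 3) 2^(1 / 6) * sigma

equilateral_lj3 <- function(sigma = 3) {
  r <- lj_min_dist(sigma)
  rbind(c(0, 0, 0), c(r, 0, 0), c(r / 2, r * sqrt(3) / 2, 0))
}

tetrahedron_lj4 <- function(sigma = 3) {
  r <- lj_min_dist(sigma)
  rbind(c(0, 0, 0), c(r, 0, 0), c(r / 2, r * sqrt(3) / 2, 0),
        c(r / 2, r * sqrt(3) / 6, r * sqrt(2 / 3)))
}
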