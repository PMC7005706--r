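# Molecular-mechanics energies, forces and the binding-energy
# decomposition.

test_that("two LJ sites at the well minimum give exactly -eps", {
  r <- lj_min_dist()
  sys <- toy_lj_system(rbind(c(0, 0, 0), c(r, 0, 0)))
  e <- total_energy(sys)
  expect_equal(e$e_lj, -1, tolerance = 1e-12)
  expect_equal(e$total, -1, tolerance = 1e-12)
})

test_that("pairs beyond the cutoff contribute nothing", {
  sys <- toy_lj_system(rbind(c(0, 0, 0), c(13, 0, 0)), charge = c(0.5, -0.5))
  e <- total_energy(sys)
  expect_identical(e$e_lj, 0)
  expect_identical(e$e_coul, 0)
})

test_that("LJ4 tetrahedron reaches -6 eps, agreeing with an R oracle", {
  # independent oracle: minimize the plain R pair sum
  o <- stats::optim(as.vector(tetrahedron_lj4() +
                                matrix(stats::rnorm(12, sd = 0.05), 4, 3)),
                    function(x) lj_cluster_energy_oracle(matrix(x, 4, 3)),
                    method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(o$value, -6, tolerance = 1e-6)
  # package path: kernel energy at the oracle's geometry
  sys <- toy_lj_system(matrix(o$par, 4, 3))
  expect_equal(total_energy(sys)$total, -6, tolerance = 1e-6)
})

test_that("missing LJ parameters raise an error naming the type", {
  sys <- toy_lj_system(rbind(c(0, 0, 0), c(4, 0, 0)))
  sys$atoms$type <- "ZZ"
  expect_error(total_energy(sys), "ZZ")
})

test_that("analytic forces match central-difference gradients", {
  set.seed(42)
  # random charged LJ gas
  sys <- toy_lj_system(matrix(stats::rnorm(30, sd = 3), 10, 3),
                       charge = round(stats::runif(10, -0.4, 0.4), 2))
  sys$atoms$charge <- sys$atoms$charge - mean(sys$atoms$charge)
  expect_lt(fd_force_mismatch(sys), 1e-4)
  # bonded peptide with every term type active
  pep <- build_conformation("Ac-SFP-NH2")
  pep$coords <- pep$coords + matrix(stats::rnorm(3 * n_atoms(pep), sd = 0.05),
                                    ncol = 3)
  expect_lt(fd_force_mismatch(pep, atoms = sample(n_atoms(pep), 8)), 1e-4)
})

test_that("forces obey Newton's third law and vanish at a minimum", {
  r <- lj_min_dist()
  dimer <- toy_lj_system(rbind(c(0, 0, 0), c(r + 0.3, 0, 0)))
  f <- forces(dimer)
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-12)
  at_min <- toy_lj_system(rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_lt(max(abs(forces(at_min))), 1e-10)
})

test_that("binding-energy arithmetic and separation limit hold", {
  expect_identical(eq_binding(-10, -3, -2), -5)

  fx <- make_fixture("tripeptide_on_slab")
  be <- binding_energy(fx$system)
  expect_lt(be$e_be, 0) # adsorbed start is attractive
  # lifting the peptide 20 A beyond the cutoff zeroes the binding energy
  sys <- fx$system
  pm <- sys$atoms$group == "peptide"
  sys$coords[pm, 3] <- sys$coords[pm, 3] + 20 + 12
  expect_identical(binding_energy(sys)$e_be, 0)
  # fragment mismatch is an error
  pepfrag <- subset_system(fx$system, which(pm)[-1])
  subfrag <- subset_system(fx$system, !pm)
  expect_error(binding_energy(fx$system, pepfrag, subfrag), "mismatch")
})

test_that("a single adsorbed LJ pair gives E_BE = -eps at the well minimum", {
  r <- lj_min_dist()
  sys <- toy_lj_system(rbind(c(0, 0, 0), c(0, 0, r)))
  sys$atoms$group <- c("surface", "peptide")
  sys$atoms$resid <- c(1L, 2L)
  expect_equal(binding_energy(sys)$e_be, -1, tolerance = 1e-12)
})

test_that("per-residue profile conserves the surface-interaction total", {
  fx <- make_fixture("tripeptide_on_slab")
  e <- total_energy(fx$system)
  prof <- per_residue_binding(fx$system)
  expect_identical(nrow(prof), 5L) # ACE + 3 residues + NH2, N to C
  expect_identical(prof$resname, c("ACE", "SER", "PHE", "PRO", "NH2"))
  expect_equal(sum(prof$e_bind), e$e_surface,
               tolerance = 1e-8)

  # single residue holds the whole interaction
  r <- lj_min_dist()
  sys <- toy_lj_system(rbind(c(0, 0, 0), c(0, 0, r)))
  sys$atoms$group <- c("surface", "peptide")
  p1 <- per_residue_binding(sys)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$e_bind, total_energy(sys)$e_surface, tolerance = 1e-12)

  # two residues, only the second in contact
  sys2 <- toy_lj_system(rbind(c(0, 0, 0), c(0, 0, 30), c(0, 0, r)))
  sys2$atoms$group <- c("surface", "peptide", "peptide")
  sys2$atoms$resid <- c(1L, 2L, 3L)
  p2 <- per_residue_binding(sys2)
  expect_equal(p2$e_bind, c(0, -1), tolerance = 1e-12)

  # far peptide: all-zero profile
  fx2 <- fx$system
  pm <- fx2$atoms$group == "peptide"
  fx2$coords[pm, 3] <- fx2$coords[pm, 3] + 40
  expect_true(all(per_residue_binding(fx2)$e_bind == 0))
})

test_that("energy is invariant under rigid motion of an open system", {
  pep <- build_conformation("Ac-SFPQ-NH2")
  e0 <- total_energy(pep)$total
  th <- 0.93
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  pep2 <- pep
  pep2$coords <- pep$coords %*% t(R)
  pep2$coords <- sweep(pep2$coords, 2, c(7, -4, 11), `+`)
  expect_equal(total_energy(pep2)$total, e0, tolerance = 1e-8)
})

test_that("switching takes the pair energy smoothly and monotonically to zero", {
  q <- 0.3
  energies <- vapply(seq(9.5, 12.1, by = 0.01), function(r) {
    sys <- toy_lj_system(rbind(c(0, 0, 0), c(r, 0, 0)), charge = c(q, q))
    total_energy(sys)$total
  }, numeric(1))
  # repulsive pair: switched energy decreases monotonically to exactly 0
  expect_true(all(diff(energies) <= 1e-12))
  expect_identical(energies[length(energies)], 0)
  # continuity: no jump beyond the scan resolution anywhere in the window
  expect_lt(max(abs(diff(energies))), 0.05)
})

test_that("breakdown components sum to the reported total", {
  fx <- make_fixture("tripeptide_on_slab")
  e <- total_energy(fx$system)
  expect_equal(e$e_bond + e$e_angle + e$e_dihedral + e$e_lj + e$e_coul +
                 e$e_restraint, e$total, tolerance = 1e-8)
})
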