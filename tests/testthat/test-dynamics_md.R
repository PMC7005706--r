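# Integrators, thermostats, restraints and solvation.

test_that("harmonic dimer vibrates at the closed-form period", {
  fx <- make_fixture("harmonic_dimer")
  s <- fx$system
  s$coords[2, 1] <- 1.7
  tr <- nve_run(s, md_config(timestep_fs = 0.5, n_steps = 400, stride = 1,
                             velocities = matrix(0, 2, 3), seed = 1))
  x <- vapply(tr$frames, function(f) f[2, 1] - f[1, 1], numeric(1))
  crossings <- which(diff(sign(x - 1.5)) != 0)
  period <- 2 * mean(diff(crossings)) * 0.5
  expect_equal(period, fx$oracle$period_fs, tolerance = 0.01)
})

test_that("a 0 K start at a minimum stays put", {
  fx <- make_fixture("harmonic_dimer")
  tr <- nve_run(fx$system, md_config(n_steps = 100, stride = 10,
                                     velocities = matrix(0, 2, 3), seed = 1))
  expect_equal(tr$final_system$coords, fx$system$coords, tolerance = 1e-12)
})

test_that("NVE conserves energy: secular drift < 1e-4 relative per ps", {
  fx <- make_fixture("tripeptide_on_slab")
  m <- suppressWarnings(local_minimize(fx$system, tol = 1e-3,
                                       max_iter = 800))
  tr <- nve_run(m$system, md_config(timestep_fs = 0.5, n_steps = 4000,
                                    temperature = 300, stride = 40,
                                    seed = 4))
  fit <- stats::lm(e_total ~ time_fs, data = tr$energies)
  drift_per_ps <- abs(stats::coef(fit)[2]) * 1000 /
    abs(mean(tr$energies$e_total))
  expect_lt(drift_per_ps, 1e-4)
})

test_that("halving the timestep shrinks energy fluctuation ~4x (2nd order)", {
  fx <- make_fixture("tripeptide_on_slab")
  m <- suppressWarnings(local_minimize(fx$system, tol = 1e-3,
                                       max_iter = 800))
  fluct <- vapply(c(1, 0.5), function(dt) {
    tr <- nve_run(m$system, md_config(timestep_fs = dt,
                                      n_steps = round(400 / dt),
                                      temperature = 300,
                                      stride = round(20 / dt), seed = 4))
    stats::sd(tr$energies$e_total)
  }, numeric(1))
  expect_gt(fluct[1] / fluct[2], 3)
})

test_that("velocity Verlet is time-reversible", {
  fx <- make_fixture("tripeptide_on_slab")
  cfg <- md_config(timestep_fs = 0.5, n_steps = 200, temperature = 300,
                   stride = 200, seed = 5)
  fwd <- nve_run(fx$system, cfg)
  back_cfg <- cfg
  back_cfg$velocities <- -fwd$final_velocities
  back <- nve_run(fwd$final_system, back_cfg)
  expect_lt(max(abs(back$final_system$coords - fx$system$coords)), 1e-6)
})

test_that("identical seeds give bitwise-identical trajectories", {
  fx <- make_fixture("tripeptide_on_slab")
  cfg <- md_config(n_steps = 100, stride = 10, seed = 77, temperature = 300)
  t1 <- nvt_run(fx$system, cfg)
  t2 <- nvt_run(fx$system, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  # frame-count contract
  expect_length(t1$frames, floor(100 / 10) + 1)
})

test_that("Nose-Hoover holds the mean temperature within 3% of setpoint", {
  pep <- build_conformation("Ac-SFP-NH2")
  pep$coords <- sweep(pep$coords, 2, colMeans(pep$coords))
  pep$coords[, 3] <- pep$coords[, 3] - min(pep$coords[, 3]) + 3
  sol <- solvate(pep, count = 45,
                 box = list(origin = c(-6, -6, 2), lengths = c(14, 14, 10)),
                 seed = 5)
  expect_gt(sum(!sol$atoms$fixed), 100)
  tr <- nvt_run(sol, md_config(timestep_fs = 0.5, n_steps = 4000,
                               temperature = 300, tau_fs = 25,
                               seed = 11, stride = 20))
  prod <- tr$energies$temperature[tr$energies$step > 2000]
  expect_gt(mean(prod), 291)
  expect_lt(mean(prod), 309)
})

test_that("the thermostat injects no net momentum into a free cluster", {
  fx <- make_fixture("lj5", seed = 2)
  m <- local_minimize(fx$system, tol = 1e-6)
  tr <- nvt_run(m$system, md_config(timestep_fs = 1, n_steps = 1000,
                                    temperature = 100, seed = 3,
                                    stride = 100))
  p <- colSums(tr$final_velocities * m$system$atoms$mass)
  expect_lt(sqrt(sum(p^2)), 1e-10)
})

test_that("non-finite forces abort with the failing step", {
  fx <- make_fixture("harmonic_dimer")
  s <- fx$system
  s$coords[2, ] <- s$coords[1, ] # coincident atoms: r = 0
  expect_error(nve_run(s, md_config(n_steps = 5,
                                    velocities = matrix(0, 2, 3))),
               "step")
})

test_that("restrained relaxation bounds drift and k = 0 is unrestrained NVT", {
  fx <- make_fixture("tripeptide_on_slab")
  stiff <- restrained_relax(fx$system, k = 1000, duration_fs = 100,
                            config = md_config(seed = 6, stride = 50,
                                               temperature = 300))
  loose <- restrained_relax(fx$system, k = 10, duration_fs = 100,
                            config = md_config(seed = 6, stride = 50,
                                               temperature = 300))
  expect_lt(stiff$rmsd, loose$rmsd)
  expect_lt(stiff$rmsd, 0.1)

  free <- restrained_relax(fx$system, k = 0, duration_fs = 100,
                           config = md_config(seed = 6, stride = 50,
                                              temperature = 300))
  plain <- nvt_run(fx$system, md_config(seed = 6, stride = 50,
                                        temperature = 300,
                                        n_steps = 200))
  expect_identical(free$system$coords, plain$final_system$coords)

  # restraint energy is reported while active
  expect_gt(max(stiff$trajectory$energies$e_pot) -
              min(stiff$trajectory$energies$e_pot), 0)
})

test_that("a restrained atom equilibrates to the equipartition MSD", {
  atoms <- data.frame(name = "X", element = "C", resid = 1L,
                      resname = "UNK", type = "HW", charge = 0, mass = 12,
                      group = "peptide", fixed = FALSE,
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, matrix(0, 1, 3))
  k <- 5
  tr <- run_md(sys, md_config(timestep_fs = 1, n_steps = 60000,
                              temperature = 300, thermostat = "langevin",
                              gamma_ps = 20, seed = 8, stride = 20,
                              restraints = list(idx = 1L,
                                                anchors = matrix(0, 1, 3),
                                                k = k)))
  msd <- mean(vapply(tr$frames[-seq_len(500)],
                     function(f) sum(f^2), numeric(1)))
  theory <- 3 * 0.0019872041 * 300 / (2 * k)
  expect_equal(msd, theory, tolerance = 0.10)
})

test_that("solvation hits liquid density, is reversible and validates the box", {
  w <- solvate(NULL, box = list(origin = c(0, 0, 0),
                                lengths = c(30, 30, 30)), seed = 3)
  nw <- attr(w, "n_water_placed")
  expect_gt(nw, 900 * 0.98)
  expect_lt(nw, 900 * 1.02)
  expect_identical(n_atoms(w), nw * 3L)
  # no oxygen-solute contact below 2.4 A
  pep <- build_conformation("Ac-SF-NH2")
  sol <- solvate(pep, count = 30,
                 box = list(origin = c(-8, -8, -8), lengths = c(16, 16, 16)),
                 seed = 9)
  ow <- sol$coords[sol$atoms$name == "OW", , drop = FALSE]
  dmin <- min(apply(ow, 1, function(o)
    min(sqrt(rowSums(sweep(pep$coords, 2, o)^2)))))
  expect_gte(dmin, 2.4)
  # count = 0 leaves the system unchanged
  same <- solvate(pep, count = 0, box = list(origin = c(0, 0, 0),
                                             lengths = c(10, 10, 10)))
  expect_identical(same$coords, pep$coords)
  # solvate then delete restores the original
  back <- delete_waters(sol)
  expect_identical(back$coords, pep$coords)
  expect_identical(back$atoms$name, pep$atoms$name)
  # impossible request errors with the achievable count
  expect_error(solvate(pep, count = 500,
                       box = list(origin = c(-3, -3, -3),
                                  lengths = c(6, 6, 6))),
               "only")
})
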