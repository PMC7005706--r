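# Stochastic-tunneling basin hopping: transform, minimization,
# perturbation moves, iteration loop and the multistart driver.

test_that("the tunneling transform has its closed-form properties", {
  expect_identical(stun_transform(5, 5, 2), 0)
  expect_equal(stun_transform(log(2), 0, 1), 0.5, tolerance = 1e-12)
  # strict monotonicity for any gamma, boundedness above the reference
  set.seed(1)
  for (rep in 1:50) {
    e <- sort(stats::rnorm(2, sd = 20))
    # gamma within the calibrated operating range (the transform
    # saturates to 1 in double precision once gamma * dE exceeds ~37)
    g <- stats::runif(1, 0.01, 20 / (abs(e[2] + 30) + 1))
    expect_lt(stun_transform(e[1], -30, g), stun_transform(e[2], -30, g))
  }
  # bounded above by 1 (attained only in the double-precision limit)
  expect_lte(stun_transform(1e6, 0, 1), 1)
  expect_lt(stun_transform(30, 0, 1), 1)
})

test_that("local minimization solves the bundled analytic cases", {
  # already at a minimum: unchanged
  r <- lj_min_dist()
  at_min <- toy_lj_system(rbind(c(0, 0, 0), c(r, 0, 0)))
  res <- local_minimize(at_min, tol = 1e-6)
  expect_equal(res$system$coords, at_min$coords, tolerance = 1e-6)
  expect_true(res$converged)

  # LJ trimer from a perturbed equilateral start reaches -3 eps
  set.seed(1)
  s <- toy_lj_system(equilateral_lj3() + matrix(stats::rnorm(9, sd = 0.2), 3, 3))
  expect_equal(local_minimize(s, tol = 1e-6)$e_total, -3, tolerance = 1e-8)

  # energy never increases
  fx <- make_fixture("tripeptide_on_slab")
  e0 <- total_energy(fx$system)$total
  res2 <- suppressWarnings(local_minimize(fx$system, tol = 1e-2,
                                          max_iter = 200))
  expect_lte(res2$e_total, e0)
})

test_that("a 2-D quadratic bowl minimizes to its analytic optimum", {
  bowl <- list(
    minimize = function(state) {
      o <- stats::optim(state, function(x)
        2 * (x[1] - 1.5)^2 + 3 * (x[2] + 0.5)^2 + 7, method = "BFGS",
        control = list(reltol = 1e-14))
      list(state = o$par, energy = o$value)
    },
    perturb = function(state, seed) { set.seed(seed); state + stats::rnorm(2) }
  )
  res <- stunbh_core(bowl, c(5, 5), stunbh_config(n_starts = 1,
                                                  iterations = 3, seed = 1))
  expect_equal(res$best_state, c(1.5, -0.5), tolerance = 1e-8)
  expect_equal(res$best_energy, 7, tolerance = 1e-10)
})

test_that("perturbation moves are seeded MD kicks that leave the slab alone", {
  fx <- make_fixture("tripeptide_on_slab")
  expect_identical(perturb_move(fx$system, list(n_steps = 0), seed = 1)$coords,
                   fx$system$coords)
  a <- perturb_move(fx$system, list(n_steps = 300, timestep_fs = 2), seed = 4)
  b <- perturb_move(fx$system, list(n_steps = 300, timestep_fs = 2), seed = 4)
  expect_identical(a$coords, b$coords)
  pm <- fx$system$atoms$group == "peptide"
  rmsd <- sqrt(mean(rowSums((a$coords[pm, ] - fx$system$coords[pm, ])^2)))
  expect_gt(rmsd, 0.1) # thermal displacement at 500 K
  expect_identical(a$coords[!pm, ], fx$system$coords[!pm, ])
})

test_that("one iteration degenerates to a single local minimization", {
  set.seed(3)
  s <- toy_lj_system(equilateral_lj3() + matrix(stats::rnorm(9, sd = 0.15), 3, 3))
  direct <- local_minimize(s, tol = 1e-3, max_iter = 500)
  one <- stunbh_iterate(s, stunbh_config(n_starts = 1, iterations = 1,
                                         seed = 9))
  expect_equal(one$best_energy, direct$e_total, tolerance = 1e-6)
})

test_that("the best-so-far trace is monotonically non-increasing", {
  fx <- make_fixture("double_well")
  res <- stunbh_core(fx$objective, 1.2,
                     stunbh_config(n_starts = 1, iterations = 30, seed = 2,
                                   beta = 3))
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("lower transformed energy is always accepted (Metropolis limit)", {
  # engineered objective: each perturbation lowers the energy, so every
  # move must be accepted
  obj <- list(
    minimize = function(state) list(state = state, energy = state),
    perturb = function(state, seed) state - 1
  )
  res <- stunbh_core(obj, 10, stunbh_config(n_starts = 1, iterations = 20,
                                            gamma = 0.5, seed = 1))
  expect_equal(res$accept_rate, 1)
  expect_equal(res$best_energy, 10 - 19)
})

test_that("STUN-BH finds the deeper well of the 1-D double well", {
  fx <- make_fixture("double_well")
  hits <- 0L
  for (s in 1:50) {
    res <- stunbh_core(fx$objective, 1.0,
                       stunbh_config(n_starts = 1, iterations = 25,
                                     seed = s, beta = 3))
    if (abs(res$best_state - fx$oracle$global_x) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 48) # >= 95% of 50 seeded runs
})

test_that("search bookkeeping schedules n_starts x iterations", {
  cfg <- stunbh_config(n_starts = 1000, iterations = 200)
  expect_identical(planned_iterations(cfg), 200000)
  expect_error(stunbh_config(n_starts = 0), "n_starts")
})

test_that("ranking by raw energy equals ranking by transformed energy", {
  set.seed(7)
  for (rep in 1:20) {
    e <- stats::rnorm(6, sd = 30)
    g <- stats::runif(1, 0.01, 20 / diff(range(e)))
    expect_identical(order(e), order(stun_transform(e, min(e), g)))
  }
})

test_that("multistart on LJ clusters matches the known global minima", {
  for (nm in c("lj3", "lj4")) {
    fx <- make_fixture(nm, seed = 7)
    res <- multistart_search(fx$system, NULL,
                             stunbh_config(n_starts = 10, iterations = 6,
                                           seed = 42,
                                           perturb_md = list(n_steps = 100,
                                                             temperature = 400)))
    expect_equal(res$minima[[1]]$e_be, fx$oracle, tolerance = 1e-4)
    expect_equal(res$completed_iterations, 60)
    # ranked ascending; best overall <= every per-start best
    e <- vapply(res$minima, `[[`, numeric(1), "e_be")
    expect_true(all(diff(e) >= 0))
    expect_true(all(res$best_per_start$e_be >= e[1] - 1e-9))
  }
})

test_that("a search is exactly reproducible from (config, master seed)", {
  fx <- make_fixture("lj3", seed = 5)
  cfg <- stunbh_config(n_starts = 3, iterations = 4, seed = 11,
                       perturb_md = list(n_steps = 50, temperature = 300))
  r1 <- multistart_search(fx$system, NULL, cfg)
  r2 <- multistart_search(fx$system, NULL, cfg)
  expect_identical(r1$best_per_start, r2$best_per_start)
  expect_identical(r1$minima[[1]]$system$coords, r2$minima[[1]]$system$coords)
})

test_that("more work never worsens the best energy found", {
  fx <- make_fixture("lj4", seed = 3)
  short <- multistart_search(fx$system, NULL,
                             stunbh_config(n_starts = 2, iterations = 3,
                                           seed = 5,
                                           perturb_md = list(n_steps = 60)))
  long <- multistart_search(fx$system, NULL,
                            stunbh_config(n_starts = 6, iterations = 3,
                                          seed = 5,
                                          perturb_md = list(n_steps = 60)))
  expect_lte(long$minima[[1]]$e_be, short$minima[[1]]$e_be + 1e-9)
})

test_that("a peptide placed above the slab searches toward adsorption", {
  fx <- make_fixture("tripeptide_on_slab")
  pep <- subset_system(fx$system, fx$system$atoms$group == "peptide")
  slab <- subset_system(fx$system, fx$system$atoms$group == "surface")
  slab$slab <- fx$system$slab
  set.seed(2)
  cfg <- stunbh_config(n_starts = 1, iterations = 2, seed = 8,
                       cg_tol = 1e-2, cg_max_iter = 150,
                       perturb_md = list(n_steps = 50))
  start <- place_peptide(pep, slab, cfg)
  expect_identical(n_atoms(start), n_atoms(fx$system))
  res <- suppressWarnings(stunbh_iterate(start, cfg))
  expect_lt(res$best_energy, 0) # bound state found
})
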