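# Ring orientation, lock-and-key registry, environment comparison and
# mobility.

make_ring <- function(center = c(0, 0, 3.5), radius = 1.39, tilt_deg = 0,
                      n = 6, az0 = 0) {
  az <- az0 + 2 * pi * (0:(n - 1)) / n
  ring <- cbind(radius * cos(az), radius * sin(az), 0)
  th <- tilt_deg * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                3, 3, byrow = TRUE)
  sweep(ring %*% t(rot), 2, center, `+`)
}

test_that("constructed rings classify flat-on, stand-up and detached", {
  flat <- ring_orientation(make_ring(tilt_deg = 0), top_z = 0)
  expect_identical(flat$class, "flat-on")
  expect_equal(flat$tilt, 0, tolerance = 1e-8)
  expect_equal(flat$height, 3.5, tolerance = 1e-12)

  up <- ring_orientation(make_ring(center = c(0, 0, 3.0), tilt_deg = 90),
                         top_z = 0)
  expect_identical(up$class, "stand-up")
  expect_equal(up$tilt, 90, tolerance = 1e-8)

  far <- ring_orientation(make_ring(center = c(0, 0, 15)), top_z = 0)
  expect_identical(far$class, "detached")

  mid <- ring_orientation(make_ring(center = c(0, 0, 3.5), tilt_deg = 40),
                          top_z = 0)
  expect_identical(mid$class, "intermediate")

  expect_error(ring_orientation(make_ring(n = 4)), "5 or 6")
  expect_warning(
    bad <- ring_orientation(rbind(make_ring(n = 5)[1:4, ], c(0, 0, 5.5))),
    "planarity")
  expect_identical(bad$class, "intermediate")
})

test_that("every ring receives exactly one orientation class", {
  set.seed(10)
  classes <- replicate(40, {
    ring <- make_ring(center = c(stats::rnorm(2), stats::runif(1, 2, 16)),
                      tilt_deg = stats::runif(1, 0, 90))
    ring_orientation(ring, top_z = 0)$class
  })
  expect_true(all(classes %in% c("flat-on", "stand-up", "intermediate",
                                 "detached")))
})

test_that("the flat benzene probe is LAK-locked over a top atom", {
  fx <- make_fixture("benzene_flat_on_au")
  rep <- detect_lak(fx$system)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$orientation, "flat-on")
  expect_identical(rep$centroid_site, "top")
  expect_true(rep$lak)
  # alternating ring carbons register with the subsurface layers
  sites <- attr(rep, "atom_sites")[[1]]
  expect_identical(sites, rep(c("hcp", "fcc"), 3))
})

test_that("stand-up, shifted and ring-free systems are LAK-negative", {
  up <- make_fixture("benzene_standup_on_au")
  rep_up <- detect_lak(up$system)
  expect_identical(rep_up$orientation, "stand-up")
  expect_false(rep_up$lak)

  # lateral shift by half a primitive lattice vector breaks the registry
  fx <- make_fixture("benzene_flat_on_au")
  s <- fx$system
  pm <- s$atoms$group == "peptide"
  s$coords[pm, 1:2] <- sweep(s$coords[pm, 1:2], 2, 0.5 * s$slab$a1, `+`)
  expect_false(detect_lak(s)$lak)

  # ring-free peptide: empty report
  slab <- build_fcc_slab(n_layers = 3, repeats = c(6, 6))
  pep <- build_conformation("Ac-SS-NH2")
  pep$coords[, 3] <- pep$coords[, 3] - min(pep$coords[, 3]) + 3
  rep0 <- detect_lak(merge_systems(pep, slab))
  expect_identical(nrow(rep0), 0L)
})

test_that("LAK detection is invariant under lattice translation and 60-degree ring rotation", {
  fx <- make_fixture("benzene_flat_on_au")
  base <- detect_lak(fx$system)
  pm <- fx$system$atoms$group == "peptide"

  s1 <- fx$system
  s1$coords[pm, 1:2] <- sweep(s1$coords[pm, 1:2], 2,
                              s1$slab$a1 + 2 * s1$slab$a2, `+`)
  t1 <- detect_lak(s1)
  expect_identical(t1$lak, base$lak)
  expect_identical(t1$centroid_site, base$centroid_site)

  s2 <- fx$system
  cen <- colMeans(s2$coords[pm, ])
  th <- pi / 3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  s2$coords[pm, ] <- sweep(sweep(s2$coords[pm, ], 2, cen) %*% t(R),
                           2, cen, `+`)
  t2 <- detect_lak(s2)
  expect_identical(t2$lak, base$lak)
  expect_identical(t2$orientation, base$orientation)
})

test_that("environment comparison reproduces the published vacuum/water contrasts", {
  cmp <- environment_comparison(
    vacuum = c(`S7-1` = -250.06, `S7-2` = -252.84),
    water = c(`S7-1` = -235.23, `S7-2` = -210.26))
  vac <- subset(cmp$contrasts, environment == "vacuum" & a == "S7-1")
  wat <- subset(cmp$contrasts, environment == "water" & a == "S7-1")
  expect_equal(abs(vac$percent_difference), 1.1, tolerance = 0.01)
  expect_equal(round(wat$percent_difference, 2), 11.88, tolerance = 1e-12)

  same <- environment_comparison(vacuum = c(a = -5, b = -5),
                                 water = c(a = -4, b = -4))
  expect_true(all(same$contrasts$percent_difference == 0))

  expect_error(environment_comparison(vacuum = c(a = -5), water = c(b = -4)),
               "matching")
})

test_that("percent differences swap consistently with the reference", {
  set.seed(4)
  for (rep in 1:20) {
    x <- -stats::runif(2, 50, 300)
    ab <- percent_difference(x[1], x[2])
    ba <- percent_difference(x[2], x[1])
    # recover one from the other through the reference change
    expect_equal(ba, -ab / (1 + ab / 100), tolerance = 1e-10)
  }
  expect_identical(percent_difference(-7, -7), 0)
})

test_that("mobility reports in-plane COM displacement, unwrapped", {
  fx <- make_fixture("tripeptide_on_slab")
  sys <- fx$system
  mk_traj <- function(frames) structure(
    list(frames = frames, system = sys, config = md_config(n_steps = 0),
         energies = data.frame(step = seq_along(frames) - 1)),
    class = "md_trajectory")

  static <- mobility(mk_traj(rep(list(sys$coords), 5)))
  expect_true(all(static$displacement == 0))

  shifted <- sys$coords
  pm <- sys$atoms$group == "peptide"
  shifted[pm, 1] <- shifted[pm, 1] + 3
  shifted[pm, 2] <- shifted[pm, 2] + 4
  expect_equal(mobility(mk_traj(list(sys$coords, shifted)))$max, 5,
               tolerance = 1e-12)

  # gradual translation by one cell vector, wrapped rigidly each frame,
  # unwraps to the full lattice-vector length
  a1cell <- sys$cell[, 1]
  Minv <- solve(sys$cell)
  frames <- lapply(seq(0, 1, length.out = 21), function(t) {
    f <- sys$coords
    f[pm, 1:2] <- sweep(f[pm, 1:2], 2, t * a1cell, `+`)
    com <- colMeans(f[pm, 1:2])
    wrap <- sys$cell %*% floor(Minv %*% com)
    f[pm, 1:2] <- sweep(f[pm, 1:2], 2, as.numeric(wrap))
    f
  })
  mob <- mobility(mk_traj(frames))
  expect_equal(mob$displacement[21], sqrt(sum(a1cell^2)), tolerance = 1e-9)
})
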