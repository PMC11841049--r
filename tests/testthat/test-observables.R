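# build a fake run carrying prescribed pressure samples
fake_run <- function(Pxx, Pyy, Pzz, Lz = 40, walled = FALSE) {
  n <- length(Pxx)
  run <- list(samples = data.frame(
    step = seq_len(n) * 50, temperature = 1, density = 3,
    Pxx = Pxx, Pyy = Pyy, Pzz = Pzz, Pxy = 0, Pxz = 0, Pyz = 0,
    Lx = 10, Ly = 10, Lz = Lz, wall_Pzz = 0),
    wall_included = walled)
  class(run) <- "dpd_run"
  run
}

test_that("block averages behave on degenerate and exact series", {
  ba <- block_average(rep(2.5, 100), 10)
  expect_equal(ba$mean, 2.5)
  expect_equal(ba$se, 0)
  # alternating series with an even block size cancels exactly
  ba2 <- block_average(rep(c(1, -1), 50), 10)
  expect_equal(ba2$mean, 0)
  expect_equal(ba2$se, 0)
  expect_error(block_average(1:5, 10), "length")
})

test_that("block-averaged errors track the analytic AR(1) value", {
  # AR(1) with phi = 0.6: var(mean of n) ~ var(x) (1+phi)/(1-phi) / n
  phi <- 0.6
  n <- 2000
  sd_analytic <- sqrt((1 / (1 - phi^2)) * (1 + phi) / (1 - phi) / n)
  set.seed(123)
  ses <- replicate(100, {
    x <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = 1))
    block_average(x, 20)$se
  })
  expect_equal(mean(ses), sd_analytic, tolerance = 0.3)
})

test_that("interfacial tension implements the slab pressure-anisotropy formula", {
  # isotropic tensor: zero tension
  run0 <- fake_run(rep(23.7, 100), rep(23.7, 100), rep(23.7, 100))
  expect_equal(interfacial_tension(run0, discard = 0)$reduced, 0)
  # P_zz exceeding the lateral components by 0.1 at L_z = 40 gives 2.0
  run1 <- fake_run(rep(23.6, 100), rep(23.6, 100), rep(23.7, 100))
  g <- interfacial_tension(run1, discard = 0)
  expect_equal(g$reduced, 2.0, tolerance = 1e-12)
  expect_equal(g$mN_m, tension_to_real(2.0), tolerance = 1e-12)
  # a walled run must be analyzed with surface_energy()
  expect_error(interfacial_tension(fake_run(1, 1, 1, walled = TRUE)),
               "surface_energy")
})

test_that("surface energy uses the same estimator and may be negative", {
  run <- fake_run(rep(5, 100), rep(5, 100), rep(4, 100), Lz = 10,
                  walled = TRUE)
  g <- surface_energy(run, discard = 0)
  expect_equal(g$reduced, -5, tolerance = 1e-12)
  # refusing runs without the wall-force virial guards a silent corruption
  run_nowall <- fake_run(rep(5, 100), rep(5, 100), rep(4, 100), walled = FALSE)
  expect_error(surface_energy(run_nowall), "wall")
})

test_that("in-plane anisotropy triggers a geometry warning", {
  set.seed(1)
  run <- fake_run(rnorm(200, 24, 0.01), rnorm(200, 23, 0.01),
                  rnorm(200, 24, 0.01))
  expect_warning(interfacial_tension(run, discard = 0), "anisotropy")
})

test_that("density profiles count beads per bin volume", {
  ff <- default_forcefield()
  # one bead per z-bin at known positions: density is 1/(area * width)
  z <- seq(0.125, 4, by = 0.25)
  pos <- cbind(1, 1, z)
  st <- dpd_state(pos, rep(1L, length(z)), c(2, 2, 4),
                  velocities = matrix(0, length(z), 3),
                  species_names = ff$species)
  prof <- density_profile(st, axis = "z", bin_width = 0.25)
  expect_equal(prof$density, rep(1 / (4 * 0.25), length(z)))
  # integrates back to N / area
  expect_equal(sum(prof$density * 0.25) * 4, length(z))
})

test_that("a repulsive wall orders the fluid over about two bead diameters", {
  ff <- default_forcefield()
  st <- build_confined(c(6, 6, 12), "water", 3, ff, seed = 23)
  run <- run_dpd(st, ff, steps = 4000, walls = dpd_walls(c(water = 40)),
                 seed = 23, sample_every = 0, trajectory_every = 500)
  prof <- density_profile(run$frames[5:8], species = "water", axis = "z",
                          bin_width = 0.25)
  bulk <- prof$density[prof$mid > 4 & prof$mid < 8]
  near <- prof$density[prof$mid < 2]
  # strong depletion at the repulsive wall, oscillations near it,
  # and a flat bulk in the slab center
  expect_lt(prof$density[1], 1)
  expect_gt(mean(abs(near - mean(bulk))), 3 * mean(abs(bulk - mean(bulk))))
  expect_equal(mean(bulk), 3, tolerance = 0.1)
})

test_that("a uniform bulk box has a flat profile at the bulk density", {
  st <- water_box(c(6, 6, 8), seed = 21)
  prof <- density_profile(st, species = "water", axis = "z", bin_width = 1)
  expect_equal(mean(prof$density), 3, tolerance = 0.01)
  # per-bin counting noise: sd ~ sqrt(3 * 36)/36 ~ 0.29 per bin
  expect_lt(max(abs(prof$density - 3)), 1)
})
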