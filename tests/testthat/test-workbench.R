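ff <- default_forcefield()

test_that("slabs hold equal bead numbers per phase at their densities", {
  st <- build_slab(c(6, 6, 20), ff, seed = 41)
  n_wat <- sum(st$species == 1)
  n_dod <- sum(st$species %in% 2:3)
  # equal bead numbers; phase volumes in inverse density proportion
  half <- 6 * 6 * 20 * 3 * 3.27 / (3 + 3.27)
  expect_equal(n_wat, round(half))
  expect_equal(n_dod, 7 * round(half / 7))  # whole 7-mers
  expect_lt(abs(n_wat - n_dod), 7)
  # each phase starts in its own region, split at the density-weighted z
  z_split <- 20 * 3.27 / (3 + 3.27)
  zw <- st$positions[st$species == 1, 3]
  zd <- st$positions[st$species %in% 2:3, 3]
  expect_true(all(zw <= z_split) && all(zd >= z_split))
  # per-phase starting densities match the requested ones
  expect_equal(n_wat / (36 * z_split), 3, tolerance = 1e-3)
  expect_equal(n_dod / (36 * (20 - z_split)), 3.27, tolerance = 2e-3)
  expect_error(build_slab(c(1, 1, 1), ff, density_a = 0.001,
                          density_b = 0.001), "too small")
})

test_that("identical fluids on both halves make a homogeneous box", {
  st <- build_slab(c(5, 5, 10), ff, species_a = "water",
                   species_b = "water", density_a = 3, density_b = 3,
                   seed = 42)
  expect_true(all(st$species == 1))
  expect_equal(nrow(st$positions), round(3 * 250 / 2) * 2)
})

test_that("confined fluids are whole molecules inside the walls", {
  st <- build_confined(c(5, 5, 12), "dodecane", 3.27, ff, seed = 43)
  expect_equal(nrow(st$positions) %% 7, 0)
  expect_equal(nrow(st$positions) / (5 * 5 * 12), 3.27, tolerance = 0.01)
  expect_true(all(st$positions[, 3] >= 0 & st$positions[, 3] <= 12))
  expect_true(st$walled)
  # water at rho = 3 in a 10 x 10 x 40 cell: 12,000 beads
  st2 <- build_confined(c(10, 10, 40), "water", 3, ff, seed = 44)
  expect_equal(nrow(st2$positions), 12000)
})

test_that("dry runs validate configurations without dynamics", {
  for (nm in c("tension", "surface-energy-scan", "droplet-validation",
               "sam-parametrization")) {
    rep0 <- reproduce_experiment(nm, scale = 0, seed = 1)
    expect_s3_class(rep0, "data.frame")
    expect_equal(nrow(rep0), 0)
  }
})

test_that("the SAM parametrization protocol reproduces the bundled amplitudes", {
  rep <- reproduce_experiment("sam-parametrization", scale = 1)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$value, rep$reference, tolerance = 0.05)
})

test_that("reports carry the content hash of the force field used", {
  rep0 <- reproduce_experiment("tension", scale = 0, seed = 1)
  h <- attr(rep0, "forcefield_hash")
  expect_match(h, "^[0-9a-f]{32}$")
  # stable for the same parameters, different for a modified amplitude
  rep1 <- reproduce_experiment("sam-parametrization", scale = 0, seed = 2)
  expect_identical(h, attr(rep1, "forcefield_hash"))
  rep2 <- reproduce_experiment("tension", scale = 0, seed = 1,
                               ff = default_forcefield(A_water_alkane = 100))
  expect_false(identical(h, attr(rep2, "forcefield_hash")))
})
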