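ff <- default_forcefield()

test_that("the bundled pair table has the expected structure", {
  expect_setequal(ff$species, c("2H2O", "CH2CH2", "CH3"))
  expect_identical(ff$A, t(ff$A))
  expect_identical(ff$R, t(ff$R))
  expect_true(all(ff$A > 0) && all(ff$R > 0))
  expect_equal(unname(ff$A["2H2O", "2H2O"]), 25)
  expect_equal(unname(ff$R["2H2O", "2H2O"]), 1)
  expect_equal(ff$max_cutoff, 1.0740)
  expect_error(dpd_forcefield(c("a", "b"), c(a = 1, b = 1),
                              matrix(c(1, 2, 3, 4), 2), diag(2) + 1),
               "symmetric")
})

test_that("dodecane is a 7-mer chain with the documented bonded terms", {
  dod <- build_dodecane()
  expect_length(dod$species, 7)
  expect_equal(dod$species[c(1, 7)], c("CH3", "CH3"))
  expect_equal(nrow(dod$bonds), 6)
  expect_equal(nrow(dod$angles), 5)
  expect_equal(dod$bonds$r0, c(0.29, rep(0.39, 4), 0.29))
  expect_true(all(dod$bonds$k_b == 150))
  expect_true(all(dod$angles$k_a == 5))
  expect_true(all(dod$angles$theta0 == pi))
  # consecutive triples along a simple chain
  expect_equal(dod$angles$j, dod$angles$i + 1)
  expect_equal(dod$angles$k, dod$angles$i + 2)
})

test_that("pair force follows the soft linear form", {
  # at the cutoff the interaction vanishes
  expect_equal(pair_force(ff, "2H2O", "2H2O", c(1, 0, 0))$magnitude, 0)
  # contact value approaches the amplitude
  expect_equal(pair_force(ff, "2H2O", "CH2CH2", c(1e-9, 0, 0))$magnitude,
               45, tolerance = 1e-6)
  # halfway inside the water-water range
  expect_equal(pair_force(ff, "2H2O", "2H2O", c(0.5, 0, 0))$magnitude, 12.5)
  expect_error(pair_force(ff, "2H2O", "2H2O", c(0, 0, 0)), "singular")
})

test_that("pair force is minus the gradient of the pair energy", {
  for (pair in list(c("2H2O", "2H2O"), c("2H2O", "CH3"),
                    c("CH2CH2", "CH2CH2"))) {
    for (r in c(0.2, 0.55, 0.9)) {
      h <- 1e-7
      up <- pair_force(ff, pair[1], pair[2], c(r + h, 0, 0))$energy
      dn <- pair_force(ff, pair[1], pair[2], c(r - h, 0, 0))$energy
      expect_equal(pair_force(ff, pair[1], pair[2], c(r, 0, 0))$magnitude,
                   -(up - dn) / (2 * h), tolerance = 1e-6)
    }
  }
})

test_that("bonded forces match the energy gradient and sum to zero", {
  set.seed(42)
  dod <- build_dodecane()
  # a perturbed near-linear chain
  pos <- cbind(cumsum(c(0, dod$bonds$r0)), 0, 0) +
    matrix(rnorm(21, sd = 0.08), 7, 3)
  out <- bonded_forces(pos, dod$bonds, dod$angles)
  # Newton's third law over the bonded cluster
  expect_equal(colSums(out$forces), c(0, 0, 0), tolerance = 1e-10)
  # force = -grad U, central differences
  efun <- function(p) bonded_forces(p, dod$bonds, dod$angles)$energy
  expect_equal(out$forces, -num_grad(efun, pos), tolerance = 1e-5)
})

test_that("bond and angle rest configurations are force-free", {
  b <- data.frame(i = 1, j = 2, k_b = 150, r0 = 0.39)
  pos <- rbind(c(0, 0, 0), c(0.39, 0, 0))
  expect_equal(bonded_forces(pos, b)$forces, matrix(0, 2, 3),
               tolerance = 1e-12)
  # stretched by 0.1: restoring force of magnitude k_b * 0.1 = 15
  pos2 <- rbind(c(0, 0, 0), c(0.49, 0, 0))
  out <- bonded_forces(pos2, b)
  expect_equal(out$forces[2, 1], -15, tolerance = 1e-10)
  expect_equal(sqrt(sum(out$forces[1, ]^2)), 15, tolerance = 1e-10)
  # collinear triple at the 180-degree rest angle
  a <- data.frame(i = 1, j = 2, k = 3, k_a = 5, theta0 = pi)
  pos3 <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.8, 0, 0))
  expect_equal(bonded_forces(pos3, NULL, a)$forces, matrix(0, 3, 3),
               tolerance = 1e-6)
})

test_that("the pair table round-trips through its TSV file bit-exactly", {
  path <- tempfile(fileext = ".tsv")
  write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_identical(ff$A[ff2$species, ff2$species], ff2$A)
  expect_identical(ff$R[ff2$species, ff2$species], ff2$R)
  expect_identical(unname(ff$mass[ff2$species]), unname(ff2$mass))
  unlink(path)
})
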