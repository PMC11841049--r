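test_that("length scale follows the water-bead mapping", {
  # 3 beads per r_c^3, 36 g/mol per bead, 1000 g/L water
  expect_equal(length_scale(3, 36, 1000), 0.564, tolerance = 1e-3)
  # doubling the bead mass 8-fold doubles r_c (cube-root scaling)
  expect_equal(length_scale(3, 36 * 8, 1000),
               2 * length_scale(3, 36, 1000), tolerance = 1e-12)
  # single-water bead mapping, direct arithmetic
  expect_equal(length_scale(3, 18, 1000),
               length_scale(3, 36, 1000) / 2^(1 / 3), tolerance = 1e-12)
  expect_equal(length_scale(3, 18, 1000), 0.448, tolerance = 1e-3)
  expect_error(length_scale(0, 36, 1000), "positive")
  expect_error(length_scale(3, -1, 1000), "positive")
})

test_that("density, pressure and tension conversions match the mapping", {
  u <- dpd_units()
  # N_A r_c^3 ~ 0.108 L/mol
  expect_equal(u$molar_volume_L, 0.108, tolerance = 1e-3)
  # liquid dodecane: 3.27 beads/r_c^3 at 24.3 g/mol -> ~740 g/L
  expect_equal(reduced_density_to_real(3.27, 24.3, u), 736, tolerance = 2e-3)
  # the reference water mapping is exact by construction
  expect_equal(reduced_density_to_real(3, 36, u), 1000, tolerance = 1e-10)
  expect_equal(reduced_density_to_real(0, 24.3, u), 0)
  # one reduced pressure unit ~ 2.3e7 Pa; operating pressure ~ 0.54 GPa
  expect_equal(pressure_to_real(1, u), 2.3e7, tolerance = 5e-3)
  expect_equal(pressure_to_real(23.7, u), 0.54e9, tolerance = 7e-3)
  expect_equal(pressure_to_real(0, u), 0)
  # one reduced tension unit ~ 12.9 mN/m
  expect_equal(tension_to_real(1, u), 12.9, tolerance = 4e-3)
  expect_equal(tension_to_real(0, u), 0)
  # inverse arithmetic: the reduced value that converts to 27.3 mN/m
  g_red <- 27.3 / tension_to_real(1, u)
  expect_equal(tension_to_real(g_red, u), 27.3, tolerance = 1e-12)
})

test_that("conversions are consistent and invertible", {
  u <- dpd_units()
  # tension factor equals pressure factor times r_c, for any value
  for (x in c(0.1, 1, 2.11, 23.7))
    expect_equal(tension_to_real(x, u),
                 pressure_to_real(x, u) * (u$r_c_nm * 1e-9) * 1e3,
                 tolerance = 1e-12)
  # real -> reduced -> real round trips to 10 significant digits
  rho <- 736.2
  rho_red <- rho * u$molar_volume_L / 24.3
  expect_equal(reduced_density_to_real(rho_red, 24.3, u), rho,
               tolerance = 1e-10)
  g <- 27.3
  expect_equal(tension_to_real(g / u$tension_mN_m, u), g, tolerance = 1e-10)
})

test_that("conversion factors are derived from inputs, not constants", {
  # a hypothetical coarser mapping shifts every factor coherently
  u2 <- dpd_units(bead_density = 3, molar_mass = 72, mass_density = 1000)
  expect_equal(u2$r_c_nm, dpd_units()$r_c_nm * 2^(1 / 3), tolerance = 1e-12)
  expect_equal(u2$tension_mN_m, dpd_units()$tension_mN_m / 2^(2 / 3),
               tolerance = 1e-12)
})
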