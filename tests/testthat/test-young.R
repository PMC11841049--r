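ref <- reference_wetting_data()

test_that("Young equation gives the documented angles from the tables", {
  # dodecane droplet (phase 2) in water (phase 1)
  expect_equal(round(young_angle(27.3, 28.5, 38.5)), 111)
  expect_equal(round(young_angle(27.3, 123.1, 147.9)), 155)
  # symmetric surfaces: a quarter-turn angle regardless of gamma_12
  expect_equal(young_angle(27.3, 50, 50), 90)
  expect_equal(young_angle(5, 20, 20), 90)
  expect_error(young_angle(27.3, 100, 10), "no finite contact angle")
  expect_error(young_angle(-1, 0, 0), "gamma_12 > 0")
})

test_that("spreading parameter classifies the three wetting regimes", {
  r <- spreading_regime(27.3, c(100, 10, 0, 30), c(10, 100, 0, 30 + 3 * 27.3))
  expect_equal(as.character(r$regime),
               c("spread", "detach", "partial", "detach"))
  expect_equal(r$S[3], -27.3)
  expect_equal(r$theta_deg[3], 90)
  # exact detachment threshold: theta = 180
  r2 <- spreading_regime(27.3, 0, 2 * 27.3 - 27.3)
  expect_equal(as.character(r2$regime), "detach-threshold")
  expect_equal(r2$theta_deg, 180)
  # theta -> 0 as S -> 0-, consistent with young_angle
  r3 <- spreading_regime(27.3, 10, 10 - 27.3 + 1e-6)
  expect_lt(r3$theta_deg, 1)
  expect_equal(r3$theta_deg, young_angle(27.3, 10, 10 - 27.3 + 1e-6),
               tolerance = 1e-9)
})

test_that("angle increases with the droplet-side surface energy", {
  g2 <- seq(10, 50, by = 5)
  th <- young_angle(27.3, 30, g2)
  expect_true(all(diff(th) > 0))
})

test_that("cubic fits recover exact data and diagnose the reference tables", {
  a <- c(0, 10, 20, 30, 40, 50)
  g <- 3 - 0.5 * a + 0.02 * a^2 - 1e-4 * a^3
  fit <- fit_gamma_cubic(a, g)
  expect_equal(fit$coefficients, c(3, -0.5, 0.02, -1e-4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_gamma_cubic(a[1:3], g[1:3]), "4 points")
  expect_error(fit_gamma_cubic(c(0, 10, 10, 20), g[1:4]), "increasing")
  # both measured surface-energy columns are nearly perfectly cubic
  # (R^2 = 0.99995, i.e. 0.9999 at floored four-decimal precision)
  for (fluid in c("water", "dodecane")) {
    f <- fit_gamma_cubic(ref$surface_energies$A_s,
                         ref$surface_energies[[fluid]])
    expect_gte(f$r_squared, 0.9999)
    expect_lt(f$r_squared, 1)
  }
  # the fitted dodecane curve rises monotonically over the scanned range
  fd <- fit_gamma_cubic(ref$surface_energies$A_s,
                        ref$surface_energies$dodecane)
  grid <- seq(0, 50, by = 0.5)
  expect_true(all(diff(predict(fd, grid)) > 0))
})

test_that("the angle map is antisymmetric for identical fluids and asymmetric otherwise", {
  fw <- fit_gamma_cubic(ref$surface_energies$A_s, ref$surface_energies$water)
  fd <- fit_gamma_cubic(ref$surface_energies$A_s,
                        ref$surface_energies$dodecane)
  a <- seq(0, 50, by = 10)
  m_same <- predict_angle_map(fw, fw, ref$gamma_12, a, a)
  # same fluid on both sides: 90 degrees on the diagonal, and
  # theta(a, b) + theta(b, a) = 180 wherever both are defined
  expect_equal(diag(m_same$theta_deg), rep(90, length(a)))
  both <- !is.na(m_same$theta_deg) & !is.na(t(m_same$theta_deg))
  expect_equal(m_same$theta_deg[both] + t(m_same$theta_deg)[both],
               rep(180, sum(both)))
  # two different fluids break the symmetry
  m_wd <- predict_angle_map(fw, fd, ref$gamma_12, a, a)
  expect_false(isTRUE(all.equal(m_wd$theta_deg[both] +
                                  t(m_wd$theta_deg)[both],
                                rep(180, sum(both)))))
  # regime bands obey the spreading-parameter inequalities
  part <- m_wd$regime == "partial" & !is.na(m_wd$regime)
  expect_true(all(m_wd$S[part] > -2 * ref$gamma_12 & m_wd$S[part] < 0))
})

test_that("amplitude inversion hits the SAM calibration points", {
  fw <- fit_gamma_cubic(ref$surface_energies$A_s, ref$surface_energies$water)
  g_dod30 <- ref$surface_energies$dodecane[ref$surface_energies$A_s == 30]
  for (i in seq_len(nrow(ref$sam))) {
    inv <- invert_for_amplitude(ref$sam$theta_exp[i], g_dod30, fw,
                                ref$gamma_12, free_side = "droplet")
    expect_equal(inv$amplitude, ref$sam$A_s_wat[i], tolerance = 0.05)
    # round trip: the returned amplitude reproduces the target angle
    expect_equal(inv$theta_check, ref$sam$theta_exp[i], tolerance = 1e-8)
  }
  expect_error(
    invert_for_amplitude(179, g_dod30, fw, ref$gamma_12,
                         free_side = "droplet"),
    "unreachable")
})
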