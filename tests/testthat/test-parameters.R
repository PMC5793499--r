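test_that("molar density ratios reproduce the tabulated volume-expansion factors", {
  om <- mg_molar_ratios(mg_physical_params())
  # (rho0/M0)/(rho1/M1) and (rho1/M1)/(rho2/M2)
  expect_equal(om$omega_alpha, (1.74 / 24.3) / (2.34 / 58.3), tolerance = 1e-12)
  expect_equal(om$omega_beta, (2.34 / 58.3) / (2.96 / 84.3), tolerance = 1e-12)
  expect_equal(signif(om$omega_alpha, 2), 1.8)
  expect_equal(signif(om$omega_beta, 2), 1.1)
  # identical molar densities give unit ratio
  om1 <- mg_molar_ratios(mg_physical_params(rho0 = 2.34, M0 = 58.3))
  expect_equal(om1$omega_alpha, 1)
})

test_that("non-dimensionalisation reproduces the tabulated coefficients", {
  p <- mg_nondimensionalize(mg_physical_params(k = 0.5), d = 1)
  expect_equal(p$gamma0, 1.2889, tolerance = 5e-5)
  expect_equal(p$gamma1, 0.7225, tolerance = 5e-5)
  expect_equal(abs(p$gamma2 - 1605.5) < 0.05, TRUE)
  expect_equal(p$DW, 2.85 / 1.66, tolerance = 1e-12)
  expect_equal(p$kappa, 0.5 / 1.66, tolerance = 1e-12)
  expect_equal(round(p$kappa, 1), 0.3)
  # infinite k maps to infinite kappa (Case 1 flag, not a large float)
  expect_true(is.infinite(mg_nondimensionalize(mg_physical_params())$kappa))
  # normalised coefficient: MW*rho0 == M0*W0* gives gamma0 = 1
  pn <- mg_nondimensionalize(mg_physical_params(MW = 24.3, rho0 = 1, W0_star = 1))
  expect_equal(pn$gamma0, 1)
})

test_that("kappa scales linearly in k and inversely in the CO2 diffusivity", {
  k1 <- mg_nondimensionalize(mg_physical_params(k = 0.2))$kappa
  k2 <- mg_nondimensionalize(mg_physical_params(k = 0.4))$kappa
  k3 <- mg_nondimensionalize(mg_physical_params(k = 0.2, DC_dim = 3.32))$kappa
  expect_equal(k2 / k1, 2, tolerance = 1e-12)
  expect_equal(k3 / k1, 0.5, tolerance = 1e-12)
})

test_that("one dimensionless time unit is the CO2 diffusion time in hours", {
  expect_equal(mg_time_unit_hours(mg_physical_params()), 24 / 1.66,
               tolerance = 1e-12)
  expect_equal(mg_time_unit_hours(
    mg_physical_params(DC_dim = 24, S0_star = 1)), 1)
  # quadratic in the reference length
  expect_equal(mg_time_unit_hours(mg_physical_params(S0_star = 2)),
               4 * mg_time_unit_hours(mg_physical_params()))
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(mg_physical_params(rho0 = -1), "positive")
  expect_error(mg_physical_params(eps1 = 1.2), "between 0 and 1")
  expect_error(mg_physical_params(k = 0), "positive")
  expect_error(mg_params(omega_alpha = 0.9), "exceed 1")
  expect_error(mg_params(d = 3), "must be 0, 1 or 2")
  expect_error(mg_params(S0 = 0), "positive")
})

test_that("presets encode the documented study configurations", {
  f3 <- mg_preset("fig3")
  expect_equal(f3$params$d, 1L)
  expect_equal(f3$params$eps1, 0.6)
  expect_equal(f3$params$eps2, 0.4)
  expect_equal(f3$params$kappa, 0.07 / 1.66, tolerance = 1e-12)
  expect_equal(f3$params$DW, 1.5625)
  expect_equal(f3$params$S0, 1)
  f4 <- mg_preset("fig4", d = 2)
  expect_true(is.infinite(f4$params$kappa))
  expect_equal(f4$params$d, 2L)
  expect_error(mg_preset("fig99"), "valid presets")
})
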