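test_that("velocity fields evaluate to their closed forms", {
  p <- mg_params(kappa = 0.04, omega_alpha = 1.8, omega_beta = 1.1, d = 1)
  vf <- mg_velocity_fields(0.5, 0.7, -0.1, -0.02, "P1_1", p)
  # direct evaluation at r = 0.6
  expect_equal(vf$vs1(0.6), 0.0667, tolerance = 5e-3)
  expect_equal(vf$vs1(0.6), -(1.8 - 1) * (-0.1) * 0.5 / 0.6, tolerance = 1e-12)
  expect_equal(vf$vf1(0.6), -0.1 * 0.5 / 0.6, tolerance = 1e-12)
  # no-slip: fluid velocity at alpha equals the interface rate
  expect_equal(vf$vf1(0.5), -0.1, tolerance = 1e-12)
  # evaluation below the inner bound errors
  expect_error(vf$vs1(0.3), "inner bound")
})

test_that("no volume change means static solid phase in every phase", {
  p <- mg_params(kappa = 0.04, omega_alpha = 1 + 1e-12, omega_beta = 1 + 1e-12)
  for (ph in c("P1_1", "P2_2")) {
    vf <- mg_velocity_fields(0.4, 0.6, -0.05, -0.01, ph, p)
    expect_equal(vf$vs1(0.5), 0, tolerance = 1e-10)
    expect_equal(vf$vs2(0.8), 0, tolerance = 1e-10)
  }
})

test_that("fluid flux is continuous across the hydroxide/carbonate interface", {
  # (1-eps1)(vf1(beta) - beta_dot) == (1-eps2)(vf2(beta) - beta_dot)
  set.seed(11)
  p <- mg_params(kappa = 0.3, d = 2)
  for (i in 1:20) {
    a <- runif(1, 0.1, 0.6); b <- runif(1, a + 0.05, 0.9)
    ad <- -runif(1, 0, 0.2); bd <- -runif(1, 0, 0.2)
    vf <- mg_velocity_fields(a, b, ad, bd, "P1_1", p)
    lhs <- (1 - p$eps1) * (vf$vf1(b) - bd)
    rhs <- (1 - p$eps2) * (vf$vf2(b) - bd)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("outer radius follows magnesium conservation", {
  p <- mg_params(omega_alpha = 1.8, omega_beta = 1.1, S0 = 1, d = 1)
  # initial and final configurations
  expect_equal(mg_outer_radius(1, 1, p), 1, tolerance = 1e-12)
  expect_equal(mg_outer_radius(0, 0, p), mg_final_size(p), tolerance = 1e-12)
  # direct evaluation: S^2 = 1.98 - 0.1*0.7^2 - 1.1*0.8*0.5^2 = 1.711
  expect_equal(mg_outer_radius(0.5, 0.7, p), sqrt(1.711), tolerance = 1e-12)
  expect_equal(mg_outer_radius(0.5, 0.7, p), 1.3080, tolerance = 5e-5)
  # S grows monotonically as the interfaces recede
  expect_true(mg_outer_radius(0.4, 0.7, p) > mg_outer_radius(0.5, 0.7, p))
  expect_true(mg_outer_radius(0.5, 0.6, p) > mg_outer_radius(0.5, 0.7, p))
  expect_error(mg_outer_radius(0.7, 0.5, p), "alpha <= beta")
})

test_that("final size has the a-priori volume-gain form and geometry ordering", {
  p1 <- mg_params(d = 1)
  expect_equal(mg_final_size(p1), sqrt(1.98), tolerance = 1e-12)
  expect_equal(mg_final_size(p1), 1.4071, tolerance = 5e-5)
  p2 <- mg_params(d = 2)
  expect_equal(mg_final_size(p2), 1.98^(1 / 3), tolerance = 1e-12)
  expect_equal(mg_final_size(p2), 1.2557, tolerance = 5e-5)
  p0 <- mg_params(d = 0)
  expect_true(mg_final_size(p2) < mg_final_size(p1))
  expect_true(mg_final_size(p1) < mg_final_size(p0))
  # no conversion gain: final size equals the initial size
  pu <- mg_params(omega_alpha = 1 + 1e-14, omega_beta = 1 + 1e-14)
  expect_equal(mg_final_size(pu), 1, tolerance = 1e-12)
})

test_that("magnesium balance residual vanishes for conservation-consistent states", {
  set.seed(7)
  for (d in 0:2) {
    p <- mg_params(d = d, S0 = 1.3)
    for (i in 1:10) {
      a <- runif(1, 0, 1.2); b <- runif(1, a, 1.3)
      st <- list(alpha = a, beta = b, S = mg_outer_radius(a, b, p))
      expect_lt(mg_balance_residual(st, p), 1e-10)
    }
    init <- list(alpha = 1.3, beta = 1.3, S = 1.3)
    expect_lt(mg_balance_residual(init, p), 1e-12)
    fin <- list(alpha = 0, beta = 0, S = mg_final_size(p))
    expect_lt(mg_balance_residual(fin, p), 1e-12)
  }
})
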