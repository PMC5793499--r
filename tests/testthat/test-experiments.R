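test_that("power-law fitting recovers exact exponents", {
  x <- c(0.5, 1, 2, 4, 8)
  expect_equal(mg_scaling_exponent(x, 3 * x^2), 2, tolerance = 1e-12)
  expect_equal(mg_scaling_exponent(x, 0.7 / x), -1, tolerance = 1e-12)
  expect_error(mg_scaling_exponent(c(1, 2), c(1, 4)), "at least 3")
  expect_error(mg_scaling_exponent(c(1, -2, 3), c(1, 4, 9)), "positive")
})

test_that("hydroxide-layer solid fraction controls core longevity only", {
  ps <- mg_preset("fig6")
  cfg <- mg_solver_config(n1 = 40, n2 = 40)
  sw <- mg_sweep("eps1", c(0.3, 0.5, 0.7), ps$params, cfg)
  expect_true(all(diff(sw$T_alpha) > 0))
  # T_beta essentially unaffected by eps1
  expect_lt(diff(range(sw$T_beta)) / mean(sw$T_beta), 0.01)
})

test_that("carbonate-layer solid fraction controls hydroxide longevity only", {
  sw <- eps2_sweep(40)
  expect_true(all(diff(sw$T_beta) > 0))
  expect_lt(diff(range(sw$T_alpha)) / mean(sw$T_alpha), 0.15)
})

test_that("slower surface kinetics prolong the core towards the instantaneous limit", {
  Ta <- c(kappa_run(0.3)$T_alpha, kappa_run(6)$T_alpha, kappa_run(60)$T_alpha)
  expect_true(all(diff(Ta) < 0))
  Ta_case1 <- fig4_run(40, d = 1)$T_alpha
  expect_true(all(Ta > Ta_case1 * 0.98))
  # the large-kappa runs approach the Case 1 value from above
  expect_lt(abs(Ta[3] - Ta_case1), abs(Ta[2] - Ta_case1))
})

test_that("advective transport choice orders core degradation as fluid < none < solid", {
  sims <- advection_runs(50)
  expect_lt(sims$fluid$T_alpha, sims$none$T_alpha)
  expect_lt(sims$none$T_alpha, sims$solid$T_alpha)
  # long-time behaviour and final size are insensitive to the choice
  Tb <- vapply(sims, function(s) s$T_beta, 0)
  expect_lt(diff(range(Tb)) / mean(Tb), 0.02)
  Sf <- vapply(sims, function(s) s$final_state$S, 0)
  expect_equal(unname(diff(range(Sf))), 0, tolerance = 1e-9)
})

test_that("sweeps tabulate one converged record per value and tolerate failures", {
  sw <- s0_sweep(40)
  expect_equal(nrow(sw), 4L)
  expect_true(all(is.finite(sw$T_beta)))
  expect_s3_class(sw, "mg_sweep")
  # an unphysical grid value yields an NA row and a warning, not an error
  ps <- mg_preset("fig6")
  cfg <- mg_solver_config(n1 = 40, n2 = 40, max_time = 1)
  expect_warning(
    sw_bad <- mg_sweep("eps2", c(0.4), ps$params, cfg),
    "failed")
  expect_true(is.na(sw_bad$T_beta[1]))
})
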