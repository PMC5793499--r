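test_that("seeded initial states honour the singular-start construction", {
  p <- mg_preset("fig3")$params
  cfg <- mg_solver_config(n1 = 40, n2 = 40, tau0 = 1e-8)
  st <- mg_initialize(p, cfg)
  expect_equal(st$phase, "P2_1")
  # leading-order kinetic displacement of the joint interface
  expect_equal(p$S0 - st$beta, (p$kappa / p$gamma0) * 1e-8, tolerance = 1e-6)
  expect_lt(p$S0 - st$beta, 1e-9)
  expect_lt(mg_balance_residual(st, p), 1e-12)

  p1 <- mg_preset("fig4")$params
  st1 <- mg_initialize(p1, cfg)
  expect_equal(st1$phase, "P1_1")
  expect_lt(mg_balance_residual(st1, p1), 1e-8)
  # seeded layers are thin and ordered
  expect_true(st1$alpha < st1$beta && st1$beta < st1$S)
  expect_equal(st1$beta - st1$alpha, cfg$delta_seed * p1$S0, tolerance = 1e-10)

  expect_error(mg_solver_config(tau0 = 0), "positive")
  expect_error(mg_initialize(p, cfg, case = 1), "finite")
  expect_error(mg_initialize(p1, cfg, case = 2), "infinite")
})

test_that("a finite-rate cylindrical run is monotone, conservative and ordered", {
  sim <- fig3_run(50)
  tr <- sim$trajectory
  expect_true(all(diff(tr$alpha) <= 1e-12))
  expect_true(all(diff(tr$beta) <= 1e-12))
  expect_true(all(diff(tr$S) >= -1e-12))
  expect_true(all(tr$alpha <= tr$beta + 1e-12 & tr$beta <= tr$S + 1e-12))
  expect_lt(max(mg_balance_residual(tr, sim$params)), 1e-6)
  # transition-time ordering and final size
  expect_true(sim$T_ab < sim$T_alpha && sim$T_alpha < sim$T_beta)
  expect_equal(sim$final_state$S, sim$S_inf, tolerance = 1e-6)
  expect_equal(tr$S[nrow(tr)], sim$S_inf, tolerance = 1e-6)
})

test_that("water accumulates above ambient near the reacting interface", {
  # production of water at the hydroxide->carbonate front lifts the local
  # concentration above the exterior value during the core phase
  sim <- fig3_run(50)
  snaps <- dplyr::bind_rows(sim$snapshots)
  w100 <- snaps[snaps$t == 100 & snaps$species == "W", ]
  expect_gt(max(w100$value), 1)
  # CO2 stays within physical bounds; water never goes negative
  cc <- snaps[snaps$species == "C", ]
  expect_gt(min(cc$value), -1e-6)
  expect_lt(max(cc$value), 1 + 1e-6)
  expect_gte(min(snaps$value[snaps$species == "W"]), -1e-9)
})

test_that("concentration snapshots carry both zones after the core phase begins", {
  sim <- fig3_run(50)
  snaps <- dplyr::bind_rows(sim$snapshots)
  s1 <- snaps[snaps$t == 1, ]
  expect_setequal(unique(s1$zone), c(1L, 2L))
  # zone 1 is still narrow shortly after it is created
  z1 <- s1[s1$zone == 1L, ]
  expect_lt(diff(range(z1$r)), 0.05)
})

test_that("phase states round-trip through JSON checkpoints", {
  p <- mg_preset("fig3")$params
  cfg <- mg_solver_config(n1 = 40, n2 = 40)
  st <- mg_initialize(p, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  mg_save_state(st, path)
  st2 <- mg_load_state(path)
  expect_equal(st2$phase, st$phase)
  expect_equal(st2$beta, st$beta, tolerance = 1e-14)
  expect_equal(st2$W2, st$W2, tolerance = 1e-14)
  expect_null(st2$W1)
})

test_that("instantaneous-reaction runs order degradation times by geometry", {
  sims <- lapply(0:2, function(d) fig4_run(40, d = d))
  Ta <- vapply(sims, function(s) s$T_alpha, 0)
  Tb <- vapply(sims, function(s) s$T_beta, 0)
  expect_true(Ta[1] > Ta[2] && Ta[2] > Ta[3])
  expect_true(Tb[1] > Tb[2] && Tb[2] > Tb[3])
  for (s in sims) expect_equal(s$final_state$S, s$S_inf, tolerance = 1e-6)
})

test_that("broom and ggplot2 methods expose the run", {
  sim <- fig3_run(50)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("t", "alpha", "beta", "S", "phase"))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$T_beta, sim$T_beta)
  pl <- ggplot2::autoplot(sim)
  expect_s3_class(pl, "ggplot")
})
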