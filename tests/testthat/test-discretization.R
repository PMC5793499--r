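# The spatial operator and the discrete interface conditions are exercised
# directly through the internal kernels.

test_that("transport operator is exact on steady and quadratic profiles", {
  n <- 40
  # uniform profile, static mesh, no advection: exact steady state
  X <- rep(0.7, n + 2)
  dX <- mgcorr:::zone_transport_rhs(X, 0.3, 1.1, 0, 0, 0, 1.5, 0L)
  expect_equal(max(abs(dX)), 0)
  # Cartesian central differences are exact on quadratics: X = r^2 gives 2D
  h <- (1.1 - 0.3) / (n + 1)
  r <- 0.3 + h * (0:(n + 1))
  dX2 <- mgcorr:::zone_transport_rhs(r^2, 0.3, 1.1, 0, 0, 0, 1.5, 0L)
  expect_equal(dX2, rep(2 * 1.5, n), tolerance = 1e-10)
})

test_that("radial diffusion operator converges at second order", {
  # X = cos(r) on a cylindrical annulus; L[X] = -cos(r) - sin(r)/r
  op_err <- function(n) {
    h <- 1 / (n + 1)
    r <- 0.5 + h * (0:(n + 1))
    dX <- mgcorr:::zone_transport_rhs(cos(r), 0.5, 1.5, 0, 0, 0, 1, 1L)
    exact <- -cos(r) - sin(r) / r
    max(abs(dX - exact[2:(n + 1)]))
  }
  ratio <- op_err(100) / op_err(200)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("discrete diffusive flux telescopes to the boundary fluxes", {
  # with V = 0 and a static mesh, sum_j r_j^d dX_j h equals the difference
  # of the conservation-form boundary fluxes: total mass changes only
  # through the boundaries
  n <- 60; d <- 2L; D <- 1.3
  inner <- 0.4; outer <- 1.2
  h <- (outer - inner) / (n + 1)
  r <- inner + h * (0:(n + 1))
  X <- 1 + sin(2 * r)
  dX <- mgcorr:::zone_transport_rhs(X, inner, outer, 0, 0, 0, D, d)
  j <- 2:(n + 1)
  total <- sum(r[j]^d * dX * h)
  flux_out <- D * (r[n + 1] + h / 2)^d * (X[n + 2] - X[n + 1]) / h
  flux_in <- D * (r[1] + h / 2)^d * (X[2] - X[1]) / h
  expect_equal(total, flux_out - flux_in, tolerance = 1e-10)
})

test_that("degenerate zones are refused by the transport operator", {
  X <- rep(1, 12)
  expect_error(
    mgcorr:::zone_transport_rhs(X, 0.5, 0.5 + 1e-14, 0, 0, 0, 1, 1L,
                                min_width = 1e-12),
    "seeded or asymptotic start")
})

test_that("joint-interface kinetics reproduce the finite-rate recession law", {
  # with ambient water at the interface, beta_dot = -kappa W^2 / gamma0
  p <- mg_params(kappa = 0.04, d = 1)
  cfg <- mg_solver_config(n1 = 40, n2 = 40)
  beta <- 0.98
  fi <- mgcorr:::phase_interface("P2_1", NULL, rep(1, 40), rep(1, 40),
                                 beta, beta, p, cfg)
  expect_equal(fi$beta_dot, -0.04 / 1.2889, tolerance = 1e-3)
  expect_equal(signif(fi$beta_dot, 2), -0.031)
  expect_true(fi$W_beta <= 1 && fi$W_beta > 0.99)
})

test_that("a flat water profile stalls the Stefan interface", {
  # Case 1: zero water gradient at alpha means no reaction flux, alpha_dot = 0
  p <- mg_params(kappa = Inf, d = 1)
  cfg <- mg_solver_config(n1 = 40, n2 = 40)
  fi <- mgcorr:::phase_interface("P1_1", rep(0, 40), rep(1, 40), rep(0.5, 40),
                                 0.5, 0.7, p, cfg)
  expect_equal(fi$alpha_dot, 0)
})

test_that("interface rates are non-positive and S_dot non-negative for expanding conversions", {
  set.seed(3)
  p <- mg_params(kappa = 0.3, d = 1)
  cfg <- mg_solver_config(n1 = 30, n2 = 30)
  for (i in 1:10) {
    W1 <- sort(runif(30, 0, 1))          # increasing water into zone 1
    W2 <- sort(runif(30, 0.5, 1))
    C2 <- sort(runif(30, 0, 1))          # CO2 increasing outwards
    fi <- mgcorr:::phase_interface("P2_2", W1, W2, C2, 0.4, 0.7, p, cfg)
    expect_lte(fi$alpha_dot, 0)
    expect_lte(fi$beta_dot, 0)
    expect_gte(fi$S_dot, 0)
  }
})

test_that("generic-flux interface conditions reduce to the native ones at no-slip", {
  W1 <- seq(0.2, 0.8, length.out = 30)
  W2 <- seq(0.8, 1, length.out = 30)
  C2 <- seq(0.1, 1, length.out = 30)
  # Case 1: the interface water value vanishes at alpha, so the advective
  # correction there is identically zero and beta_dot agrees exactly across
  # modes (the CO2 advective flux vanishes with C(beta) = 0)
  p1 <- mg_params(kappa = Inf, d = 1)
  fis1 <- lapply(c("fluid", "none", "solid"), function(m) {
    cfg <- mg_solver_config(n1 = 30, n2 = 30, advection_mode = m)
    mgcorr:::phase_interface("P1_1", W1, W2, C2, 0.4, 0.7, p1, cfg)
  })
  expect_equal(fis1[[1]]$beta_dot, fis1[[2]]$beta_dot, tolerance = 1e-14)
  expect_equal(fis1[[1]]$alpha_dot, fis1[[3]]$alpha_dot, tolerance = 1e-14)
  # Case 2: the interface water values differ only at the small
  # advective-correction scale
  p2 <- mg_params(kappa = 0.3, d = 1)
  fis2 <- lapply(c("fluid", "none", "solid"), function(m) {
    cfg <- mg_solver_config(n1 = 30, n2 = 30, advection_mode = m)
    mgcorr:::phase_interface("P2_2", W1, W2, C2, 0.4, 0.7, p2, cfg)
  })
  expect_equal(fis2[[2]]$W_beta, fis2[[1]]$W_beta, tolerance = 1e-2)
  expect_false(identical(fis2[[1]]$W_beta, fis2[[2]]$W_beta))
})

test_that("solver velocities agree with the closed-form velocity fields", {
  p <- mg_params(kappa = 0.3, d = 2)
  a <- 0.45; b <- 0.75; ad <- -0.07; bd <- -0.01
  r <- seq(b + 0.01, 1.1, length.out = 7)
  vf <- mg_velocity_fields(a, b, ad, bd, "P1_1", p)
  expect_equal(
    mgcorr:::zone_velocity(2L, "P1_1", "fluid", a, b, ad, bd, r, p),
    vf$vf2(r), tolerance = 1e-12)
  expect_equal(
    mgcorr:::zone_velocity(2L, "P1_1", "solid", a, b, ad, bd, r, p),
    vf$vs2(r), tolerance = 1e-12)
  r1 <- seq(a + 0.01, b, length.out = 5)
  expect_equal(
    mgcorr:::zone_velocity(1L, "P1_1", "fluid", a, b, ad, bd, r1, p),
    vf$vf1(r1), tolerance = 1e-12)
})
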