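# Method-of-lines kernel.
#
# Each zone is mapped by the affine front-fixing (Landau) transform onto the
# fixed interval rho in [1,2]: r(rho) = inner + (rho-1)*(outer-inner), so the
# moving-boundary PDEs become fixed-domain equations with an apparent
# advection -rdot(rho)*dX/dr from the mesh motion. Interior nodes are the ODE
# state; boundary values are eliminated algebraically from the active
# boundary/interface conditions using second-order 3-point one-sided
# gradient stencils, which also yields the interface rates (Stefan/kinetic
# conditions). Central differences are used for both advection and
# diffusion; an optional first-order upwind flag exists for robustness
# experiments.

# Positive root of the interface-kinetics polynomial
#   q3*w^3 + q2*w^2 + 3*w - b = 0,   q3, q2 >= 0,
# i.e. the Robin boundary-value solve normalised by the one-sided gradient
# coefficient a (q3 = A3/a, q2 = A2/a). The normalised form matters: when
# the zone is very thin a is enormous and the raw quadratic formula cancels
# catastrophically, and noise in the boundary value is amplified by the
# 1/h^2 diffusion stencil. The polynomial is increasing and convex on
# w >= 0, so it has exactly one non-negative root when b > 0; Newton from
# an upper starting point converges monotonically. b <= 0 (transient
# inverted gradient) maps to w = 0, a stalled interface.
pos_poly_root <- function(q3, q2, b) {
  if (b <= 0) return(0)
  # stable positive root of q2*w^2 + 3*w - b = 0 as the starting point
  w <- 2 * b / (3 + sqrt(9 + 4 * q2 * b))
  for (i in 1:60) {
    f <- ((q3 * w + q2) * w + 3) * w - b
    fp <- (3 * q3 * w + 2 * q2) * w + 3
    step <- f / fp
    w <- w - step
    if (abs(step) < 1e-15 * max(1, abs(w))) break
  }
  max(w, 0)
}

# Time-derivatives at the n interior nodes of one zone for one species.
#
# X: full grid values, length n+2 (boundary values included).
# inner/outer and their rates: current physical bounds of the zone.
# V: advective velocity at the interior nodes (length n or scalar).
# D: diffusivity; d: geometry index; upwind: first-order upwinding switch.
#
# The operator is the physical advection-diffusion RHS evaluated at fixed
# rho: dX/dt|rho = -(V - rdot)*dX/dr + (D/r^d) d/dr(r^d dX/dr), with
# rdot(rho) the affine mesh velocity. At a node sitting exactly at r = 0 the
# radial operator is replaced by its regular limit (d+1)*d2X/dr2.
zone_transport_rhs <- function(X, inner, outer, inner_dot, outer_dot,
                               V, D, d, min_width = 0, upwind = FALSE) {
  n <- length(X) - 2L
  width <- outer - inner
  if (!is.finite(width) || width <= min_width) {
    stop("zone width below the minimum (", format(min_width),
         "): a seeded or asymptotic start is required", call. = FALSE)
  }
  h <- width / (n + 1)
  j <- 2:(n + 1)
  r <- inner + h * (j - 1)
  rdot <- inner_dot + ((j - 1) / (n + 1)) * (outer_dot - inner_dot)
  vel <- V - rdot
  if (upwind) {
    dXf <- (X[j + 1] - X[j]) / h
    dXb <- (X[j] - X[j - 1]) / h
    adv <- vel * ifelse(vel > 0, dXb, dXf)
  } else {
    adv <- vel * (X[j + 1] - X[j - 1]) / (2 * h)
  }
  dd <- X[j + 1] - 2 * X[j] + X[j - 1]
  if (d == 0L) {
    lap <- dd / h^2
  } else {
    rp <- r + h / 2
    rm <- r - h / 2
    lap <- (rp^d * (X[j + 1] - X[j]) - rm^d * (X[j] - X[j - 1])) / (h^2 * r^d)
    at0 <- r == 0
    if (any(at0)) {
      lap[at0] <- (d + 1) * dd[at0] / h^2
    }
  }
  -adv + D * lap
}

# Interface rates and eliminated boundary values for one phase.
#
# Works from the interior grids; everything here is the discrete form of the
# active boundary-condition set of the phase. `mode` selects the advective
# velocity used in the interface flux balances ("fluid" reproduces the
# native porous-media conditions exactly because the no-slip/flux-continuity
# relations cancel the advective terms; "none"/"solid" use the generic
# moving-frame flux (1-eps)*((V-cdot)*X - D*dX/dr) with V = 0 or V = vs).
#
# Returns rates alpha_dot/beta_dot, boundary values W_alpha, W_beta, C_beta,
# the algebraic S and S_dot, and the zone spacings.
phase_interface <- function(phase, W1, W2, C2, alpha, beta, p, cfg) {
  d <- p$d; wa <- p$omega_alpha; wb <- p$omega_beta
  e1 <- p$eps1; e2 <- p$eps2
  DW <- p$DW; g0 <- p$gamma0; g1c <- p$gamma1; g2c <- p$gamma2
  kap <- p$kappa
  mode <- cfg$advection_mode
  minw <- cfg$min_zone_width * p$S0

  if (phase == "P2_1") {
    S <- outer_radius_raw(beta, beta, p)
    if (S - beta <= minw) {
      stop("zone 2 width below minimum in P2_1", call. = FALSE)
    }
    h2 <- (S - beta) / (length(W2) + 1)
    bw <- 4 * W2[1] - W2[2]
    bc <- 4 * C2[1] - C2[2]
    a2 <- DW * (1 - e2) / (2 * h2)
    cV2 <- switch(mode, fluid = 0, none = 1, solid = wa * wb)
    Wb <- pos_poly_root((1 - e2) * cV2 * kap / (g0 * a2),
                        g1c * wa * kap / (g0 * a2), bw)
    bdot <- -kap * Wb^2 / g0
    Cb <- (g2c * wa * bdot + (1 - e2) * bc / (2 * h2)) /
      ((1 - e2) * (3 / (2 * h2) - cV2 * bdot))
    Sdot <- -(wa * wb - 1) * pow_d(beta, d) * bdot / pow_d(S, d)
    return(list(alpha_dot = bdot, beta_dot = bdot, W_alpha = NA_real_,
                W_beta = Wb, C_beta = Cb, S = S, S_dot = Sdot,
                h1 = NA_real_, h2 = h2))
  }

  core <- phase %in% c("P1_1", "P2_2")
  if (!core) alpha <- 0
  S <- outer_radius_raw(alpha, beta, p)
  if (beta - alpha <= minw || S - beta <= minw) {
    stop("zone width below minimum in ", phase, call. = FALSE)
  }
  n1 <- length(W1); n2 <- length(W2)
  h1 <- (beta - alpha) / (n1 + 1)
  h2 <- (S - beta) / (n2 + 1)

  # alpha side
  if (core) {
    b1 <- 4 * W1[1] - W1[2]
    a1 <- (1 - e1) * DW / (2 * h1)
    if (is.infinite(kap)) {
      Wa <- 0
      adot <- -a1 * b1 / (2 * g0)
    } else {
      cV1 <- switch(mode, fluid = 0, none = 1, solid = wa)
      Wa <- pos_poly_root((1 - e1) * cV1 * kap / (g0 * a1), 2 * kap / a1, b1)
      adot <- -kap * Wa^2 / g0
    }
    if (adot > 0) adot <- 0  # interface never regrows
  } else {
    Wa <- (4 * W1[1] - W1[2]) / 3  # no-flux ghost value at r = 0
    adot <- 0
  }

  # beta side: CO2 exhaustion Dirichlet + its flux sets beta_dot, then the
  # water-flux jump sets the shared interface water value.
  bc <- 4 * C2[1] - C2[2]
  ad <- pow_d(alpha, d) * adot
  vs1b <- -(wa - 1) * ad / pow_d(beta, d)
  bdot <- vs1b - (1 - e2) * bc / (2 * h2) / g2c
  if (bdot > 0) bdot <- 0
  bd <- pow_d(beta, d) * bdot
  if (mode == "fluid") {
    Tadv <- 0
  } else {
    V1b <- if (!core) 0 else switch(mode, none = 0,
                                    solid = -(wa - 1) * ad / pow_d(beta, d))
    V2b <- switch(mode,
                  none = 0,
                  solid = -(wb * (wa - 1) * ad + (wb - 1) * bd) / pow_d(beta, d))
    Tadv <- (1 - e2) * (V2b - bdot) - (1 - e1) * (V1b - bdot)
  }
  c1 <- 4 * W1[n1] - W1[n1 - 1]
  c2 <- 4 * W2[1] - W2[2]
  rhsv <- -g1c * (bdot - vs1b)
  Wb <- (rhsv + DW * (1 - e2) * c2 / (2 * h2) + DW * (1 - e1) * c1 / (2 * h1)) /
    (Tadv + 3 * DW * ((1 - e2) / (2 * h2) + (1 - e1) / (2 * h1)))
  Sdot <- outer_radius_rate(alpha, beta, adot, bdot, S, p)
  list(alpha_dot = adot, beta_dot = bdot, W_alpha = Wa, W_beta = Wb,
       C_beta = 0, S = S, S_dot = Sdot, h1 = h1, h2 = h2)
}

# Advective velocity (selected by mode) at the interior nodes of one zone.
# All fields are const / r^d; the constant is phase- and mode-dependent.
zone_velocity <- function(zone, phase, mode, alpha, beta, adot, bdot, r, p) {
  d <- p$d; wa <- p$omega_alpha; wb <- p$omega_beta
  e1 <- p$eps1; e2 <- p$eps2
  if (mode == "none") return(0)
  ad <- pow_d(alpha, d) * adot
  bd <- pow_d(beta, d) * bdot
  core <- phase %in% c("P1_1", "P2_2")
  num <- if (zone == 1L) {
    if (!core) 0
    else if (mode == "fluid") ad else -(wa - 1) * ad
  } else if (phase == "P2_1") {
    if (mode == "fluid") bd else -(wa * wb - 1) * bd
  } else if (core) {
    if (mode == "fluid") ((1 - e1) * ad - (e2 - e1) * bd) / (1 - e2)
    else -(wb * (wa - 1) * ad + (wb - 1) * bd)
  } else {
    if (mode == "fluid") -(e2 - e1) * bd / (1 - e2) else -(wb - 1) * bd
  }
  if (num == 0) 0 else num / pow_d(r, d)
}

# Full time-derivative vector for the ODE state of one phase.
#
# State layouts:
#   P2_1:              (W2 interior, C2 interior, beta)
#   P1_1 / P2_2:       (W1, W2, C2 interiors, alpha, beta)
#   P1_2 / P2_3:       (W1, W2, C2 interiors, beta)      [alpha == 0]
# S is always algebraic (magnesium conservation), never integrated.
phase_rhs <- function(t, y, ctx) {
  p <- ctx$p; cfg <- ctx$cfg; phase <- ctx$phase
  n1 <- ctx$n1; n2 <- ctx$n2
  d <- p$d
  mode <- cfg$advection_mode
  minw <- cfg$min_zone_width * p$S0

  if (phase == "P2_1") {
    # The last state entry is the receded depth u = S0 - beta, not beta:
    # near the singular start u is ~kappa*tau0/gamma0 << S0 and integrating
    # it directly keeps finite-difference Jacobian perturbations far smaller
    # than the zone width.
    W2 <- y[1:n2]; C2 <- y[n2 + (1:n2)]; beta <- p$S0 - y[2 * n2 + 1]
    fi <- phase_interface(phase, NULL, W2, C2, beta, beta, p, cfg)
    W2f <- c(fi$W_beta, W2, 1)
    C2f <- c(fi$C_beta, C2, 1)
    j <- 2:(n2 + 1)
    r2 <- beta + fi$h2 * (j - 1)
    V2 <- zone_velocity(2L, phase, mode, beta, beta, fi$beta_dot, fi$beta_dot,
                        r2, p)
    dW2 <- zone_transport_rhs(W2f, beta, fi$S, fi$beta_dot, fi$S_dot, V2,
                              p$DW, d, minw, cfg$upwind)
    dC2 <- zone_transport_rhs(C2f, beta, fi$S, fi$beta_dot, fi$S_dot, V2,
                              1, d, minw, cfg$upwind)
    return(list(c(dW2, dC2, -fi$beta_dot), c(C_beta = fi$C_beta, S = fi$S)))
  }

  core <- phase %in% c("P1_1", "P2_2")
  W1 <- y[1:n1]; W2 <- y[n1 + (1:n2)]; C2 <- y[n1 + n2 + (1:n2)]
  if (core) {
    alpha <- y[n1 + 2 * n2 + 1]; beta <- y[n1 + 2 * n2 + 2]
  } else {
    # log(beta) is the integrated variable once the core is gone: trial
    # iterates of the implicit solver then cannot drive the hydroxide zone
    # to negative width while beta shrinks towards the stop radius.
    alpha <- 0; beta <- exp(y[n1 + 2 * n2 + 1])
  }
  fi <- phase_interface(phase, W1, W2, C2, alpha, beta, p, cfg)
  W1f <- c(fi$W_alpha, W1, fi$W_beta)
  W2f <- c(fi$W_beta, W2, 1)
  C2f <- c(0, C2, 1)
  j1 <- 2:(n1 + 1); j2 <- 2:(n2 + 1)
  r1 <- alpha + fi$h1 * (j1 - 1)
  r2 <- beta + fi$h2 * (j2 - 1)
  V1 <- zone_velocity(1L, phase, mode, alpha, beta, fi$alpha_dot, fi$beta_dot,
                      r1, p)
  V2 <- zone_velocity(2L, phase, mode, alpha, beta, fi$alpha_dot, fi$beta_dot,
                      r2, p)
  dW1 <- zone_transport_rhs(W1f, alpha, beta, fi$alpha_dot, fi$beta_dot, V1,
                            p$DW, d, minw, cfg$upwind)
  dW2 <- zone_transport_rhs(W2f, beta, fi$S, fi$beta_dot, fi$S_dot, V2,
                            p$DW, d, minw, cfg$upwind)
  dC2 <- zone_transport_rhs(C2f, beta, fi$S, fi$beta_dot, fi$S_dot, V2,
                            1, d, minw, cfg$upwind)
  dy <- if (core) c(dW1, dW2, dC2, fi$alpha_dot, fi$beta_dot)
        else c(dW1, dW2, dC2, fi$beta_dot / beta)
  list(dy, c(S = fi$S))
}

# Terminal-event function per phase: the integrator stops at a sign change.
phase_rootfunc <- function(t, y, ctx) {
  p <- ctx$p; cfg <- ctx$cfg; phase <- ctx$phase
  n1 <- ctx$n1; n2 <- ctx$n2
  stop_r <- cfg$stop_radius * p$S0
  if (phase == "P2_1") {
    W2 <- y[1:n2]; C2 <- y[n2 + (1:n2)]; beta <- p$S0 - y[2 * n2 + 1]
    fi <- phase_interface(phase, NULL, W2, C2, beta, beta, p, ctx$cfg)
    return(fi$C_beta)
  }
  if (phase %in% c("P1_1", "P2_2")) {
    alpha <- y[n1 + 2 * n2 + 1]
    return(alpha - stop_r)
  }
  beta <- exp(y[n1 + 2 * n2 + 1])
  # For d >= 1 the quasi-steady CO2 profile has a boundary layer of radial
  # scale beta at the inner interface; once beta falls below a few zone-2
  # spacings the one-sided gradient there is no longer resolved, so the
  # handover to the analytic tail happens at whichever threshold is met
  # first.
  thr <- cfg$endgame_width * p$S0
  if (p$d > 0L) {
    S <- outer_radius_raw(0, beta, p)
    thr <- max(thr, 8 * (S - beta) / (n2 + 1))
  }
  beta - thr
}
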