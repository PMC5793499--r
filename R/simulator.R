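#' Solver configuration
#'
#' Numerical controls for [mg_simulate()].
#'
#' @param n1,n2 Interior nodes in zone 1 (hydroxide) and zone 2 (carbonate);
#'   at least 20.
#' @param rtol,atol Relative/absolute tolerances of the stiff integrator.
#' @param tau0 Start-time offset (> 0): integration starts from a seeded
#'   state at `t = tau0` rather than from the singular all-coincident
#'   initial condition `alpha = beta = S = S0`.
#' @param delta_seed Relative thickness used to seed a freshly created zone
#'   (fraction of `S0`).
#' @param stop_radius Inner-interface position (fraction of `S0`) treated as
#'   zero: the Mg core is never integrated exactly to the origin, where the
#'   `1/r^d` velocity fields blow up. The truncated-volume error is
#'   O(stop_radius^(d+1)).
#' @param endgame_width Hydroxide-layer width (fraction of `S0`) at which
#'   the final phase hands over to the analytic quasi-steady tail: below
#'   this width the shrinking zone-1 mesh can no longer resolve the (flat)
#'   water profile in double precision, while the CO2 transport that drives
#'   `beta` is quasi-steady, so the remaining exhaustion time is computed by
#'   quadrature of the quasi-steady interface flux instead of integrated.
#' @param advection_mode Advective velocity used for reactant transport:
#'   `"fluid"` (porous-media fluid velocity, the native model), `"none"`
#'   (pure diffusion) or `"solid"` (reactants dragged with the crystal
#'   structure). Interface flux balances switch consistently.
#' @param snapshot_times Dimensionless times at which to store concentration
#'   profiles.
#' @param max_time Safety cap on integration time.
#' @param min_zone_width Hard guard (fraction of `S0`) below which the
#'   transport operator refuses a zone; degenerate zones must be seeded.
#' @param upwind Use first-order upwinding for advection instead of central
#'   differences (robustness experiments only).
#' @param trajectory_points Target number of stored trajectory points per
#'   phase (log-spaced in time).
#' @param verbose Log phase transitions.
#' @return An object of class `mg_solver_config`.
#' @export
mg_solver_config <- function(n1 = 200, n2 = 200, rtol = 1e-7, atol = 1e-9,
                             tau0 = 1e-8, delta_seed = 1e-5,
                             stop_radius = 1e-6, endgame_width = 1e-4,
                             advection_mode = c("fluid", "none", "solid"),
                             snapshot_times = NULL, max_time = 1e6,
                             min_zone_width = 1e-12, upwind = FALSE,
                             trajectory_points = 150, verbose = FALSE) {
  advection_mode <- match.arg(advection_mode)
  if (n1 < 20 || n2 < 20) stop("n1 and n2 must be at least 20", call. = FALSE)
  if (!is.numeric(tau0) || tau0 <= 0) {
    stop("`tau0` must be positive: the coincident-interface initial state is ",
         "singular and integration starts from a seeded state", call. = FALSE)
  }
  if (delta_seed <= 0 || delta_seed >= 0.1) {
    stop("`delta_seed` must be a small positive fraction", call. = FALSE)
  }
  if (stop_radius <= 0 || stop_radius >= 0.1) {
    stop("`stop_radius` must be a small positive fraction", call. = FALSE)
  }
  if (endgame_width <= 0 || endgame_width >= 0.1) {
    stop("`endgame_width` must be a small positive fraction", call. = FALSE)
  }
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), rtol = rtol,
                 atol = atol, tau0 = tau0, delta_seed = delta_seed,
                 stop_radius = stop_radius, endgame_width = endgame_width,
                 advection_mode = advection_mode,
                 snapshot_times = snapshot_times, max_time = max_time,
                 min_zone_width = min_zone_width, upwind = upwind,
                 trajectory_points = as.integer(trajectory_points),
                 verbose = isTRUE(verbose)),
            class = "mg_solver_config")
}

new_phase_state <- function(phase, t, alpha, beta, S, W1, W2, C2) {
  structure(list(phase = phase, t = t, alpha = alpha, beta = beta, S = S,
                 W1 = W1, W2 = W2, C2 = C2),
            class = "mg_phase_state")
}

#' @export
print.mg_phase_state <- function(x, ...) {
  cat(sprintf("<mg_phase_state> phase %s at t = %g\n", x$phase, x$t))
  cat(sprintf("  alpha = %g, beta = %g, S = %g\n", x$alpha, x$beta, x$S))
  invisible(x)
}

#' Seeded initial state for a corrosion run
#'
#' The exact initial condition has all three interfaces coincident at `S0`
#' and is singular; integration therefore starts from a thin seeded state at
#' `t = tau0` with quasi-steady profiles.
#'
#' For Case 2 (finite `kappa`) the run starts in phase `P2_1` with the joint
#' interface displaced to leading order by the surface kinetics at ambient
#' water concentration, `beta = S0 - (kappa/gamma0) * tau0`, and uniform
#' ambient water and CO2 in the thin carbonate shell. For Case 1
#' (instantaneous reaction, `kappa = Inf`) the run starts in phase `P1_1`
#' with both product layers seeded at relative thickness `delta_seed` and a
#' linear water profile across the hydroxide layer. Transition times are
#' insensitive to both `tau0` and `delta_seed` over wide ranges (see the
#' package vignette).
#'
#' @param p An [mg_params()] object; `kappa` selects the case.
#' @param cfg An [mg_solver_config()].
#' @param case Optionally assert the reaction case (1 or 2); an error is
#'   raised if it contradicts `kappa`.
#' @return An `mg_phase_state`.
#' @export
mg_initialize <- function(p, cfg = mg_solver_config(), case = NULL) {
  stopifnot(inherits(p, "mg_params"), inherits(cfg, "mg_solver_config"))
  case1 <- is.infinite(p$kappa)
  if (!is.null(case)) {
    if (case == 1 && !case1) {
      stop("Case 1 requested but `kappa` is finite", call. = FALSE)
    }
    if (case == 2 && case1) {
      stop("Case 2 requested but `kappa` is infinite", call. = FALSE)
    }
  }
  S0 <- p$S0
  if (case1) {
    delta <- cfg$delta_seed * S0
    alpha <- S0 - 2 * delta
    beta <- S0 - delta
    S <- mg_outer_radius(alpha, beta, p)
    W1 <- (1:cfg$n1) / (cfg$n1 + 1)  # linear, 0 at alpha to 1 at beta
    new_phase_state("P1_1", cfg$tau0, alpha, beta, S,
                    W1, rep(1, cfg$n2), rep(1, cfg$n2))
  } else {
    beta <- S0 - (p$kappa / p$gamma0) * cfg$tau0
    if (beta <= 0) stop("`tau0` too large for this kappa", call. = FALSE)
    S <- mg_outer_radius(beta, beta, p)
    new_phase_state("P2_1", cfg$tau0, beta, beta, S,
                    NULL, rep(1, cfg$n2), rep(1, cfg$n2))
  }
}

# In P2_1 the integrated interface variable is the receded depth
# u = S0 - beta (tiny near the singular start), not beta itself.
pack_state <- function(state, p) {
  switch(state$phase,
         P2_1 = c(state$W2, state$C2, p$S0 - state$beta),
         P1_1 = ,
         P2_2 = c(state$W1, state$W2, state$C2, state$alpha, state$beta),
         P1_2 = ,
         P2_3 = c(state$W1, state$W2, state$C2, log(state$beta)),
         stop("cannot pack state in phase ", state$phase))
}

unpack_state <- function(y, t, phase, p, cfg) {
  n1 <- cfg$n1; n2 <- cfg$n2
  if (phase == "P2_1") {
    beta <- p$S0 - y[2 * n2 + 1]
    new_phase_state(phase, t, beta, beta, mg_outer_radius(beta, beta, p),
                    NULL, y[1:n2], y[n2 + (1:n2)])
  } else if (phase %in% c("P1_1", "P2_2")) {
    alpha <- y[n1 + 2 * n2 + 1]; beta <- y[n1 + 2 * n2 + 2]
    new_phase_state(phase, t, alpha, beta, mg_outer_radius(alpha, beta, p),
                    y[1:n1], y[n1 + (1:n2)], y[n1 + n2 + (1:n2)])
  } else {
    beta <- exp(y[n1 + 2 * n2 + 1])
    new_phase_state(phase, t, 0, beta, mg_outer_radius(0, beta, p),
                    y[1:n1], y[n1 + (1:n2)], y[n1 + n2 + (1:n2)])
  }
}

# Analytic small-time advance for the joint-interface phase.
#
# While the carbonate shell is thinner than the seeding scale
# delta_seed * S0, its interior is quasi-steady to round-off and the
# interface follows the surface kinetics at ambient water concentration,
# beta_dot = -kappa/gamma0. Discretising a shell this thin is numerically
# meaningless (second differences of the near-ambient profiles fall below
# machine precision), so the state is advanced in closed form until the
# shell reaches the seeding scale and only then handed to the integrator,
# seeded with the quasi-steady linear profiles implied by the interface
# flux conditions.
lift_p21_state <- function(state, p, cfg) {
  delta <- cfg$delta_seed * p$S0
  # never lift past the point where interface CO2 would drop below ~half
  # ambient (fast kinetics exhaust CO2 while the shell is still thin)
  slope_C_cap <- p$gamma2 * p$omega_alpha * p$kappa /
    (p$gamma0 * (1 - p$eps2))
  delta <- min(delta, 0.5 / slope_C_cap)
  width0 <- state$S - state$beta
  if (width0 >= delta) {
    return(list(state = state, trajectory = NULL))
  }
  f <- function(b) (outer_radius_raw(b, b, p) - b) - delta
  beta_t <- stats::uniroot(f, c(p$S0 / 2, state$beta), tol = 1e-15)$root
  t_lift <- state$t + (state$beta - beta_t) * p$gamma0 / p$kappa
  tt <- exp(seq(log(state$t), log(t_lift), length.out = 25))
  beta_v <- state$beta - (p$kappa / p$gamma0) * (tt - state$t)
  S_v <- vapply(beta_v, function(b) outer_radius_raw(b, b, p), 0)
  traj <- tibble::tibble(t = tt, alpha = beta_v, beta = beta_v, S = S_v,
                         phase = "P2_1")
  S_t <- S_v[length(S_v)]
  n2 <- length(state$W2)
  r2 <- seq(beta_t, S_t, length.out = n2 + 2)[2:(n2 + 1)]
  slope_W <- p$gamma1 * p$omega_alpha * p$kappa /
    (p$gamma0 * (1 - p$eps2) * p$DW)
  slope_C <- p$gamma2 * p$omega_alpha * p$kappa / (p$gamma0 * (1 - p$eps2))
  st <- new_phase_state("P2_1", t_lift, beta_t, beta_t, S_t, NULL,
                        1 - slope_W * (S_t - r2), 1 - slope_C * (S_t - r2))
  list(state = st, trajectory = traj)
}

# Remaining hydroxide-exhaustion time from beta_e down to zero under the
# quasi-steady CO2 approximation: beta_dot = -(1-eps2) * dC/dr|beta / gamma2
# with the quasi-steady radial profile C(beta) = 0, C(S) = 1 and S slaved to
# beta by conservation. The integrand vanishes at the origin for d >= 1 and
# is finite for d = 0; the result is O(beta_e^2 * gamma2), far below the
# phase duration for the default endgame width.
qs_tail_time <- function(beta_e, p, with_beta = NULL) {
  d <- p$d
  gradC <- function(b) {
    S <- outer_radius_raw(0, b, p)
    if (d == 0L) 1 / (S - b)
    else if (d == 1L) 1 / (b * log(S / b))
    else S / (b * (S - b))
  }
  integrand <- Vectorize(function(b) p$gamma2 / ((1 - p$eps2) * gradC(b)))
  tail_from <- function(b) {
    stats::integrate(integrand, 0, b, rel.tol = 1e-10)$value
  }
  if (is.null(with_beta)) tail_from(beta_e)
  else vapply(with_beta, tail_from, 0)
}

# log-spaced output times for one phase
phase_times <- function(t0, cfg) {
  tt <- exp(seq(log(t0), log(cfg$max_time), length.out = cfg$trajectory_points))
  snaps <- cfg$snapshot_times
  if (!is.null(snaps)) {
    tt <- c(tt, snaps[snaps > t0 & snaps < cfg$max_time])
  }
  sort(unique(tt))
}

#' Integrate one corrosion phase to its terminal event
#'
#' Advances the method-of-lines system with the stiff `lsodar` integrator
#' (variable-order BDF with root finding) until the phase's terminal event:
#' exhaustion of CO2 at the joint interface (`P2_1`), the Mg core shrinking
#' to `stop_radius` (`P1_1`/`P2_2`), or the hydroxide layer shrinking to
#' `stop_radius` (`P1_2`/`P2_3`).
#'
#' @param state An `mg_phase_state`.
#' @param p An [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @return A list with `state` (at the event), `event` (label), `trajectory`
#'   (tibble of t, alpha, beta, S, phase) and `snapshots`.
#' @export
mg_integrate_phase <- function(state, p, cfg = mg_solver_config()) {
  stopifnot(inherits(state, "mg_phase_state"))
  phase <- state$phase
  if (phase == "DONE") stop("phase is DONE; nothing to integrate", call. = FALSE)
  pre_traj <- NULL
  if (phase == "P2_1") {
    lifted <- lift_p21_state(state, p, cfg)
    pre_traj <- lifted$trajectory
    state <- lifted$state
  }
  n1 <- if (is.null(state$W1)) 0L else length(state$W1)
  n2 <- length(state$W2)
  cfg_run <- cfg
  cfg_run$n1 <- max(n1, 1L); cfg_run$n2 <- n2
  ctx <- list(p = p, cfg = cfg_run, phase = phase, n1 = n1, n2 = n2)
  y0 <- pack_state(state, p)
  tt <- phase_times(state$t, cfg)
  # The first step must undercut the fastest diffusive relaxation time of
  # the freshly seeded grids (~h_min^2/D); the integrator's automatic
  # initial step is chosen from the residual norm alone and overshoots it.
  w1 <- if (phase == "P2_1") Inf else (state$beta - state$alpha) / (n1 + 1)
  w2 <- (state$S - state$beta) / (n2 + 1)
  hini <- 0.01 * min(w1, w2)^2 / max(p$DW, 1)
  out <- deSolve::lsodar(y = y0, times = tt, func = phase_rhs, parms = ctx,
                         rtol = cfg$rtol, atol = cfg$atol,
                         rootfunc = phase_rootfunc, maxsteps = 100000,
                         hini = hini)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0) {
    stop(sprintf("no terminal event before max_time = %g in phase %s",
                 cfg$max_time, phase), call. = FALSE)
  }
  tend <- out[nrow(out), 1]
  yend <- out[nrow(out), 1 + seq_along(y0)]
  end_state <- unpack_state(unname(yend), tend, phase, p, cfg_run)
  event <- switch(phase,
                  P2_1 = "co2_exhausted",
                  P1_1 = , P2_2 = "mg_exhausted",
                  P1_2 = , P2_3 = "hydroxide_exhausted")
  # trajectory columns
  times_out <- out[, 1]
  if (phase == "P2_1") {
    beta_v <- p$S0 - out[, 1 + 2 * n2 + 1]
    alpha_v <- beta_v
  } else if (phase %in% c("P1_1", "P2_2")) {
    alpha_v <- out[, 1 + n1 + 2 * n2 + 1]
    beta_v <- out[, 1 + n1 + 2 * n2 + 2]
  } else {
    beta_v <- exp(out[, 1 + n1 + 2 * n2 + 1])
    alpha_v <- rep(0, nrow(out))
  }
  S_v <- out[, ncol(out)]  # algebraic S is the last auxiliary column
  traj <- tibble::tibble(t = times_out, alpha = unname(alpha_v),
                         beta = unname(beta_v), S = unname(S_v),
                         phase = phase)
  if (!is.null(pre_traj)) traj <- dplyr::bind_rows(pre_traj, traj)
  if (phase %in% c("P1_2", "P2_3")) {
    # analytic quasi-steady tail from the endgame width down to zero
    beta_e <- end_state$beta
    dt_tail <- qs_tail_time(beta_e, p)
    bb <- beta_e * 10^seq(-0.5, -3, length.out = 6)
    tail_t <- tend + dt_tail - qs_tail_time(beta_e, p, with_beta = bb)
    tail_rows <- tibble::tibble(
      t = c(tail_t, tend + dt_tail), alpha = 0, beta = c(bb, 0),
      S = vapply(c(bb, 0), function(b) outer_radius_raw(0, b, p), 0),
      phase = phase)
    traj <- dplyr::bind_rows(traj, tail_rows)
    end_state$t <- tend + dt_tail
    end_state$beta <- 0
    end_state$S <- outer_radius_raw(0, 0, p)
    tend <- end_state$t
  }
  snaps <- list()
  if (!is.null(cfg$snapshot_times)) {
    hit <- times_out %in% cfg$snapshot_times
    for (i in which(hit)) {
      st <- unpack_state(unname(out[i, 1 + seq_along(y0)]), times_out[i],
                         phase, p, cfg_run)
      snaps[[length(snaps) + 1L]] <- mg_profiles(st, p, cfg_run)
    }
  }
  if (cfg$verbose) {
    message(sprintf("[mgcorr] %s -> %s at t = %.6g (alpha = %.4g, beta = %.4g, S = %.6g)",
                    phase, event, tend, end_state$alpha, end_state$beta,
                    end_state$S))
  }
  list(state = end_state, event = event, trajectory = traj, snapshots = snaps)
}

#' Advance the corrosion state across a phase transition
#'
#' Applies the boundary-condition switch implied by a terminal event and
#' reseeds/remeshes zones as needed: after CO2 exhaustion at the joint
#' interface the hydroxide layer is seeded at relative thickness
#' `delta_seed` with the pre-transition interface water value; after Mg
#' exhaustion the inner interface is set to zero and the hydroxide zone is
#' remeshed over `(0, beta)` with a no-flux origin; after hydroxide
#' exhaustion the run is `DONE`.
#'
#' @param state State at the event (from [mg_integrate_phase()]).
#' @param event Event label (must match the phase).
#' @param p An [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @return A new `mg_phase_state`.
#' @export
mg_advance_phase <- function(state, event, p, cfg = mg_solver_config()) {
  stopifnot(inherits(state, "mg_phase_state"))
  phase <- state$phase
  n1 <- cfg$n1; n2 <- cfg$n2
  if (phase == "P2_1" && event == "co2_exhausted") {
    fi <- phase_interface("P2_1", NULL, state$W2, state$C2, state$beta,
                          state$beta, p, cfg)
    beta <- state$beta
    alpha <- beta - cfg$delta_seed * p$S0
    if (alpha <= 0) stop("block too small to seed the hydroxide layer",
                         call. = FALSE)
    S_old <- state$S
    S_new <- mg_outer_radius(alpha, beta, p)
    # zone 2 remeshed over (beta, S_new); profiles re-interpolated
    r_old <- seq(beta, S_old, length.out = n2 + 2)
    r_new <- seq(beta, S_new, length.out = n2 + 2)[2:(n2 + 1)]
    W2 <- stats::approx(r_old, c(fi$W_beta, state$W2, 1), xout = r_new,
                        rule = 2)$y
    C2 <- stats::approx(r_old, c(max(fi$C_beta, 0), state$C2, 1),
                        xout = r_new, rule = 2)$y
    W1 <- rep(fi$W_beta, n1)
    return(new_phase_state("P2_2", state$t, alpha, beta, S_new, W1, W2, C2))
  }
  if (phase %in% c("P1_1", "P2_2") && event == "mg_exhausted") {
    fi <- phase_interface(phase, state$W1, state$W2, state$C2, state$alpha,
                          state$beta, p, cfg)
    r_old <- seq(state$alpha, state$beta, length.out = n1 + 2)
    r_new <- seq(0, state$beta, length.out = n1 + 2)[2:(n1 + 1)]
    W1 <- stats::approx(r_old, c(fi$W_alpha, state$W1, fi$W_beta),
                        xout = r_new, rule = 2)$y
    nxt <- if (phase == "P1_1") "P1_2" else "P2_3"
    return(new_phase_state(nxt, state$t, 0, state$beta,
                           mg_outer_radius(0, state$beta, p),
                           W1, state$W2, state$C2))
  }
  if (phase %in% c("P1_2", "P2_3") && event == "hydroxide_exhausted") {
    return(new_phase_state("DONE", state$t, 0, 0, state$S,
                           state$W1, state$W2, state$C2))
  }
  stop("event `", event, "` is inconsistent with phase ", phase,
       call. = FALSE)
}

#' Simulate the full corrosion history of a magnesium block
#'
#' Runs the phase-sequenced moving-boundary corrosion model from a seeded
#' start until the hydroxide layer is exhausted and only magnesium carbonate
#' remains: for finite `kappa` (Case 2) through phases `P2_1` (joint
#' interface, CO2 not yet exhausted), `P2_2` (three zones) and `P2_3` (core
#' gone); for `kappa = Inf` (Case 1) through `P1_1` and `P1_2`. The outer
#' surface is always obtained algebraically from magnesium conservation.
#'
#' @param p An [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @param case Optionally assert the reaction case (1 or 2).
#' @return An object of class `mg_sim` with elements:
#'   * `trajectory`: tibble of `t`, `alpha`, `beta`, `S`, `phase`;
#'   * `T_ab`, `T_alpha`, `T_beta`: transition times (CO2 exhaustion at the
#'     joint interface, Case 2 only; Mg exhaustion; hydroxide exhaustion);
#'   * `S_inf`: a-priori final size; `snapshots`; `params`; `config`; `case`.
#'   Use [tidy()][generics::tidy] / [glance()][generics::glance] /
#'   [ggplot2::autoplot()] on it.
#' @export
#' @examples
#' \donttest{
#' ps <- mg_preset("fig3")
#' cfg <- mg_solver_config(n1 = 40, n2 = 40, rtol = 1e-6, atol = 1e-8)
#' sim <- mg_simulate(ps$params, cfg)
#' glance(sim)
#' }
mg_simulate <- function(p, cfg = mg_solver_config(), case = NULL) {
  stopifnot(inherits(p, "mg_params"), inherits(cfg, "mg_solver_config"))
  state <- mg_initialize(p, cfg, case)
  case_n <- if (is.infinite(p$kappa)) 1L else 2L
  trajs <- list()
  snaps <- list()
  T_ab <- NA_real_; T_alpha <- NA_real_; T_beta <- NA_real_
  while (state$phase != "DONE") {
    step <- mg_integrate_phase(state, p, cfg)
    trajs[[length(trajs) + 1L]] <- step$trajectory
    snaps <- c(snaps, step$snapshots)
    if (step$event == "co2_exhausted") T_ab <- step$state$t
    if (step$event == "mg_exhausted") T_alpha <- step$state$t
    if (step$event == "hydroxide_exhausted") T_beta <- step$state$t
    state <- mg_advance_phase(step$state, step$event, p, cfg)
  }
  traj <- dplyr::bind_rows(trajs)
  structure(list(trajectory = traj, T_ab = T_ab, T_alpha = T_alpha,
                 T_beta = T_beta, S_inf = mg_final_size(p),
                 final_state = state, snapshots = snaps,
                 params = p, config = cfg, case = case_n),
            class = "mg_sim")
}

#' @export
print.mg_sim <- function(x, ...) {
  cat(sprintf("<mg_sim> magnesium corrosion run (Case %d, d = %d)\n",
              x$case, x$params$d))
  if (!is.na(x$T_ab)) cat(sprintf("  T_ab    = %.6g (CO2 exhausted at joint interface)\n", x$T_ab))
  cat(sprintf("  T_alpha = %.6g (Mg core exhausted)\n", x$T_alpha))
  cat(sprintf("  T_beta  = %.6g (Mg(OH)2 layer exhausted)\n", x$T_beta))
  cat(sprintf("  final S = %.6g (a-priori S_inf = %.6g)\n",
              x$final_state$S, x$S_inf))
  invisible(x)
}

#' Concentration profiles of a phase state
#'
#' Reconstructs the full concentration grids of a state, including the
#' boundary values implied by the active boundary conditions, as a tidy
#' table.
#'
#' @param state An `mg_phase_state`.
#' @param p An [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @return A tibble with columns `t`, `phase`, `zone`, `species`
#'   (`"W"` water or `"C"` CO2), `r`, `value`.
#' @export
mg_profiles <- function(state, p, cfg = mg_solver_config()) {
  stopifnot(inherits(state, "mg_phase_state"))
  fi <- phase_interface(state$phase, state$W1, state$W2, state$C2,
                        state$alpha, state$beta, p, cfg)
  r2 <- seq(state$beta, fi$S, length.out = length(state$W2) + 2)
  res <- list(
    tibble::tibble(zone = 2L, species = "W", r = r2,
                   value = c(fi$W_beta, state$W2, 1)),
    tibble::tibble(zone = 2L, species = "C", r = r2,
                   value = c(fi$C_beta, state$C2, 1))
  )
  if (state$phase != "P2_1") {
    r1 <- seq(state$alpha, state$beta, length.out = length(state$W1) + 2)
    res <- c(list(tibble::tibble(zone = 1L, species = "W", r = r1,
                                 value = c(fi$W_alpha, state$W1, fi$W_beta))),
             res)
  }
  out <- dplyr::bind_rows(res)
  out$t <- state$t
  out$phase <- state$phase
  dplyr::relocate(out, "t", "phase")
}

#' Save / load a phase state as JSON
#'
#' Checkpoint and resume support: the full `mg_phase_state` (phase label,
#' time, interfaces and concentration grids) round-trips through a JSON
#' file.
#'
#' @param state An `mg_phase_state`.
#' @param path File path.
#' @return `mg_save_state()` returns `path` invisibly; `mg_load_state()`
#'   returns the state.
#' @export
mg_save_state <- function(state, path) {
  stopifnot(inherits(state, "mg_phase_state"))
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname mg_save_state
#' @export
mg_load_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- if (is.null(x$W1) || length(x$W1) == 0) NULL else as.numeric(x$W1)
  new_phase_state(x$phase, x$t, x$alpha, x$beta, x$S,
                  W1, as.numeric(x$W2), as.numeric(x$C2))
}
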