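# Closed-form consequences of mass conservation.
#
# With ideal 1D geometry (slab/rod/ball, geometry index d) and incompressible
# phases, the solid- and fluid-phase velocity fields in each porous product
# layer are algebraic: every field has the form const / r^d within its zone,
# with the constant fixed by the interface stoichiometry. The outer surface S
# follows algebraically from alpha and beta by conservation of magnesium
# moles, which also yields the final carbonate block size a priori.

# x^d with the convention 0^0 = 1 (Cartesian geometry).
pow_d <- function(x, d) if (d == 0L) rep(1, length(x)) else x^d

#' Solid- and fluid-phase velocity fields
#'
#' Closed-form radial velocity fields in the Mg(OH)2 layer (zone 1, functions
#' `vs1`, `vf1`) and the MgCO3 layer (zone 2, `vs2`, `vf2`), given the
#' interface positions and rates and the corrosion phase. Each field is of
#' the form `const / r^d`. The fields differ by phase:
#'
#' * `"P1_1"`/`"P2_2"` (Mg core present, both layers present): production of
#'   hydroxide at `alpha` and carbonate at `beta` drive both solid fields;
#'   the fluid fields satisfy no-slip `vf1(alpha) = alpha_dot` and fluid-flux
#'   continuity at `beta`.
#' * `"P1_2"`/`"P2_3"` (Mg exhausted): zone-1 velocities vanish.
#' * `"P2_1"` (joint interface, zone 1 absent): Mg converts directly to
#'   carbonate at `beta`; zone-1 fields are undefined (`NULL`).
#'
#' @param alpha,beta Interface positions (0 <= alpha <= beta).
#' @param alpha_dot,beta_dot Interface rates.
#' @param phase One of `"P1_1"`, `"P1_2"`, `"P2_1"`, `"P2_2"`, `"P2_3"`.
#' @param p An [mg_params()] object.
#' @return A list of class `mg_velocity_field` with functions `vs1`, `vf1`
#'   (or `NULL` in `"P2_1"`), `vs2`, `vf2`, each taking a radius vector, and
#'   the `phase` label. Evaluation below the zone's inner bound errors.
#' @export
#' @examples
#' p <- mg_params(kappa = 0.04)
#' vf <- mg_velocity_fields(0.5, 0.7, -0.1, -0.02, "P1_1", p)
#' vf$vf1(0.5)  # no-slip: equals alpha_dot
mg_velocity_fields <- function(alpha, beta, alpha_dot, beta_dot, phase, p) {
  stopifnot(inherits(p, "mg_params"))
  phase <- match.arg(phase, c("P1_1", "P1_2", "P2_1", "P2_2", "P2_3"))
  if (alpha < 0 || beta < alpha) stop("need 0 <= alpha <= beta", call. = FALSE)
  if (phase == "P2_1" && abs(alpha - beta) > 1e-12 * max(1, beta)) {
    stop("phase P2_1 requires alpha == beta", call. = FALSE)
  }
  if (phase %in% c("P1_2", "P2_3") && alpha != 0) {
    stop("phases P1_2/P2_3 require alpha == 0", call. = FALSE)
  }
  d <- p$d; wa <- p$omega_alpha; wb <- p$omega_beta
  e1 <- p$eps1; e2 <- p$eps2
  ad <- pow_d(alpha, d) * alpha_dot
  bd <- pow_d(beta, d) * beta_dot
  guard <- function(lo, nm) {
    force(lo)
    function(r) {
      if (any(r < lo - 1e-12)) {
        stop("velocity field ", nm, " evaluated below its zone's inner bound",
             call. = FALSE)
      }
      r
    }
  }
  g1 <- guard(alpha, "in zone 1"); g2 <- guard(beta, "in zone 2")
  fields <- switch(phase,
    P1_1 = ,
    P2_2 = list(
      vs1 = function(r) -(wa - 1) * ad / pow_d(g1(r), d),
      vf1 = function(r) ad / pow_d(g1(r), d),
      vs2 = function(r) -(wb * (wa - 1) * ad + (wb - 1) * bd) / pow_d(g2(r), d),
      vf2 = function(r) ((1 - e1) * ad - (e2 - e1) * bd) /
        ((1 - e2) * pow_d(g2(r), d))
    ),
    P1_2 = ,
    P2_3 = list(
      vs1 = function(r) 0 * g1(r),
      vf1 = function(r) 0 * g1(r),
      vs2 = function(r) -(wb - 1) * bd / pow_d(g2(r), d),
      vf2 = function(r) -(e2 - e1) * bd / ((1 - e2) * pow_d(g2(r), d))
    ),
    P2_1 = list(
      vs1 = NULL,
      vf1 = NULL,
      vs2 = function(r) -(wa * wb - 1) * bd / pow_d(g2(r), d),
      vf2 = function(r) bd / pow_d(g2(r), d)
    )
  )
  structure(c(fields, list(phase = phase)), class = "mg_velocity_field")
}

#' Outer surface position from magnesium conservation
#'
#' The position `S` of the outer carbonate surface is fixed algebraically by
#' the interface positions: total magnesium moles across the core and the
#' two product layers are conserved, giving
#' `S^(d+1) = omega_alpha*omega_beta*S0^(d+1) - (omega_beta-1)*beta^(d+1)
#'  - omega_beta*(omega_alpha-1)*alpha^(d+1)`.
#' The special configurations `alpha == beta` (joint-interface phase) and
#' `alpha == 0` (core exhausted) are contained in the same formula. `S` grows
#' as the interfaces recede whenever both molar ratios exceed 1.
#'
#' @param alpha,beta Interface positions (0 <= alpha <= beta <= S).
#' @param p An [mg_params()] object.
#' @return The outer radius `S`.
#' @export
#' @examples
#' p <- mg_params()
#' mg_outer_radius(1, 1, p)  # initial state: S = S0
#' mg_outer_radius(0, 0, p)  # all converted: S = final size
mg_outer_radius <- function(alpha, beta, p) {
  stopifnot(inherits(p, "mg_params"))
  if (any(alpha < 0) || any(beta < alpha)) {
    stop("need 0 <= alpha <= beta", call. = FALSE)
  }
  d1 <- p$d + 1
  rad <- p$omega_alpha * p$omega_beta * p$S0^d1 -
    (p$omega_beta - 1) * beta^d1 -
    p$omega_beta * (p$omega_alpha - 1) * alpha^d1
  if (any(rad < 0)) {
    stop("internal inconsistency: negative radicand in outer-radius formula",
         call. = FALSE)
  }
  rad^(1 / d1)
}

#' Final size of the fully corroded block
#'
#' When the Mg core and hydroxide layer are exhausted only MgCO3 remains;
#' its size follows a priori from the total volume gain of the two
#' conversions: `S_inf = S0 * (omega_alpha*omega_beta)^(1/(d+1))`. Larger
#' geometry index shrinks the relative gain, so for the same parameters the
#' slab finishes largest and the ball smallest.
#'
#' @param p An [mg_params()] object.
#' @return The final outer radius `S_inf`.
#' @export
#' @examples
#' mg_final_size(mg_params(d = 1))  # sqrt(1.98)
mg_final_size <- function(p) {
  stopifnot(inherits(p, "mg_params"))
  p$S0 * (p$omega_alpha * p$omega_beta)^(1 / (p$d + 1))
}

#' Global magnesium balance residual
#'
#' Restates magnesium-mole conservation as a runtime invariant: moles in the
#' core plus the hydroxide and carbonate layers must equal the initial core
#' content, i.e.
#' `|wa*wb*alpha^(d+1) + wb*(beta^(d+1)-alpha^(d+1)) + (S^(d+1)-beta^(d+1))
#'  - wa*wb*S0^(d+1)|` is zero in exact arithmetic for every phase. Any
#' state whose `S` came from [mg_outer_radius()] satisfies it to round-off;
#' the simulator checks it along trajectories.
#'
#' @param state An `mg_phase_state` (see [mg_initialize()]) or any list with
#'   fields `alpha`, `beta`, `S`.
#' @param p An [mg_params()] object.
#' @return The absolute residual (dimensionless).
#' @export
mg_balance_residual <- function(state, p) {
  stopifnot(inherits(p, "mg_params"))
  d1 <- p$d + 1
  wa <- p$omega_alpha; wb <- p$omega_beta
  abs(wa * wb * state$alpha^d1 +
        wb * (state$beta^d1 - state$alpha^d1) +
        (state$S^d1 - state$beta^d1) -
        wa * wb * p$S0^d1)
}

# Unvalidated outer radius for solver internals: trial steps of the
# integrator may probe slightly negative alpha before the stop event is
# located, where the conservation formula is still smooth.
outer_radius_raw <- function(alpha, beta, p) {
  d1 <- p$d + 1
  rad <- p$omega_alpha * p$omega_beta * p$S0^d1 -
    (p$omega_beta - 1) * beta^d1 -
    p$omega_beta * (p$omega_alpha - 1) * alpha^d1
  if (any(rad < 0)) {
    stop("internal inconsistency: negative radicand in outer-radius formula",
         call. = FALSE)
  }
  rad^(1 / d1)
}

# Rate of change of S implied by the conservation formula (chain rule).
outer_radius_rate <- function(alpha, beta, alpha_dot, beta_dot, S, p) {
  d <- p$d
  -((p$omega_beta - 1) * pow_d(beta, d) * beta_dot +
      p$omega_beta * (p$omega_alpha - 1) * pow_d(alpha, d) * alpha_dot) /
    pow_d(S, d)
}
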