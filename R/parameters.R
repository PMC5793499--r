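#' Dimensional physical parameters for magnesium corrosion
#'
#' Bundles the dimensional constants of the corrosion system: diffusivities
#' of water and CO2 in the porous product layers, molecular masses and mass
#' densities of Mg, Mg(OH)2 and MgCO3 (densities are those of the deposited
#' layers, inclusive of the void fraction), ambient reactant concentrations,
#' the Mg--water surface reaction rate, and the solid volume fractions of the
#' two product layers. Units are fixed to cm, day and g throughout.
#'
#' Defaults are literature estimates for corrosion of a magnesium pellet in
#' aqueous/physiological media at body-relevant conditions.
#'
#' @param DW_dim Diffusivity of H2O (cm^2/day).
#' @param DC_dim Diffusivity of CO2 (cm^2/day).
#' @param M0,M1,M2 Molecular masses of Mg, Mg(OH)2, MgCO3 (g/mol).
#' @param MW,MC Molecular masses of H2O and CO2 (g/mol).
#' @param rho0,rho1,rho2 Mass densities of the Mg, Mg(OH)2 and MgCO3 layers
#'   (g/cm^3).
#' @param W0_star Ambient water mass concentration (g/cm^3).
#' @param C0_star Ambient CO2 (or bicarbonate-equivalent) mass concentration
#'   (g/cm^3).
#' @param k Mg--water reaction rate constant (cm^4/(g day)); `Inf` selects the
#'   instantaneous-reaction limit (Case 1).
#' @param eps1,eps2 Solid volume fractions of the Mg(OH)2 and MgCO3 layers,
#'   in (0, 1). The Mg core is fully solid.
#' @param S0_star Reference length used for non-dimensionalisation (cm).
#' @param S0_dim Initial pellet size (half-thickness or radius, cm).
#'
#' @return An object of class `mg_physical_params` (a named list).
#' @seealso [mg_nondimensionalize()], [mg_molar_ratios()], [mg_time_unit_hours()]
#' @export
#' @examples
#' phys <- mg_physical_params(k = 0.5)
#' mg_molar_ratios(phys)
mg_physical_params <- function(DW_dim = 2.85, DC_dim = 1.66,
                               M0 = 24.3, M1 = 58.3, M2 = 84.3,
                               MW = 18, MC = 44,
                               rho0 = 1.74, rho1 = 2.34, rho2 = 2.96,
                               W0_star = 1, C0_star = 0.0011,
                               k = Inf, eps1 = 0.6, eps2 = 0.4,
                               S0_star = 1, S0_dim = 1) {
  p <- list(DW_dim = DW_dim, DC_dim = DC_dim, M0 = M0, M1 = M1, M2 = M2,
            MW = MW, MC = MC, rho0 = rho0, rho1 = rho1, rho2 = rho2,
            W0_star = W0_star, C0_star = C0_star, k = k,
            eps1 = eps1, eps2 = eps2, S0_star = S0_star, S0_dim = S0_dim)
  pos <- c("DW_dim", "DC_dim", "M0", "M1", "M2", "MW", "MC",
           "rho0", "rho1", "rho2", "W0_star", "C0_star", "S0_star", "S0_dim")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("`k` must be positive (possibly Inf for an instantaneous reaction)",
         call. = FALSE)
  }
  for (nm in c("eps1", "eps2")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1) {
      stop("`", nm, "` must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  structure(p, class = "mg_physical_params")
}

#' Dimensionless parameters of the corrosion model
#'
#' The constants of the dimensionless advection--diffusion system actually
#' integrated: the water/CO2 diffusivity ratio `DW`, interface mass-flux
#' coefficients `gamma0`, `gamma1`, `gamma2`, the dimensionless surface
#' reaction rate `kappa` (`Inf` selects Case 1), the molar density ratios
#' `omega_alpha` (Mg : Mg(OH)2) and `omega_beta` (Mg(OH)2 : MgCO3), the layer
#' solid fractions, initial size and geometry index.
#'
#' `omega_alpha` and `omega_beta` must exceed 1: each conversion gains
#' volume, which is what drives the outward motion of the outer surface and
#' the monotonicity properties of the solution.
#'
#' @param DW Water/CO2 diffusivity ratio.
#' @param gamma0,gamma1,gamma2 Interface mass-flux coefficients.
#' @param kappa Dimensionless Mg--water reaction rate; `Inf` for Case 1.
#' @param omega_alpha,omega_beta Molar density ratios (> 1).
#' @param eps1,eps2 Solid fractions of zones 1 and 2, in (0, 1).
#' @param S0 Dimensionless initial size.
#' @param d Geometry index: 0 Cartesian (slab), 1 cylindrical (rod),
#'   2 spherical (ball).
#'
#' @return An object of class `mg_params` (a named list).
#' @export
#' @examples
#' p <- mg_params(kappa = 0.04, d = 1)
#' mg_final_size(p)
mg_params <- function(DW = 1.5625, gamma0 = 1.2889, gamma1 = 0.7225,
                      gamma2 = 1605.5, kappa = Inf,
                      omega_alpha = 1.8, omega_beta = 1.1,
                      eps1 = 0.6, eps2 = 0.4, S0 = 1, d = 1) {
  for (nm in c("DW", "gamma0", "gamma1", "gamma2", "S0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0) {
    stop("`kappa` must be positive (possibly Inf)", call. = FALSE)
  }
  if (!is.finite(omega_alpha) || omega_alpha <= 1 ||
      !is.finite(omega_beta) || omega_beta <= 1) {
    stop("`omega_alpha` and `omega_beta` must exceed 1 (volume gain on conversion)",
         call. = FALSE)
  }
  for (nm in c("eps1", "eps2")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop("`", nm, "` must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  if (!d %in% c(0, 1, 2)) stop("`d` must be 0, 1 or 2", call. = FALSE)
  structure(list(DW = DW, gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 kappa = kappa, omega_alpha = omega_alpha,
                 omega_beta = omega_beta, eps1 = eps1, eps2 = eps2,
                 S0 = S0, d = as.integer(d)),
            class = "mg_params")
}

#' @export
print.mg_params <- function(x, ...) {
  geom <- c("Cartesian", "cylindrical", "spherical")[x$d + 1L]
  cat("<mg_params> dimensionless magnesium corrosion parameters\n")
  cat(sprintf("  geometry d = %d (%s), S0 = %g\n", x$d, geom, x$S0))
  cat(sprintf("  kappa = %s (%s)\n",
              format(x$kappa),
              if (is.infinite(x$kappa)) "Case 1, instantaneous reaction"
              else "Case 2, finite rate"))
  cat(sprintf("  DW = %g, gamma0 = %g, gamma1 = %g, gamma2 = %g\n",
              x$DW, x$gamma0, x$gamma1, x$gamma2))
  cat(sprintf("  omega_alpha = %g, omega_beta = %g, eps1 = %g, eps2 = %g\n",
              x$omega_alpha, x$omega_beta, x$eps1, x$eps2))
  invisible(x)
}

#' @export
print.mg_physical_params <- function(x, ...) {
  cat("<mg_physical_params> dimensional magnesium corrosion parameters (cm/g/day)\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Molar density ratios of the corrosion conversions
#'
#' The volume-expansion factors of the two conversions: `omega_alpha` is the
#' molar density of Mg over that of Mg(OH)2 and `omega_beta` that of Mg(OH)2
#' over MgCO3, with molar density rho_i / M_i of each deposited layer. Values
#' above 1 mean the product layer occupies more volume than the reactant it
#' replaces, pushing the outer surface outward.
#'
#' @param phys An [mg_physical_params()] object.
#' @return A tibble with columns `omega_alpha` and `omega_beta`.
#' @export
#' @examples
#' mg_molar_ratios(mg_physical_params())  # ~1.78 and ~1.14
mg_molar_ratios <- function(phys) {
  stopifnot(inherits(phys, "mg_physical_params"))
  mu0 <- phys$rho0 / phys$M0
  mu1 <- phys$rho1 / phys$M1
  mu2 <- phys$rho2 / phys$M2
  tibble::tibble(omega_alpha = mu0 / mu1, omega_beta = mu1 / mu2)
}

#' Non-dimensionalise physical corrosion parameters
#'
#' Rescales lengths by the reference size `S0_star`, time by the CO2
#' diffusion timescale `S0_star^2 / DC`, and concentrations by their ambient
#' values, producing the dimensionless parameter set that the solver
#' integrates:
#' `DW = DW_dim/DC_dim`, `gamma0 = MW rho0/(M0 W0*)`,
#' `gamma1 = MW rho1/(M1 W0*)`, `gamma2 = MC rho1/(M1 C0*)`,
#' `kappa = S0* W0* k / DC_dim` (infinite `k` maps to infinite `kappa`),
#' and `S0 = S0_dim/S0_star`. The molar ratios come from
#' [mg_molar_ratios()].
#'
#' @param phys An [mg_physical_params()] object.
#' @param d Geometry index (0, 1 or 2).
#' @return An [mg_params()] object.
#' @export
#' @examples
#' mg_nondimensionalize(mg_physical_params(k = 0.0664), d = 1)
mg_nondimensionalize <- function(phys, d = 1) {
  stopifnot(inherits(phys, "mg_physical_params"))
  om <- mg_molar_ratios(phys)
  mg_params(
    DW = phys$DW_dim / phys$DC_dim,
    gamma0 = phys$MW * phys$rho0 / (phys$M0 * phys$W0_star),
    gamma1 = phys$MW * phys$rho1 / (phys$M1 * phys$W0_star),
    gamma2 = phys$MC * phys$rho1 / (phys$M1 * phys$C0_star),
    kappa = phys$S0_star * phys$W0_star * phys$k / phys$DC_dim,
    omega_alpha = om$omega_alpha, omega_beta = om$omega_beta,
    eps1 = phys$eps1, eps2 = phys$eps2,
    S0 = phys$S0_dim / phys$S0_star, d = d
  )
}

#' Hours represented by one dimensionless time unit
#'
#' Time is scaled by the CO2 diffusion timescale over the reference length,
#' `S0_star^2 / DC`; in hours this is `24 * S0_star^2 / DC_dim`. For the
#' default parameters one dimensionless time unit is about 14.5 h.
#'
#' @param phys An [mg_physical_params()] object.
#' @return Hours per dimensionless time unit (a single number).
#' @export
#' @examples
#' mg_time_unit_hours(mg_physical_params())  # ~14.46
mg_time_unit_hours <- function(phys) {
  stopifnot(inherits(phys, "mg_physical_params"))
  24 * phys$S0_star^2 / phys$DC_dim
}

#' Named parameter presets for the package's worked examples
#'
#' Returns the dimensionless parameter set and solver defaults used by the
#' package's standard worked examples. All presets share the tabulated
#' dimensionless constants (including the tabulated `DW = 1.5625`; computing
#' the ratio of the tabulated dimensional diffusivities instead gives
#' 2.85/1.66 = 1.717 -- both paths are supported, see
#' [mg_nondimensionalize()]) and differ in reaction rate, geometry and role:
#'
#' * `"fig2"`, `"fig3"`: cylindrical finite-rate run, `kappa = 0.04`,
#'   `eps1 = 0.6`, `eps2 = 0.4`, `S0 = 1` (interface trajectories and
#'   concentration snapshots).
#' * `"fig4"`: instantaneous reaction (Case 1, `kappa = Inf`), same solid
#'   fractions; geometry selectable via `d`.
#' * `"fig5"`: finite rate `kappa = 0.3` (k = 0.5 cm^4/(g day)), used for
#'   initial-size sweeps.
#' * `"fig6"`: solid-fraction sweeps at `kappa` in {0.3, 6, Inf}.
#' * `"fig7"`: spherical contour study over (kappa, eps).
#' * `"fig8"`: kappa sweep across geometries.
#' * `"fig9"`: advection-mode comparison, cylindrical, `kappa = 0.04`.
#'
#' @param name Preset name (see above).
#' @param d Optional geometry override (0, 1 or 2).
#' @return A list with elements `params` ([mg_params()]) and
#'   `config` ([mg_solver_config()]).
#' @export
#' @examples
#' ps <- mg_preset("fig3")
#' ps$params
mg_preset <- function(name, d = NULL) {
  # Finite-rate presets carry the unrounded kappa = k/DC implied by the
  # quoted dimensional rates (k = 0.07 and 0.5 cm^4/(g day), DC = 1.66
  # cm^2/day); the rounded "0.04"/"0.3" labels are their 1-s.f. displays.
  presets <- list(
    fig2 = list(kappa = 0.07 / 1.66, d = 1),
    fig3 = list(kappa = 0.07 / 1.66, d = 1),
    fig4 = list(kappa = Inf, d = 1),
    fig5 = list(kappa = 0.5 / 1.66, d = 1),
    fig6 = list(kappa = 0.3, d = 1),
    fig7 = list(kappa = 0.3, d = 2),
    fig8 = list(kappa = 0.3, d = 1),
    fig9 = list(kappa = 0.07 / 1.66, d = 1)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown preset; valid presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  ps <- presets[[name]]
  if (!is.null(d)) ps$d <- d
  list(
    params = mg_params(DW = 1.5625, gamma0 = 1.2889, gamma1 = 0.7225,
                       gamma2 = 1605.5, kappa = ps$kappa,
                       omega_alpha = 1.8, omega_beta = 1.1,
                       eps1 = 0.6, eps2 = 0.4, S0 = 1, d = ps$d),
    config = mg_solver_config()
  )
}
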