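#' Parameter sweep over degradation timescales
#'
#' Re-runs [mg_simulate()] over a grid of one parameter (`"S0"`, `"eps1"`,
#' `"eps2"`, `"kappa"` or `"d"`) and tabulates the degradation timescales.
#' `kappa = Inf` entries switch the run to the instantaneous-reaction Case 1.
#' Individual run failures are recorded as `NA` rows with a warning, not
#' fatal to the sweep.
#'
#' @param parameter One of `"S0"`, `"eps1"`, `"eps2"`, `"kappa"`, `"d"`.
#' @param values Grid of values to sweep.
#' @param p Base [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @return A tibble of class `mg_sweep` with columns `parameter`, `value`,
#'   `T_ab`, `T_alpha`, `T_beta`, `S_inf`.
#' @export
#' @examples
#' \donttest{
#' ps <- mg_preset("fig5")
#' cfg <- mg_solver_config(n1 = 30, n2 = 30, rtol = 1e-6, atol = 1e-8)
#' mg_sweep("S0", c(0.5, 1), ps$params, cfg)
#' }
mg_sweep <- function(parameter, values, p, cfg = mg_solver_config()) {
  parameter <- match.arg(parameter, c("S0", "eps1", "eps2", "kappa", "d"))
  stopifnot(inherits(p, "mg_params"), length(values) >= 1)
  rows <- purrr::map(values, function(v) {
    pv <- unclass(p)
    pv[[parameter]] <- v
    pi <- do.call(mg_params, pv)
    tryCatch({
      sim <- mg_simulate(pi, cfg)
      tibble::tibble(parameter = parameter, value = v, T_ab = sim$T_ab,
                     T_alpha = sim$T_alpha, T_beta = sim$T_beta,
                     S_inf = sim$S_inf)
    }, error = function(e) {
      warning("sweep run at ", parameter, " = ", v, " failed: ",
              conditionMessage(e), call. = FALSE)
      tibble::tibble(parameter = parameter, value = v, T_ab = NA_real_,
                     T_alpha = NA_real_, T_beta = NA_real_, S_inf = NA_real_)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mg_sweep", class(out))
  out
}

#' Fitted power-law exponent
#'
#' Ordinary least-squares slope of `log(T)` against `log(x)`: the exponent
#' `p` of a power law `T = c * x^p`. Used to check the quadratic scaling of
#' the hydroxide-exhaustion time with initial block size and its `1/(1-eps2)`
#' porosity scaling.
#'
#' @param x Positive predictor values (at least 3).
#' @param T_values Positive timescales, same length.
#' @return The fitted exponent (a single number).
#' @export
#' @examples
#' mg_scaling_exponent(c(1, 2, 4), 3 * c(1, 2, 4)^2)  # exactly 2
mg_scaling_exponent <- function(x, T_values) {
  if (length(x) < 3 || length(T_values) != length(x)) {
    stop("need at least 3 matched points", call. = FALSE)
  }
  if (any(x <= 0) || any(T_values <= 0)) {
    stop("power-law fit requires positive values", call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(T_values) ~ log(x)))[2])
}

#' Compare the three advective-transport assumptions
#'
#' Runs an identical configuration under the three choices of advective
#' reactant velocity: the porous-media fluid velocity (the native model),
#' zero advection, and the solid-phase velocity (reactants dragged with the
#' crystal structure). Because the reactions gain volume, the fluid drift is
#' inward (towards the reaction sites) and the solid drift outward, so the
#' Mg core degrades fastest under fluid advection and slowest under solid
#' advection; the final size is identical by conservation.
#'
#' @param p An [mg_params()] object.
#' @param cfg An [mg_solver_config()]; its `advection_mode` is ignored.
#' @return A named list of `mg_sim` objects: `fluid`, `none`, `solid`.
#' @export
mg_compare_advection <- function(p, cfg = mg_solver_config()) {
  stopifnot(inherits(p, "mg_params"))
  modes <- c("fluid", "none", "solid")
  out <- purrr::map(modes, function(m) {
    cfg_m <- cfg
    cfg_m$advection_mode <- m
    mg_simulate(p, cfg_m)
  })
  stats::setNames(out, modes)
}

#' Gridded Mg-exhaustion times over (kappa, eps) pairs
#'
#' Computes `T_alpha` on a rectangular grid of reaction rate and one solid
#' fraction, the raw material for a contour map of core longevity.
#'
#' @param kappa_values Positive reaction-rate grid.
#' @param eps_values Solid-fraction grid in (0, 1).
#' @param which_eps `"eps1"` (vary the hydroxide fraction) or `"eps2"`.
#' @param p Base [mg_params()] object.
#' @param cfg An [mg_solver_config()].
#' @return A tibble with columns `kappa`, `eps`, `T_alpha`.
#' @export
mg_contour_grid <- function(kappa_values, eps_values,
                            which_eps = c("eps1", "eps2"),
                            p, cfg = mg_solver_config()) {
  which_eps <- match.arg(which_eps)
  grid <- expand.grid(kappa = kappa_values, eps = eps_values)
  rows <- purrr::pmap(grid, function(kappa, eps) {
    pv <- unclass(p)
    pv$kappa <- kappa
    pv[[which_eps]] <- eps
    pi <- do.call(mg_params, pv)
    Ta <- tryCatch(mg_simulate(pi, cfg)$T_alpha, error = function(e) NA_real_)
    tibble::tibble(kappa = kappa, eps = eps, T_alpha = Ta)
  })
  dplyr::bind_rows(rows)
}
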