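#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a corrosion simulation
#'
#' Returns the interface trajectory as a tibble with one row per stored time
#' point: columns `t`, `alpha` (Mg/Mg(OH)2 interface), `beta`
#' (Mg(OH)2/MgCO3 interface), `S` (outer surface) and `phase`.
#'
#' @param x An `mg_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mg_sim
#' @export
tidy.mg_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a corrosion simulation
#'
#' @param x An `mg_sim` object.
#' @param ... Unused.
#' @return A one-row tibble with the case, geometry, reaction rate, the
#'   three transition times, the final computed outer radius and the
#'   a-priori final size.
#' @method glance mg_sim
#' @export
glance.mg_sim <- function(x, ...) {
  tibble::tibble(case = x$case, d = x$params$d, kappa = x$params$kappa,
                 eps1 = x$params$eps1, eps2 = x$params$eps2,
                 S0 = x$params$S0,
                 T_ab = x$T_ab, T_alpha = x$T_alpha, T_beta = x$T_beta,
                 S_final = x$final_state$S, S_inf = x$S_inf)
}

#' Plot the interface trajectories of a corrosion run
#'
#' Interface positions `alpha`, `beta` and outer surface `S` against time
#' (log-scaled), with the transition times marked.
#'
#' @param object An `mg_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mg_sim
#' @export
autoplot.mg_sim <- function(object, ...) {
  traj <- tidyr_longer(object$trajectory)
  pl <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data$value,
                                           colour = .data$interface)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t (dimensionless)", y = "position",
                  colour = NULL,
                  title = sprintf("Mg corrosion, Case %d, d = %d",
                                  object$case, object$params$d)) +
    ggplot2::theme_minimal()
  tt <- c(object$T_ab, object$T_alpha, object$T_beta)
  tt <- tt[!is.na(tt)]
  if (length(tt)) {
    pl <- pl + ggplot2::geom_vline(xintercept = tt, linetype = "dashed",
                                   colour = "grey50")
  }
  pl
}

# base pivot to avoid a hard tidyr dependency in plotting
tidyr_longer <- function(traj) {
  dplyr::bind_rows(
    tibble::tibble(t = traj$t, interface = "alpha", value = traj$alpha),
    tibble::tibble(t = traj$t, interface = "beta", value = traj$beta),
    tibble::tibble(t = traj$t, interface = "S", value = traj$S)
  )
}

#' Plot degradation timescales from a parameter sweep
#'
#' @param object An `mg_sweep` tibble (from [mg_sweep()]).
#' @param ... Unused.
#' @return A ggplot of `T_alpha` and `T_beta` against the swept value on
#'   log-log axes.
#' @method autoplot mg_sweep
#' @export
autoplot.mg_sweep <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = object$value, time = object$T_alpha,
                   which = "T_alpha"),
    tibble::tibble(value = object$value, time = object$T_beta,
                   which = "T_beta")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$time,
                                   colour = .data$which)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$parameter[1], y = "degradation time",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot concentration snapshots
#'
#' @param profiles A profiles tibble from [mg_profiles()] (rows from several
#'   times may be bound together).
#' @return A ggplot of water and CO2 concentration against radius, faceted
#'   by species, one line per time.
#' @export
mg_plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$r, y = .data$value,
                               colour = factor(.data$t),
                               linetype = factor(.data$zone))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "r", y = "concentration", colour = "t",
                  linetype = "zone") +
    ggplot2::theme_minimal()
}
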