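# Shared simulation runs, computed lazily and cached for the whole test
# session. Problem sizes are chosen so the full suite stays fast while the
# headline runs remain mesh-converged (see the methods vignette).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

fig3_run <- function(n) {
  key <- paste0("fig3_", n)
  cached(key, {
    ps <- mg_preset("fig3")
    cfg <- mg_solver_config(n1 = n, n2 = n,
                            snapshot_times = if (n == 50) c(1, 100) else NULL)
    mg_simulate(ps$params, cfg)
  })
}

fig4_run <- function(n = 100, d = 1) {
  key <- paste0("fig4_", n, "_", d)
  cached(key, {
    ps <- mg_preset("fig4", d = d)
    mg_simulate(ps$params, mg_solver_config(n1 = n, n2 = n))
  })
}

kappa_run <- function(kappa, n = 40) {
  key <- paste0("kap_", format(kappa), "_", n)
  cached(key, {
    p <- mg_params(kappa = kappa, d = 1)
    mg_simulate(p, mg_solver_config(n1 = n, n2 = n))
  })
}

advection_runs <- function(n = 50) {
  cached(paste0("adv_", n), {
    ps <- mg_preset("fig9")
    mg_compare_advection(ps$params, mg_solver_config(n1 = n, n2 = n))
  })
}

s0_sweep <- function(n = 40) {
  cached(paste0("s0sweep_", n), {
    ps <- mg_preset("fig5")
    mg_sweep("S0", c(0.5, 1, 2, 4), ps$params,
             mg_solver_config(n1 = n, n2 = n))
  })
}

eps2_sweep <- function(n = 40) {
  cached(paste0("eps2sweep_", n), {
    ps <- mg_preset("fig6")
    mg_sweep("eps2", seq(0.2, 0.8, by = 0.1), ps$params,
             mg_solver_config(n1 = n, n2 = n))
  })
}

seed_variant_run <- function(tau0 = 1e-8, delta_seed = 1e-5, n = 50) {
  key <- paste0("seedvar_", format(tau0), "_", format(delta_seed), "_", n)
  cached(key, {
    ps <- mg_preset("fig3")
    mg_simulate(ps$params,
                mg_solver_config(n1 = n, n2 = n, tau0 = tau0,
                                 delta_seed = delta_seed))
  })
}
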