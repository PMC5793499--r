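# Configuration files, result serialisation and the command-line interface.
#
# A run configuration supplies the parameters exactly one of three ways --
# a "physical" block (dimensional, cm/g/day), a "dimensionless" block, or a
# "preset" name -- plus optional geometry, case, solver and outputs blocks.
# Outputs are plain CSV/JSON: 1D trajectories are small and diffable.

#' Read and validate a run configuration
#'
#' Reads a YAML or JSON configuration with exactly one of the blocks
#' `physical` (dimensional parameters, fields of [mg_physical_params()]),
#' `dimensionless` (fields of [mg_params()]) or `preset` (a name known to
#' [mg_preset()]), plus optional `geometry` (d), `initial_size`, `case`
#' (1 or 2), `solver` ([mg_solver_config()] fields) and `outputs`
#' (`directory`, `snapshot_times`). Unknown keys are rejected with a
#' field-level message; all fields are validated before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `mg_run_config` with elements `params`
#'   ([mg_params()]), `physical` (the dimensional set, or `NULL`), `config`
#'   ([mg_solver_config()]), `case` and `outputs`.
#' @export
mg_read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON, got extension `.", ext, "`",
         call. = FALSE)
  }
  known <- c("physical", "dimensionless", "preset", "geometry",
             "initial_size", "case", "solver", "outputs")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  src <- intersect(c("physical", "dimensionless", "preset"), names(raw))
  if (length(src) != 1L) {
    stop("config must contain exactly one of `physical`, `dimensionless` ",
         "or `preset`", call. = FALSE)
  }
  d <- raw$geometry
  physical <- NULL
  if (src == "preset") {
    ps <- mg_preset(raw$preset, d = d)
    params <- ps$params
    cfg <- ps$config
  } else if (src == "physical") {
    check_fields(raw$physical, names(formals(mg_physical_params)), "physical")
    physical <- do.call(mg_physical_params, raw$physical)
    params <- mg_nondimensionalize(physical, d = if (is.null(d)) 1 else d)
    cfg <- mg_solver_config()
  } else {
    check_fields(raw$dimensionless, names(formals(mg_params)), "dimensionless")
    args <- raw$dimensionless
    if (!is.null(args$kappa) && identical(args$kappa, "Inf")) {
      args$kappa <- Inf
    }
    if (!is.null(d)) args$d <- d
    params <- do.call(mg_params, args)
    cfg <- mg_solver_config()
  }
  if (src != "preset" && !is.null(d) && params$d != d) {
    params$d <- as.integer(d)
  }
  if (!is.null(raw$initial_size)) {
    pv <- unclass(params)
    pv$S0 <- raw$initial_size
    params <- do.call(mg_params, pv)
  }
  if (!is.null(raw$solver)) {
    check_fields(raw$solver, names(formals(mg_solver_config)), "solver")
    cfg_args <- utils::modifyList(
      lapply(unclass(cfg), identity)[setdiff(names(unclass(cfg)), character())],
      raw$solver)
    cfg <- do.call(mg_solver_config, cfg_args)
  }
  case <- raw$case
  if (!is.null(case)) {
    if (!case %in% c(1, 2)) stop("`case` must be 1 or 2", call. = FALSE)
    if (case == 1 && is.finite(params$kappa)) {
      stop("case 1 requires an infinite kappa/k", call. = FALSE)
    }
    if (case == 2 && is.infinite(params$kappa)) {
      stop("case 2 requires a finite kappa/k", call. = FALSE)
    }
  }
  outputs <- raw$outputs
  if (!is.null(outputs)) {
    check_fields(outputs, c("directory", "snapshot_times"), "outputs")
    if (!is.null(outputs$snapshot_times)) {
      cfg$snapshot_times <- as.numeric(outputs$snapshot_times)
    }
  }
  structure(list(params = params, physical = physical, config = cfg,
                 case = case, outputs = outputs),
            class = "mg_run_config")
}

check_fields <- function(block, allowed, label) {
  if (is.null(block) || !length(names(block))) {
    stop("`", label, "` block must be a named mapping", call. = FALSE)
  }
  bad <- setdiff(names(block), allowed)
  if (length(bad)) {
    stop("unknown `", label, "` field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write simulation results to disk
#'
#' Writes the interface trajectory as CSV (columns `t`, `alpha`, `beta`,
#' `S`, `phase`, plus `t_hours` when dimensional parameters are available),
#' the transition times and sizes as JSON, and any concentration snapshots
#' as one CSV each (columns `t`, `phase`, `zone`, `species`, `r`, `value`).
#' Numeric fields are written with full double precision (at least 10
#' significant digits) in a deterministic field order.
#'
#' @param sim An `mg_sim` object.
#' @param dir Output directory (created if needed).
#' @param phys Optional [mg_physical_params()] for dimensional time columns.
#' @return Invisibly, the paths written.
#' @export
mg_write_result <- function(sim, dir, phys = NULL) {
  stopifnot(inherits(sim, "mg_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  traj <- sim$trajectory
  hours <- if (!is.null(phys)) mg_time_unit_hours(phys) else NA_real_
  if (!is.na(hours)) traj$t_hours <- traj$t * hours
  traj_path <- file.path(dir, "trajectory.csv")
  write_csv_precise(traj, traj_path)
  times <- list(T_ab = sim$T_ab, T_alpha = sim$T_alpha, T_beta = sim$T_beta,
                S_final = sim$final_state$S, S_inf = sim$S_inf,
                case = sim$case, d = sim$params$d)
  if (!is.na(hours)) times$time_unit_hours <- hours
  times_path <- file.path(dir, "times.json")
  jsonlite::write_json(times, times_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(traj_path, times_path)
  if (length(sim$snapshots)) {
    for (i in seq_along(sim$snapshots)) {
      sp <- file.path(dir, sprintf("snapshot_%02d.csv", i))
      write_csv_precise(sim$snapshots[[i]], sp)
      paths <- c(paths, sp)
    }
  }
  invisible(paths)
}

# CSV writer keeping >= 10 significant digits on numeric columns.
write_csv_precise <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 12, format = "g") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
}

cli_usage <- function() {
  paste(
    "mgcorr -- moving-boundary magnesium corrosion simulator",
    "",
    "usage: mgcorr <command> [options]",
    "",
    "commands:",
    "  run                single simulation (--config or --preset)",
    "  sweep              parameter study (--param, --values, --preset/--config)",
    "  compare-advection  run fluid/none/solid advection variants",
    "  reproduce <name>   run a named figure preset end-to-end (fig2..fig9)",
    "",
    "options:",
    "  --config PATH   YAML/JSON run configuration",
    "  --preset NAME   named preset (fig2, fig3, fig4, fig5, fig9, ...)",
    "  --out DIR       output directory (default: mgcorr-out)",
    "  --param NAME    sweep parameter (S0, eps1, eps2, kappa, d)",
    "  --values CSV    comma-separated sweep values (Inf allowed)",
    "  --nodes N       override mesh nodes per zone",
    "  --verbose       log solver progress",
    sep = "\n")
}

cli_parse <- function(args) {
  out <- list(flags = list(), positional = character())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      if (grepl("=", a)) {
        kv <- sub("^--", "", a)
        key <- sub("=.*$", "", kv)
        out$flags[[key]] <- sub("^[^=]*=", "", kv)
      } else {
        key <- sub("^--", "", a)
        if (key == "verbose") {
          out$flags[[key]] <- TRUE
        } else {
          if (i == length(args)) stop("flag --", key, " needs a value",
                                      call. = FALSE)
          i <- i + 1
          out$flags[[key]] <- args[i]
        }
      }
    } else {
      out$positional <- c(out$positional, a)
    }
    i <- i + 1
  }
  out
}

cli_load <- function(flags) {
  if (!is.null(flags$config)) {
    rc <- mg_read_config(flags$config)
  } else if (!is.null(flags$preset)) {
    ps <- mg_preset(flags$preset)
    rc <- list(params = ps$params, physical = NULL, config = ps$config,
               case = NULL, outputs = NULL)
  } else {
    stop("provide --config or --preset", call. = FALSE)
  }
  if (!is.null(flags$nodes)) {
    n <- as.integer(flags$nodes)
    rc$config$n1 <- n
    rc$config$n2 <- n
  }
  if (isTRUE(flags$verbose)) rc$config$verbose <- TRUE
  rc
}

#' Command-line entry point
#'
#' Implements the `mgcorr` command-line tool (see
#' `system.file("cli", "mgcorr", package = "mgcorr")`): subcommands `run`,
#' `sweep`, `compare-advection` and `reproduce`, all thin wrappers over
#' [mg_simulate()], [mg_sweep()], [mg_compare_advection()] and the presets.
#' Outputs are deterministic CSV/JSON files; re-running a command with the
#' same configuration byte-reproduces them.
#'
#' @param args Character vector of command-line arguments.
#' @return Process exit status, invisibly: 0 on success, non-zero on error.
#' @export
mg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    pa <- cli_parse(args)
    cmd <- if (length(pa$positional)) pa$positional[1] else ""
    outdir <- if (!is.null(pa$flags$out)) pa$flags$out else "mgcorr-out"
    if (cmd == "run") {
      rc <- cli_load(pa$flags)
      sim <- mg_simulate(rc$params, rc$config, case = rc$case)
      dir_out <- if (!is.null(rc$outputs$directory)) rc$outputs$directory
                 else outdir
      mg_write_result(sim, dir_out, rc$physical)
      message("wrote trajectory and times to ", dir_out)
      0L
    } else if (cmd == "sweep") {
      rc <- cli_load(pa$flags)
      if (is.null(pa$flags$param) || is.null(pa$flags$values)) {
        stop("sweep needs --param and --values", call. = FALSE)
      }
      vals <- as.numeric(strsplit(pa$flags$values, ",")[[1]])
      sw <- mg_sweep(pa$flags$param, vals, rc$params, rc$config)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_csv_precise(sw, file.path(outdir, "sweep.csv"))
      message("wrote sweep table to ", outdir)
      0L
    } else if (cmd == "compare-advection") {
      rc <- cli_load(pa$flags)
      sims <- mg_compare_advection(rc$params, rc$config)
      for (m in names(sims)) {
        mg_write_result(sims[[m]], file.path(outdir, m), rc$physical)
      }
      message("wrote advection comparison to ", outdir)
      0L
    } else if (cmd == "reproduce") {
      if (length(pa$positional) < 2) stop("reproduce needs a preset name",
                                          call. = FALSE)
      cli_reproduce(pa$positional[2], outdir, pa$flags)
      0L
    } else {
      cat(cli_usage(), "\n")
      if (cmd == "") 0L else 1L
    }
  }, error = function(e) {
    message("mgcorr error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_reproduce <- function(name, outdir, flags = list()) {
  ps <- mg_preset(name)
  cfg <- ps$config
  if (!is.null(flags$nodes)) {
    cfg$n1 <- cfg$n2 <- as.integer(flags$nodes)
  }
  if (isTRUE(flags$verbose)) cfg$verbose <- TRUE
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (name %in% c("fig2", "fig3", "fig4")) {
    sim <- mg_simulate(ps$params, cfg)
    mg_write_result(sim, outdir)
  } else if (name == "fig5") {
    sw <- mg_sweep("S0", c(0.5, 1, 2, 4), ps$params, cfg)
    write_csv_precise(sw, file.path(outdir, "sweep_S0.csv"))
    expo <- mg_scaling_exponent(sw$value, sw$T_beta)
    jsonlite::write_json(list(parameter = "S0", exponent_T_beta = expo),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (name == "fig6") {
    sw1 <- mg_sweep("eps1", seq(0.2, 0.8, by = 0.1), ps$params, cfg)
    sw2 <- mg_sweep("eps2", seq(0.2, 0.8, by = 0.1), ps$params, cfg)
    write_csv_precise(dplyr::bind_rows(sw1, sw2), file.path(outdir, "sweep_eps.csv"))
  } else if (name == "fig7") {
    gr <- mg_contour_grid(c(0.1, 0.3, 1, 3), c(0.3, 0.5, 0.7), "eps1",
                          ps$params, cfg)
    write_csv_precise(gr, file.path(outdir, "contour_T_alpha.csv"))
  } else if (name == "fig8") {
    sw <- mg_sweep("kappa", c(0.1, 0.3, 1, 3, 10, Inf), ps$params, cfg)
    write_csv_precise(sw, file.path(outdir, "sweep_kappa.csv"))
  } else if (name == "fig9") {
    sims <- mg_compare_advection(ps$params, cfg)
    for (m in names(sims)) mg_write_result(sims[[m]], file.path(outdir, m))
    gl <- dplyr::bind_rows(lapply(sims, glance), .id = "mode")
    write_csv_precise(gl, file.path(outdir, "summary.csv"))
  } else {
    stop("no reproduce recipe for preset ", name, call. = FALSE)
  }
  message("wrote ", name, " outputs to ", outdir)
  invisible(outdir)
}
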