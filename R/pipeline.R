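#' Pipeline configuration
#'
#' Single configuration object driving the full chain (environment ->
#' bubble -> transport -> ensemble). Physical defaults follow the study
#' inputs: a 4.5 mm initial bubble of pure methane, surface-exchange
#' constants `a = 6.97e-7 s/m` and `Sc = 677`, 1 m cells, 0.01 day steps,
#' a 36-member annual ensemble and the 1e-7 depletion stop criterion.
#'
#' @param station_depth sea-floor depth, m.
#' @param d0 initial bubble equivalent diameter, m.
#' @param halflife_days biodegradation half-life (scalar) or sweep grid, days.
#' @param release_day day of year of the single-run release.
#' @param n_starts ensemble members per year.
#' @param stop_fraction depletion stop criterion (fraction of released).
#' @param dz cell thickness, m.
#' @param dt transport time step, days.
#' @param a,Sc surface-exchange constants ([kw_from_wind()]).
#' @param seed integer seed (wind series and any other randomness).
#' @param scenario named list of [scenario_config()] overrides.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(station_depth = 65, d0 = 4.5e-3,
                            halflife_days = 50, release_day = 15,
                            n_starts = 36, stop_fraction = 1e-7,
                            dz = 1, dt = 0.01, a = 6.97e-7, Sc = 677,
                            seed = 1, scenario = list()) {
  cfg <- as.list(environment())
  validate_config(cfg)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, enforces physical ranges, and rejects unknown keys. Each
#' violation is itemized with the offending key.
#'
#' @param config a named list of configuration entries.
#' @return normalized `pipeline_config`, or an error listing all violations.
#' @export
validate_config <- function(config) {
  defaults <- list(station_depth = NULL, d0 = 4.5e-3, halflife_days = 50,
                   release_day = 15, n_starts = 36, stop_fraction = 1e-7,
                   dz = 1, dt = 0.01, a = 6.97e-7, Sc = 677, seed = 1,
                   scenario = list())
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config[setdiff(names(config), unknown)],
                    keep.null = TRUE)
  if (is.null(cfg$station_depth))
    errors <- c(errors, "missing required key: station_depth")
  else if (!is.numeric(cfg$station_depth) || cfg$station_depth <= 0)
    errors <- c(errors, "station_depth must be a positive number")
  if (!is.numeric(cfg$d0) || cfg$d0 <= 0 || cfg$d0 > 0.05)
    errors <- c(errors, "d0 must be in (0, 0.05] m")
  if (!is.numeric(cfg$halflife_days) || any(cfg$halflife_days <= 0))
    errors <- c(errors, "halflife_days must be positive")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0)
    errors <- c(errors, "dt must be positive")
  if (!is.numeric(cfg$dz) || cfg$dz <= 0)
    errors <- c(errors, "dz must be positive")
  if (!is.numeric(cfg$n_starts) || cfg$n_starts < 1)
    errors <- c(errors, "n_starts must be >= 1")
  if (!is.numeric(cfg$stop_fraction) || cfg$stop_fraction <= 0 || cfg$stop_fraction >= 1)
    errors <- c(errors, "stop_fraction must be in (0, 1)")
  if (!is.numeric(cfg$a) || cfg$a <= 0) errors <- c(errors, "a must be positive")
  if (!is.numeric(cfg$Sc) || cfg$Sc <= 0) errors <- c(errors, "Sc must be positive")
  if (!is.list(cfg$scenario))
    errors <- c(errors, "scenario must be a list of scenario_config overrides")
  else {
    bad <- setdiff(names(cfg$scenario), names(formals(scenario_config)))
    if (length(bad))
      errors <- c(errors, paste0("unknown scenario key(s): ", paste(bad, collapse = ", ")))
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param file YAML path.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  validate_config(yaml::read_yaml(file))
}

#' Run the full fate pipeline
#'
#' Orchestrates the chain: synthetic environment, single-bubble run at the
#' release day (deposition profile), single depletion run, annual ensemble
#' (or half-life sweep when `halflife_days` is a vector), and the
#' ventilation-rate diagnostic. Writes all outputs as CSV to `out_dir`
#' together with a provenance record (config, its MD5 hash, seed, package
#' version). Idempotent for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` skips file output.
#' @param quiet suppress progress messages.
#' @return list with `scenario`, `bubble`, `balance`, `fate` (ensemble or
#'   sweep results), `ventilation`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- validate_config(unclass(config))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage environment: building synthetic scenario")
  scen_cfg <- do.call(scenario_config, config$scenario)
  scenario <- stage("environment",
    make_scenario(config$station_depth, scen_cfg, seed = config$seed,
                  dz = config$dz))

  say("stage bubble: integrating single bubble")
  bubble <- stage("bubble",
    integrate_bubble(config$station_depth, d0 = config$d0, profile = scenario,
                     day = config$release_day, dz = config$dz))

  k1_single <- halflife_to_rate(config$halflife_days[1])
  say("stage transport: single depletion run")
  balance <- stage("transport",
    run_until_depleted(bubble$deposition, scenario, k1 = k1_single,
                       start_day = config$release_day,
                       stop_fraction = config$stop_fraction, dt = config$dt,
                       a = config$a, Sc = config$Sc))
  closure <- abs(balance$dissolved + balance$biodegraded + balance$ventilated +
                   balance$bubble - 1)
  say(sprintf("  mass-closure residual: max %.2e", max(closure)))

  say("stage fate: annual ensemble")
  fate <- stage("fate", {
    if (length(config$halflife_days) > 1)
      halflife_sweep(bubble$deposition, scenario,
                     halflife_days = config$halflife_days,
                     n_starts = config$n_starts, dt = config$dt,
                     stop_fraction = config$stop_fraction,
                     a = config$a, Sc = config$Sc)
    else
      annual_ensemble(bubble$deposition, scenario, k1 = k1_single,
                      n_starts = config$n_starts, dt = config$dt,
                      stop_fraction = config$stop_fraction,
                      a = config$a, Sc = config$Sc)
  })
  ventilation <- ventilation_rate(balance)

  hash <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    hash <- unname(tools::md5sum(file.path(out_dir, "config.yaml")))
    write_scenario(scenario, file.path(out_dir, "scenario"))
    write_deposition_csv(bubble$deposition, file.path(out_dir, "deposition.csv"))
    write.csv(bubble$trajectory, file.path(out_dir, "trajectory.csv"),
              row.names = FALSE, quote = FALSE)
    write_mass_balance_csv(balance, file.path(out_dir, "mass_balance.csv"))
    if (inherits(fate, "fate_summary"))
      write_fate_summary_csv(fate, file.path(out_dir, "fate_summary.csv"))
    else {
      write.csv(fate$members, file.path(out_dir, "fate_members.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(as.data.frame(t(fate$mean)), file.path(out_dir, "fate_mean.csv"),
                row.names = FALSE, quote = FALSE)
    }
    write.csv(as.data.frame(ventilation), file.path(out_dir, "ventilation.csv"),
              row.names = FALSE, quote = FALSE)
    prov <- list(config_hash = hash, seed = config$seed,
                 package_version = as.character(utils::packageVersion("seepfate")),
                 r_version = R.version.string,
                 max_closure_residual = max(closure))
    yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  } else {
    tf <- tempfile(fileext = ".yaml")
    write_config(config, tf)
    hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }

  list(scenario = scenario, bubble = bubble, balance = balance, fate = fate,
       ventilation = ventilation, config = config, config_hash = hash)
}
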