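# Declarative run configuration: a YAML-compatible key/value tree that
# round-trips losslessly and fully determines a run together with the
# master seed.  No code in config files.

#' Build a run configuration
#'
#' @param system list describing the system fixture, e.g.
#'   \code{list(fixture = "dimer", seed = 1, n_solvent = 0)} or
#'   \code{list(kind = "double_well_1d", barrier = 2, asymmetry = 0.8)}.
#' @param protocol one of tremd/tiger2/tiger2h/tiger2hs.
#' @param ladder list(t_min, t_max, m).
#' @param schedule list(sampling_steps, quench_steps, step_size).
#' @param n_cycles recorded cycles.
#' @param master_seed integer.
#' @param restraints optional list of restraint blocks
#'   (list(type, atoms, theta0/d0, k, flat_bottom)) or the string
#'   \code{"rigid_body"}.
#' @param shell optional list(r, n).
#' @param analysis list(features = "distance" or "dpca", bins,
#'   temperature).
#' @param out_dir optional output directory.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(system, protocol = "tiger2",
                       ladder = list(t_min = 280, t_max = 600, m = 8),
                       schedule = list(sampling_steps = 20,
                                       quench_steps = 10,
                                       step_size = 0.1),
                       n_cycles = 100, master_seed = 1,
                       restraints = NULL, shell = NULL,
                       analysis = list(features = "distance", bins = 30,
                                       temperature = 280),
                       out_dir = NULL) {
  protocol <- match.arg(protocol,
                        c("tremd", "tiger2", "tiger2h", "tiger2hs"))
  structure(list(system = system, protocol = protocol, ladder = ladder,
                 schedule = schedule, n_cycles = as.integer(n_cycles),
                 master_seed = as.integer(master_seed),
                 restraints = restraints, shell = shell,
                 analysis = analysis, out_dir = out_dir),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a \code{run_config}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Read a run configuration from YAML
#'
#' @param file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  x <- yaml::read_yaml(file)
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

#' Materialise the system described by a config
#'
#' @param config a \code{run_config}.
#' @return a \code{dimer_system} or \code{potential_spec}.
#' @export
config_system <- function(config) {
  s <- config$system
  if (!is.null(s$fixture) && s$fixture == "dimer") {
    make_dimer_fixture(seed = s$seed,
                       n_solvent = if (is.null(s$n_solvent)) 0
                                   else s$n_solvent)
  } else if (!is.null(s$kind)) {
    switch(s$kind,
      double_well_1d = make_double_well(s$barrier,
                                        if (is.null(s$asymmetry)) 0
                                        else s$asymmetry),
      harmonic_nd = make_harmonic(s$k, if (is.null(s$d)) 1 else s$d),
      dihedral_chain = make_dihedral_chain(s$n_angles, s$barrier,
                                           if (is.null(s$asymmetry)) 0.5
                                           else s$asymmetry),
      stop("unknown system kind: ", s$kind))
  } else stop("config$system must name a fixture or a potential kind")
}

#' Run the protocol described by a config
#'
#' Thin orchestration over \code{\link{run_protocol}}: materialises the
#' system, restraints and shell from the config and launches the run.
#' When \code{config$out_dir} is set, the baseline trajectory
#' (multi-model PDB), the per-frame energy CSV, the exchange log and a
#' JSON run-meta file (ladder, schedule, seed, both per-replica and
#' aggregate step accounting) are written there, together with a copy
#' of the exact config used.
#'
#' @param config a \code{run_config}.
#' @return the \code{baseline_ensemble}.
#' @export
run_from_config <- function(config) {
  system <- config_system(config)
  ladder <- build_ladder(config$ladder$t_min, config$ladder$t_max,
                         config$ladder$m)
  schedule <- do.call(cycle_schedule, config$schedule)
  restr <- NULL
  if (!is.null(config$restraints)) {
    if (identical(config$restraints, "rigid_body"))
      restr <- make_rigid_body_restraints(system)
    else
      restr <- lapply(config$restraints, function(b)
        if (b$type == "dihedral")
          dihedral_restraint(b$atoms, b$theta0, b$k)
        else
          distance_restraint(b$atoms, b$d0, b$k,
                             if (is.null(b$flat_bottom)) 0.05
                             else b$flat_bottom))
  }
  shell <- if (!is.null(config$shell))
    shell_spec(config$shell$r, config$shell$n)
  ens <- run_protocol(config$protocol, system, ladder, schedule,
                      config$n_cycles, config$master_seed,
                      restraints = restr, shell = shell)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(config$out_dir, "run.yaml"))
    if (inherits(system, "dimer_system"))
      write_trajectory_pdb(ens$frames,
                           file.path(config$out_dir, "baseline.pdb"),
                           chain = system$chain, labels = system$type)
    else
      write_trajectory_xyz(lapply(ens$frames, function(f)
        matrix(c(as.numeric(f), rep(0, 2 * length(f))),
               ncol = 3)),
        file.path(config$out_dir, "baseline.xyz"))
    write_energy_sidecar(ens$info,
                         file.path(config$out_dir, "baseline.csv"))
    if (!is.null(ens$exchanges))
      write.csv(ens$exchanges,
                file.path(config$out_dir, "exchanges.csv"),
                row.names = FALSE)
    write_run_meta(ens, file.path(config$out_dir, "run_meta.json"))
  }
  ens
}

#' Write run metadata as JSON
#'
#' Records protocol, ladder, schedule, master seed, frame count and
#' both step accountings (per replica and aggregate over replicas).
#'
#' @param ensemble a \code{baseline_ensemble}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_run_meta <- function(ensemble, file) {
  m <- ensemble$meta
  total <- m$n_cycles + m$burnin_cycles
  meta <- list(
    protocol = m$protocol,
    ladder = list(t_min = m$ladder$t_min, t_max = m$ladder$t_max,
                  m = m$ladder$m, temps = m$ladder$temps),
    schedule = list(sampling_steps = m$schedule$sampling_steps,
                    quench_steps = m$schedule$quench_steps,
                    step_size = m$schedule$step_size),
    master_seed = m$master_seed,
    n_cycles = m$n_cycles,
    burnin_cycles = m$burnin_cycles,
    n_frames = length(ensemble$frames),
    steps_per_replica = total * (m$schedule$sampling_steps +
                                 m$schedule$quench_steps),
    steps_aggregate = total * m$ladder$m *
      (m$schedule$sampling_steps + m$schedule$quench_steps),
    n_energy_evals = m$n_energy_evals,
    package_version = as.character(utils::packageVersion("tigerex")))
  jsonlite::write_json(meta, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
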