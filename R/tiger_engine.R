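# Replica-exchange schedulers.
#
# T-REMD attempts Metropolis swaps between temperature neighbours.  The
# TIGER2-family cycle instead samples every replica at its rung
# temperature, quenches all of them to the baseline temperature, then
# attempts exchanges between the current baseline replica and the other
# replicas in ascending ladder order: each accepted candidate becomes
# the new baseline comparator and the displaced baseline state is
# appended to the baseline ensemble (multi-acceptance).  Afterwards the
# non-baseline replicas are reassigned to the remaining rungs by
# exchange-energy rank (lowest energy -> lowest temperature).  The
# protocols differ only in the energy driving the exchange decisions:
# full potential (TIGER2), solute-only plus implicit term (TIGER2h), or
# solute plus a fixed shell of nearest explicit solvent plus implicit
# remainder (TIGER2hs).

#' Geometric (exponential) temperature ladder
#'
#' temps[i] = Tmin (Tmax/Tmin)^(i/(M-1)): successive ratios are
#' constant, e.g. 64 rungs from 280 K to 600 K, or 11 rungs from
#' 280 K to 450 K.
#'
#' @param t_min,t_max endpoint temperatures, K; 0 < t_min < t_max.
#' @param m number of rungs; >= 2.
#' @return object of class \code{temperature_ladder} with field
#'   \code{temps}.
#' @examples
#' build_ladder(280, 600, 64)$temps[c(1, 64)]
#' @export
build_ladder <- function(t_min, t_max, m) {
  if (!(is.numeric(t_min) && is.numeric(t_max) && t_min > 0 &&
        t_max > t_min))
    stop("need 0 < t_min < t_max")
  if (m < 2) stop("a ladder needs at least 2 rungs")
  m <- as.integer(m)
  temps <- t_min * (t_max / t_min)^((0:(m - 1)) / (m - 1))
  structure(list(t_min = t_min, t_max = t_max, m = m, temps = temps),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat("temperature_ladder:", x$m, "rungs,", format(x$t_min), "-",
      format(x$t_max), "K (geometric)\n")
  invisible(x)
}

.check_rungs <- function(states) {
  r <- vapply(states, function(s) s$rung, 0L)
  if (!identical(sort(r), 0:(length(states) - 1L)) ||
      anyDuplicated(r))
    stop("duplicate or missing rung assignment: ",
         paste(r, collapse = " "))
  if (any(r != 0:(length(states) - 1L)))
    stop("states must be ordered by rung")
  invisible(r)
}

#' One T-REMD neighbour-exchange step
#'
#' Alternating-parity neighbour pairs (i, i+1) swap rungs with
#' probability min(1, exp((beta_i - beta_{i+1})(E_i - E_{i+1}))).
#'
#' @param states list of \code{replica_state}, one per rung, ordered by
#'   rung.
#' @param ladder a \code{temperature_ladder}.
#' @param parity 0 or 1: which neighbour pairing is attempted.
#' @param stream \code{rng_stream} of the exchange scheduler.
#' @return list with the updated \code{states} (ordered by rung) and a
#'   \code{decisions} data frame (lower rung, deltaBetaDeltaE, p,
#'   accepted).
#' @export
tremd_exchange <- function(states, ladder, parity, stream) {
  .check_rungs(states)
  m <- length(states)
  beta <- 1 / kT(ladder$temps)
  first <- 1L + (as.integer(parity) %% 2L)
  lo <- seq(first, m - 1L, by = 2L)
  dec <- data.frame(rung_low = integer(0), delta = numeric(0),
                    p = numeric(0), accepted = logical(0))
  for (i in lo) {
    Ei <- states[[i]]$energy; Ej <- states[[i + 1L]]$energy
    delta <- (beta[i] - beta[i + 1L]) * (Ei - Ej)
    p <- min(1, exp(delta))
    u <- with_stream(stream, runif(1))
    acc <- u < p
    if (acc) {
      tmp <- states[[i]]
      states[[i]] <- states[[i + 1L]]
      states[[i + 1L]] <- tmp
      states[[i]]$rung <- i - 1L
      states[[i + 1L]]$rung <- i
    }
    dec <- rbind(dec, data.frame(rung_low = i - 1L, delta = delta,
                                 p = p, accepted = acc))
  }
  list(states = states, decisions = dec)
}

#' One TIGER global-exchange step
#'
#' All states must already be quenched to the baseline temperature.
#' Candidates are visited in ascending rung order; each attempt accepts
#' with probability min(1, exp(-(E_cand - E_base)/(k_B T_base))).  On
#' acceptance the candidate becomes the new baseline comparator and the
#' displaced baseline state is returned as an accepted frame.  Finally
#' the non-baseline replicas are reassigned to rungs 1..M-1 by exchange
#' energy (lowest energy to the lowest temperature; ties broken by
#' previous rung).
#'
#' @param states list of quenched \code{replica_state}, ordered by rung
#'   (element 1 is the current baseline replica).
#' @param energies exchange-decision energies, kcal/mol, one per state.
#' @param t_base baseline temperature, K.
#' @param stream exchange \code{rng_stream}.
#' @return list: \code{states} (reassigned, ordered by rung),
#'   \code{accepted} (list of displaced baseline frames: coords,
#'   energy, source_rung), \code{decisions} data frame
#'   (candidate_rung, deltaE, p, accepted).
#' @export
tiger_exchange <- function(states, energies, t_base, stream) {
  m <- length(states)
  if (length(energies) != m)
    stop("mismatched state/energy list lengths")
  .check_rungs(states)
  base <- 1L
  accepted <- list()
  cand_r <- integer(m - 1L); dE_v <- numeric(m - 1L)
  p_v <- numeric(m - 1L); acc_v <- logical(m - 1L)
  for (cand in seq_len(m)[-1L]) {
    dE <- energies[cand] - energies[base]
    p <- min(1, exp(-dE / kT(t_base)))
    u <- with_stream(stream, runif(1))
    acc <- u < p
    k <- cand - 1L
    cand_r[k] <- cand - 1L; dE_v[k] <- dE; p_v[k] <- p; acc_v[k] <- acc
    if (acc) {
      accepted[[length(accepted) + 1L]] <-
        list(coords = states[[base]]$coords, energy = energies[base],
             source_rung = states[[base]]$rung)
      base <- cand
    }
  }
  rest <- setdiff(seq_len(m), base)
  ord <- rest[order(energies[rest], rest)]
  new_states <- vector("list", m)
  new_states[[1L]] <- states[[base]]
  new_states[[1L]]$rung <- 0L
  for (k in seq_along(ord)) {
    new_states[[k + 1L]] <- states[[ord[k]]]
    new_states[[k + 1L]]$rung <- k
  }
  list(states = new_states, accepted = accepted,
       decisions = data.frame(candidate_rung = cand_r, deltaE = dE_v,
                              p = p_v, accepted = acc_v),
       baseline_from_rung = base - 1L)
}

#' Run a replica-exchange protocol
#'
#' Executes \code{n_cycles} of sample -> (quench) -> exchange and
#' collects the baseline ensemble.  For \code{"tremd"} the rung-0 state
#' after each neighbour-exchange step is recorded (no quench).  For the
#' TIGER protocols every displaced baseline state plus the final
#' baseline state of each cycle is recorded.  Step sizes are adapted
#' per rung during the burn-in cycles (targeting 30-50 percent MC
#' acceptance), then frozen; burn-in frames are discarded.  The whole
#' run is bit-reproducible from \code{master_seed}.
#'
#' @param protocol \code{"tremd"}, \code{"tiger2"}, \code{"tiger2h"} or
#'   \code{"tiger2hs"}.
#' @param system a \code{potential_spec}, or a \code{dimer_system}
#'   (required for tiger2h/tiger2hs).
#' @param ladder a \code{temperature_ladder}; rung 0 is the baseline.
#' @param schedule a \code{cycle_schedule}.
#' @param n_cycles recorded cycles; >= 1.
#' @param master_seed single integer seeding every stream.
#' @param burnin_cycles discarded adaptation cycles; default
#'   \code{max(10, ceiling(n_cycles/10))}.
#' @param restraints optional restraint list (dimer systems), added to
#'   the propagation potential and to full exchange energies.
#' @param shell a \code{shell_spec} (required for tiger2hs).
#' @param hybrid a \code{hybrid_model}; default zero implicit term.
#' @param method propagator, \code{"mc"} (default) or
#'   \code{"langevin"}.
#' @param hybrid_pbc minimum-image convention for hybrid exchange
#'   energies (default TRUE, matching the propagation potential; set
#'   FALSE to evaluate them in open boundaries).
#' @param adapt adapt step sizes during burn-in (default TRUE).
#' @return object of class \code{baseline_ensemble}: \code{frames}
#'   (list of coordinates), \code{info} (cycle, source_rung, energy),
#'   \code{exchanges} (per-attempt log), \code{replica_trace} (cycle x
#'   rung matrix of replica identities, burn-in included), \code{meta}.
#' @export
run_protocol <- function(protocol = c("tiger2", "tiger2h", "tiger2hs",
                                      "tremd"),
                         system, ladder, schedule, n_cycles, master_seed,
                         burnin_cycles = NULL, restraints = NULL,
                         shell = NULL, hybrid = NULL,
                         method = c("mc", "langevin"),
                         hybrid_pbc = TRUE, adapt = TRUE) {
  protocol <- match.arg(protocol)
  method <- match.arg(method)
  stopifnot(inherits(ladder, "temperature_ladder"),
            inherits(schedule, "cycle_schedule"), n_cycles >= 1)
  if (is.null(burnin_cycles))
    burnin_cycles <- max(10L, ceiling(n_cycles / 10))

  is_dimer <- inherits(system, "dimer_system")
  if (protocol %in% c("tiger2h", "tiger2hs") && !is_dimer)
    stop(protocol, " needs a dimer_system (solute/solvent split)")
  idx <- if (is_dimer) dimer_indices(system)
  if (protocol == "tiger2hs") {
    if (!is_dimer || length(idx$solvent) == 0L)
      stop("tiger2hs needs a system with explicit solvent particles")
    if (is.null(shell)) stop("tiger2hs needs a shell_spec")
    if (shell$n > length(idx$solvent))
      stop("shell size exceeds the solvent count")
  }
  if (is.null(hybrid)) hybrid <- hybrid_model(0)

  potential <- if (is_dimer) dimer_potential(system, restraints)
               else system
  if (!is_dimer && !is.null(restraints))
    stop("restraints are only supported for dimer systems")

  exchange_energy <- switch(protocol,
    tremd = , tiger2 = function(st) st$energy,
    tiger2h = function(st)
      hybrid_energy(st$coords, system, shell_spec(r = 0, n = 0L),
                    hybrid, restraints = restraints, pbc = hybrid_pbc),
    tiger2hs = function(st)
      hybrid_energy(st$coords, system, shell, hybrid,
                    restraints = restraints, pbc = hybrid_pbc))

  m <- ladder$m
  t_base <- ladder$temps[1]
  xstream <- rng_stream(derive_seed(master_seed, 0L))
  states <- lapply(seq_len(m), function(i) {
    s <- replica_state(potential$init, i - 1L, potential,
                       rng_stream(derive_seed(master_seed, i)))
    s$id <- i
    s
  })
  step_sizes <- rep(schedule$step_size, m)
  replica_trace <- matrix(NA_integer_, burnin_cycles + n_cycles, m)

  frames <- list()
  info_cycle <- integer(0); info_rung <- integer(0); info_e <- numeric(0)
  xlog <- list()
  total <- burnin_cycles + n_cycles
  nd <- if (isTRUE(potential$particle)) nrow(potential$init)
        else length(potential$init)

  for (cyc in seq_len(total)) {
    recording <- cyc > burnin_cycles
    rec_cycle <- cyc - burnin_cycles
    # sampling phase at each rung temperature
    for (i in seq_len(m)) {
      states[[i]] <- propagate(states[[i]], potential, ladder$temps[i],
                               schedule$sampling_steps,
                               step_size = step_sizes[i], method = method)
      if (adapt && !recording && method == "mc") {
        a <- attr(states[[i]], "acceptance")
        if (!is.na(a)) {
          if (a > 0.5) step_sizes[i] <- step_sizes[i] * 1.15
          else if (a < 0.3) step_sizes[i] <- step_sizes[i] / 1.15
        }
      }
    }
    if (protocol == "tremd") {
      ex <- tremd_exchange(states, ladder, cyc %% 2L, xstream)
      states <- ex$states
      if (recording) {
        frames[[length(frames) + 1L]] <- states[[1L]]$coords
        info_cycle <- c(info_cycle, rec_cycle)
        info_rung <- c(info_rung, 0L)
        info_e <- c(info_e, states[[1L]]$energy)
        ex$decisions$cycle <- rec_cycle
        xlog[[length(xlog) + 1L]] <- ex$decisions
      }
    } else {
      for (i in seq_len(m))
        states[[i]] <- quench(states[[i]], potential, t_base, schedule,
                              method = method)
      ex_e <- vapply(states, exchange_energy, 0)
      ex <- tiger_exchange(states, ex_e, t_base, xstream)
      if (recording) {
        for (fr in ex$accepted) {
          frames[[length(frames) + 1L]] <- fr$coords
          info_cycle <- c(info_cycle, rec_cycle)
          info_rung <- c(info_rung, fr$source_rung)
          info_e <- c(info_e, fr$energy)
        }
        # the surviving baseline state closes the cycle's acceptances
        frames[[length(frames) + 1L]] <- ex$states[[1L]]$coords
        info_cycle <- c(info_cycle, rec_cycle)
        info_rung <- c(info_rung, ex$baseline_from_rung)
        info_e <- c(info_e, ex_e[ex$baseline_from_rung + 1L])
        ex$decisions$cycle <- rec_cycle
        xlog[[length(xlog) + 1L]] <- ex$decisions
      }
      states <- ex$states
      if (method == "langevin")   # reheat: fresh velocities at new rung T
        for (i in seq_len(m)) states[[i]]$velocities <- NULL
    }
    replica_trace[cyc, ] <- vapply(states, function(s) s$id, 0L)
  }

  steps_per_cycle <- schedule$sampling_steps +
    if (protocol == "tremd") 0L else schedule$quench_steps
  structure(list(
    frames = frames,
    info = data.frame(cycle = info_cycle, source_rung = info_rung,
                      energy = info_e),
    exchanges = do.call(rbind, xlog),
    replica_trace = replica_trace,
    meta = list(protocol = protocol, ladder = ladder,
                schedule = schedule, master_seed = master_seed,
                n_cycles = n_cycles, burnin_cycles = burnin_cycles,
                method = method, step_sizes = step_sizes,
                n_energy_evals = as.double(total) * m * steps_per_cycle * nd,
                shell = shell)),
    class = "baseline_ensemble")
}

#' @export
print.baseline_ensemble <- function(x, ...) {
  cat("baseline_ensemble:", x$meta$protocol, "-", length(x$frames),
      "frames over", x$meta$n_cycles, "cycles (",
      x$meta$burnin_cycles, "burn-in )\n")
  cat("  ladder:", x$meta$ladder$m, "rungs",
      format(x$meta$ladder$t_min), "-", format(x$meta$ladder$t_max),
      "K; seed", x$meta$master_seed, "\n")
  invisible(x)
}

#' Baseline frames as a matrix (vector-coordinate systems)
#'
#' @param ensemble a \code{baseline_ensemble}.
#' @return frames x dof numeric matrix.
#' @export
ensemble_matrix <- function(ensemble) {
  do.call(rbind, lapply(ensemble$frames, as.numeric))
}

#' Count well transitions of a 1D trajectory
#'
#' Number of sign changes of (x - split) along the sequence; two
#' transitions make one round trip.
#'
#' @param x numeric trajectory.
#' @param split dividing point between the wells.
#' @return integer count.
#' @export
count_transitions <- function(x, split = 0) {
  s <- sign(x - split)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
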