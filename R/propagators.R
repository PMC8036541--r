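# Within-replica canonical samplers.  Metropolis Monte Carlo is the
# default propagator (sequential single-coordinate or single-bead
# sweeps, detailed balance w.r.t. exp(-V/kT)); an underdamped Langevin
# (BAOAB) integrator is available for potentials that expose a
# gradient.  The quench stage of a TIGER cycle is the same propagator
# run at the baseline temperature.

#' Create a replica state
#'
#' @param coords coordinates (vector, or n x 3 matrix for particle
#'   systems), nm (degrees for angular systems).
#' @param rung 0-based position on the temperature ladder.
#' @param potential the \code{potential_spec}; used to evaluate the
#'   stored potential energy.
#' @param stream an \code{rng_stream} owned exclusively by this replica.
#' @param velocities optional velocities (Langevin only), nm/ps.
#' @return object of class \code{replica_state}.
#' @export
replica_state <- function(coords, rung, potential, stream,
                          velocities = NULL) {
  e <- potential$energy(coords)
  if (!is.finite(e)) stop("non-finite energy at the supplied coordinates")
  structure(list(coords = coords, velocities = velocities,
                 rung = as.integer(rung), energy = e, stream = stream),
            class = "replica_state")
}

#' Sampling/quench schedule of one TIGER cycle
#'
#' @param sampling_steps MC sweeps (or Langevin steps) of the hot
#'   sampling phase; > 0.
#' @param quench_steps sweeps/steps of the baseline-temperature quench;
#'   >= 0.
#' @param step_size MC trial displacement half-width (nm or degrees) or
#'   Langevin timestep (ps).
#' @return object of class \code{cycle_schedule}.
#' @export
cycle_schedule <- function(sampling_steps = 20, quench_steps = 10,
                           step_size = 0.1) {
  stopifnot(sampling_steps > 0, quench_steps >= 0, step_size > 0)
  structure(list(sampling_steps = as.integer(sampling_steps),
                 quench_steps = as.integer(quench_steps),
                 step_size = step_size),
            class = "cycle_schedule")
}

#' Propagate a replica at fixed temperature
#'
#' Runs \code{steps} Metropolis sweeps (method \code{"mc"}) or BAOAB
#' Langevin steps (method \code{"langevin"}) at temperature \code{T},
#' drawing all randomness from the state's own stream.  The returned
#' state's stored energy is a fresh evaluation at the final coordinates.
#'
#' @param state a \code{replica_state}.
#' @param potential a \code{potential_spec}.
#' @param temperature K; > 0.
#' @param steps number of sweeps/steps; >= 0 (0 returns the state
#'   unchanged).
#' @param step_size MC displacement half-width or Langevin dt; default
#'   0.1.
#' @param method \code{"mc"} or \code{"langevin"}.
#' @param record_every if > 0, record coordinates every that many
#'   sweeps into an attribute \code{"trace"}.
#' @param gamma Langevin friction, 1/ps.
#' @param mass particle mass (model units), default 1.
#' @return the propagated \code{replica_state}; attributes
#'   \code{"acceptance"} (MC acceptance fraction) and optionally
#'   \code{"trace"}.
#' @export
propagate <- function(state, potential, temperature, steps,
                      step_size = 0.1, method = c("mc", "langevin"),
                      record_every = 0, gamma = 5, mass = 1) {
  method <- match.arg(method)
  stopifnot(temperature > 0, steps >= 0)
  if (steps == 0) return(state)
  beta <- 1 / kT(temperature)
  out <- with_stream(state$stream, {
    if (method == "mc") {
      if (isTRUE(potential$particle))
        .mc_particle(state$coords, potential, beta, step_size, steps,
                     record_every)
      else
        .mc_vector(state$coords, potential, beta, step_size, steps,
                   record_every)
    } else {
      .langevin(state, potential, temperature, steps, step_size, gamma,
                mass, record_every)
    }
  })
  ns <- state
  ns$coords <- out$x
  ns$velocities <- out$v
  ns$energy <- potential$energy(out$x)
  if (!is.finite(ns$energy)) {
    stop("non-finite energy after propagation; rung ", state$rung,
         " T=", temperature, " coords range [",
         paste(range(out$x), collapse = ", "), "]")
  }
  attr(ns, "acceptance") <- out$acc
  if (record_every > 0) attr(ns, "trace") <- out$trace
  ns
}

.mc_vector <- function(x, pot, beta, step, sweeps, record_every) {
  nd <- length(x)
  E <- pot$energy(x)
  acc <- 0L; tot <- 0L
  trace <- if (record_every > 0)
    matrix(NA_real_, floor(sweeps / record_every), nd) else NULL
  ri <- 0L
  for (s in seq_len(sweeps)) {
    for (j in seq_len(nd)) {
      prop <- x[j] + runif(1, -step, step)
      if (!is.null(pot$wrap)) prop <- pot$wrap(prop)
      tot <- tot + 1L
      if (prop < pot$lower[1] || prop > pot$upper[1]) next
      xp <- x; xp[j] <- prop
      Ep <- pot$energy(xp)
      if (!is.finite(Ep))
        stop("non-finite trial energy at x=", paste(xp, collapse = ","))
      dE <- Ep - E
      if (dE <= 0 || runif(1) < exp(-beta * dE)) {
        x <- xp; E <- Ep; acc <- acc + 1L
      }
    }
    if (record_every > 0 && s %% record_every == 0) {
      ri <- ri + 1L; trace[ri, ] <- x
    }
  }
  list(x = x, v = NULL, acc = acc / tot, trace = trace)
}

.mc_particle <- function(x, pot, beta, step, sweeps, record_every) {
  n <- nrow(x)
  acc <- 0L; tot <- 0L
  trace <- if (record_every > 0) vector("list", floor(sweeps / record_every))
           else NULL
  ri <- 0L
  for (s in seq_len(sweeps)) {
    for (i in seq_len(n)) {
      p <- x[i, ] + runif(3, -step, step)
      dE <- pot$delta_move(x, i, p)
      tot <- tot + 1L
      if (dE <= 0 || runif(1) < exp(-beta * dE)) {
        x[i, ] <- p; acc <- acc + 1L
      }
    }
    if (record_every > 0 && s %% record_every == 0) {
      ri <- ri + 1L; trace[[ri]] <- x
    }
  }
  list(x = x, v = NULL, acc = acc / tot, trace = trace)
}

.langevin <- function(state, pot, temperature, steps, dt, gamma, mass,
                      record_every) {
  if (is.null(pot$grad))
    stop("Langevin propagation needs a potential with a gradient")
  x <- state$coords
  nd <- length(x)
  sdv <- sqrt(kT(temperature) / mass)
  v <- state$velocities
  if (is.null(v)) v <- rnorm(nd, 0, sdv)
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2) * sdv
  trace <- if (record_every > 0)
    matrix(NA_real_, floor(steps / record_every), nd) else NULL
  ri <- 0L
  g <- pot$grad(x)
  for (s in seq_len(steps)) {
    v <- v - 0.5 * dt * g / mass
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * rnorm(nd)
    x <- x + 0.5 * dt * v
    # reflect at the domain boundary to keep the walk inside
    if (is.finite(pot$lower[1])) {
      lo <- pot$lower; hi <- pot$upper
      out <- x < lo
      x[out] <- 2 * lo - x[out]; v[out] <- -v[out]
      out <- x > hi
      x[out] <- 2 * hi - x[out]; v[out] <- -v[out]
    }
    g <- pot$grad(x)
    v <- v - 0.5 * dt * g / mass
    if (record_every > 0 && s %% record_every == 0) {
      ri <- ri + 1L; trace[ri, ] <- x
    }
  }
  list(x = x, v = v, acc = NA_real_, trace = trace)
}

#' Quench a replica to the baseline temperature
#'
#' Propagates \code{quench_steps} at \code{t_base}.  For Langevin,
#' velocities are first resampled from the Maxwell-Boltzmann
#' distribution at \code{t_base} (default) or rescaled to it.  The rung
#' index is unchanged; the stored energy is refreshed.
#'
#' @param state a \code{replica_state}.
#' @param potential a \code{potential_spec}.
#' @param t_base baseline temperature, K.
#' @param schedule a \code{cycle_schedule} (uses \code{quench_steps} and
#'   \code{step_size}).
#' @param method \code{"mc"} or \code{"langevin"}.
#' @param velocity_mode \code{"resample"} or \code{"rescale"} at quench
#'   onset (Langevin only).
#' @return the quenched \code{replica_state}.
#' @export
quench <- function(state, potential, t_base, schedule,
                   method = c("mc", "langevin"),
                   velocity_mode = c("resample", "rescale")) {
  method <- match.arg(method)
  velocity_mode <- match.arg(velocity_mode)
  if (schedule$quench_steps == 0) return(state)
  if (method == "langevin" && !is.null(state$velocities)) {
    sdv <- sqrt(kT(t_base))
    if (velocity_mode == "resample") {
      state$velocities <- with_stream(state$stream,
        rnorm(length(state$velocities), 0, sdv))
    } else {
      cur <- sqrt(mean(state$velocities^2))
      if (cur > 0) state$velocities <- state$velocities * sdv / cur
    }
  }
  propagate(state, potential, t_base, schedule$quench_steps,
            step_size = schedule$step_size, method = method)
}

#' Single-temperature canonical Monte Carlo trace
#'
#' Convenience wrapper: equilibrate then record a plain Metropolis MC
#' trajectory at one temperature.  This is the equivalence oracle for
#' the replica-exchange protocols on systems without kinetic trapping.
#'
#' @param potential a \code{potential_spec}.
#' @param temperature K.
#' @param sweeps recorded-phase sweeps.
#' @param step_size MC displacement half-width.
#' @param seed integer seed.
#' @param record_every record interval in sweeps.
#' @param burnin discarded equilibration sweeps.
#' @return matrix (or list, for particle systems) of recorded
#'   configurations; attribute \code{"acceptance"}.
#' @export
mc_sample <- function(potential, temperature, sweeps, step_size = 0.1,
                      seed = 1, record_every = 1, burnin = 0) {
  st <- replica_state(potential$init, 0L, potential, rng_stream(seed))
  if (burnin > 0)
    st <- propagate(st, potential, temperature, burnin, step_size)
  st <- propagate(st, potential, temperature, sweeps, step_size,
                  record_every = record_every)
  out <- attr(st, "trace")
  attr(out, "acceptance") <- attr(st, "acceptance")
  out
}
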