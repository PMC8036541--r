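# Hybrid explicit/implicit exchange energies.
#
# For exchange decisions only (never for propagation), the bulk solvent
# is replaced by a mean-field term: the N solvent particles nearest to
# the solute are kept explicitly, all pair terms among solute + shell
# are summed, and the excluded bulk contributes a linear implicit
# remainder.  The shell size N is determined once, from the radial
# distribution of nearest-solute distances on a pre-run trajectory, and
# then held fixed -- a varying shell would bias exchange energies
# between states.

#' Fixed hydration-shell specification
#'
#' @param r shell cutoff distance, nm.
#' @param n number of explicit solvent particles kept; >= 0.
#' @return object of class \code{shell_spec}.
#' @export
shell_spec <- function(r, n) {
  n <- as.integer(n)
  if (n < 0) stop("shell size must be >= 0")
  structure(list(r = r, n = n), class = "shell_spec")
}

#' @export
print.shell_spec <- function(x, ...) {
  cat("shell_spec: r =", x$r, "nm, N =", x$n, "\n")
  invisible(x)
}

#' Implicit-bulk model for hybrid exchange energies
#'
#' The implicit remainder is linear in the number of excluded solvent
#' particles: constant * (n_solvent - N), with \code{constant} the mean
#' per-particle interaction energy (kcal/mol), typically calibrated
#' with \code{\link{calibrate_implicit_constant}}.
#'
#' @param constant mean per-particle bulk interaction, kcal/mol.
#' @return object of class \code{hybrid_model}.
#' @export
hybrid_model <- function(constant = 0) {
  structure(list(constant = constant), class = "hybrid_model")
}

#' Select the N solvent particles nearest to the solute
#'
#' Distance of a solvent particle is the minimum over all solute
#' pseudo-atoms (minimum image when \code{box} is given).  Ties are
#' broken by particle index, so the selection is deterministic.
#'
#' @param solute m x 3 solute coordinates.
#' @param solvent s x 3 solvent coordinates.
#' @param n number to select; 0 <= n <= s.
#' @param box optional cubic box side for minimum-image distances.
#' @return integer indices (into the solvent rows) of the selected
#'   shell, ordered by distance.
#' @export
select_shell <- function(solute, solvent, n, box = NULL) {
  n <- as.integer(n)
  s <- if (is.null(solvent)) 0L else nrow(solvent)
  if (n < 0 || n > s)
    stop("shell size ", n, " outside [0, ", s, "]")
  if (n == 0L) return(integer(0))
  d <- nearest_solute_distance(solute, solvent, box)
  order(d, seq_len(s))[seq_len(n)]
}

#' Nearest-solute-atom distance of each solvent particle
#'
#' @inheritParams select_shell
#' @return numeric vector, one distance per solvent particle.
#' @export
nearest_solute_distance <- function(solute, solvent, box = NULL) {
  vapply(seq_len(nrow(solvent)), function(i) {
    dx <- sweep(solute, 2, solvent[i, ])
    if (!is.null(box)) dx <- dx - box * round(dx / box)
    sqrt(min(rowSums(dx^2)))
  }, 0)
}

#' Hybrid explicit/implicit exchange energy
#'
#' Explicit pair terms over solute + the N nearest solvent particles
#' (solute-solute, solute-shell, shell-shell, chain bonds, restraints
#' internal to the subset), plus the implicit bulk remainder for the
#' excluded particles.  With the shell covering all solvent and a zero
#' implicit constant this equals the full explicit potential energy
#' exactly.
#'
#' @param coords full n x 3 coordinate matrix of the system.
#' @param system a \code{dimer_system}.
#' @param shell a \code{shell_spec} (or plain integer N).
#' @param model a \code{hybrid_model}; default zero implicit term.
#' @param restraints optional restraint list included in the explicit
#'   part.
#' @param pbc minimum-image convention for the explicit terms (FALSE
#'   evaluates them in open boundaries).
#' @return energy in kcal/mol.
#' @export
hybrid_energy <- function(coords, system, shell, model = hybrid_model(0),
                          restraints = NULL, pbc = TRUE) {
  n_keep <- if (inherits(shell, "shell_spec")) shell$n
            else as.integer(shell)
  idx <- dimer_indices(system)
  n_solv <- length(idx$solvent)
  if (n_keep > n_solv) stop("shell size exceeds the solvent count")
  sel <- if (n_keep > 0L)
    idx$solvent[select_shell(coords[idx$solute, , drop = FALSE],
                             coords[idx$solvent, , drop = FALSE],
                             n_keep,
                             box = if (pbc) system$box else NULL)]
  else integer(0)
  explicit <- dimer_energy(system, coords,
                           indices = c(idx$solute, sel), pbc = pbc,
                           restraints = restraints)
  explicit + model$constant * (n_solv - n_keep)
}

#' Calibrate the implicit per-particle constant from the fixture
#'
#' Mean per-solvent-particle interaction energy:
#' (E_full - E_solute-only) / n_solvent, averaged over the supplied
#' frames (default: the system's own configuration).
#'
#' @param system a \code{dimer_system} with solvent.
#' @param frames optional list of coordinate matrices.
#' @param pbc minimum-image convention.
#' @return kcal/mol per excluded particle.
#' @export
calibrate_implicit_constant <- function(system, frames = NULL,
                                        pbc = TRUE) {
  idx <- dimer_indices(system)
  if (length(idx$solvent) == 0L) return(0)
  if (is.null(frames)) frames <- list(system$xyz)
  per <- vapply(frames, function(x) {
    (dimer_energy(system, x, pbc = pbc) -
     dimer_energy(system, x, indices = idx$solute, pbc = pbc)) /
      length(idx$solvent)
  }, 0)
  mean(per)
}

#' Hydration-shell size from the nearest-solute radial distribution
#'
#' For every frame and every solvent particle the nearest-solute-atom
#' distance is computed and histogrammed in bins of \code{bin_width}
#' (0.005 nm by default); the shell occupancy N(r) is the across-frame
#' mean count of particles falling in the bins up to \code{r}, rounded
#' half to even.  N(r) is non-decreasing in r and differs from the
#' exact cumulative count by at most one count (bin rounding).
#'
#' @param trajectory list of n x 3 coordinate frames (full system).
#' @param system a \code{dimer_system} defining the solute/solvent
#'   split and the box.
#' @param r shell cutoff, nm.
#' @param bin_width histogram bin width, nm (default 0.005).
#' @param pbc minimum-image convention.
#' @return a \code{shell_spec} with attributes \code{n_frames},
#'   \code{bin_width} and \code{profile} (function N(r)).
#' @export
shell_size_from_rdf <- function(trajectory, system, r,
                                bin_width = 0.005, pbc = TRUE) {
  if (length(trajectory) < 1L) stop("empty trajectory")
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- dimer_indices(system)
  box <- if (pbc) system$box else NULL
  dists <- lapply(trajectory, function(x)
    nearest_solute_distance(x[idx$solute, , drop = FALSE],
                            x[idx$solvent, , drop = FALSE], box))
  count_at <- function(rr) {
    edge <- bin_width * floor(rr / bin_width + 1e-9)
    mean(vapply(dists, function(d) sum(d <= edge), 0))
  }
  n <- round(count_at(r))
  out <- shell_spec(r = r, n = n)
  attr(out, "n_frames") <- length(trajectory)
  attr(out, "bin_width") <- bin_width
  attr(out, "profile") <- function(rr)
    vapply(rr, function(z) round(count_at(z)), 0)
  out
}
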