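# Harmonic restraint terms added to the potential.
#
# Backbone-dihedral restraints give rigid-body-like docking (strongly
# penalising internal torsion changes while leaving the relative pose
# of the two chains free); flat-bottom distance restraints are the toy
# analogue of restraining backbone hydrogen bonds to preserve secondary
# structure.  Convention: E = k * delta^2 with no 1/2 factor and delta
# in degrees (dihedral) or nm beyond the flat bottom (distance); the
# 1/2 convention is available via the `half` flag.

#' Harmonic dihedral restraint
#'
#' @param atoms four bead indices defining the dihedral.
#' @param theta0 reference angle, degrees.
#' @param k force constant, kcal/(mol deg^2); >= 0.  The paper-scale
#'   rigid-body default is 25.
#' @return object of class \code{dihedral_restraint}.
#' @export
dihedral_restraint <- function(atoms, theta0, k = 25) {
  stopifnot(length(atoms) == 4L, k >= 0)
  structure(list(type = "dihedral", atoms = as.integer(atoms),
                 theta0 = theta0, k = k),
            class = c("dihedral_restraint", "restraint"))
}

#' Flat-bottom harmonic distance restraint
#'
#' Penalises |d - d0| beyond \code{flat_bottom}:
#' E = k max(0, |d - d0| - flat_bottom)^2.
#'
#' @param atoms two bead indices.
#' @param d0 reference distance, nm.
#' @param k force constant, kcal/(mol nm^2); >= 0.
#' @param flat_bottom half-width of the zero-energy region, nm; >= 0
#'   (default 0.05).
#' @return object of class \code{distance_restraint}.
#' @export
distance_restraint <- function(atoms, d0, k, flat_bottom = 0.05) {
  stopifnot(length(atoms) == 2L, k >= 0, flat_bottom >= 0)
  structure(list(type = "distance", atoms = as.integer(atoms),
                 d0 = d0, k = k, flat_bottom = flat_bottom),
            class = c("distance_restraint", "restraint"))
}

#' Dihedral angle of four points
#'
#' Standard atan2 convention, degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angular deviation to (-180, 180] degrees
#'
#' @param delta deviation in degrees.
#' @return wrapped deviation.
#' @export
wrap_deviation <- function(delta) {
  w <- ((delta + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Total restraint energy of a configuration
#'
#' Sum over restraints of k delta^2 (delta: wrapped dihedral deviation
#' in degrees, or the distance excess beyond the flat bottom in nm).
#' Invariant under global rotation/translation and continuous across
#' the +-180 degree seam.
#'
#' @param coords n x 3 coordinate matrix.
#' @param restraints list of restraint objects.
#' @param half use the 1/2 k delta^2 convention (default FALSE).
#' @return energy in kcal/mol.
#' @export
restraint_energy <- function(coords, restraints, half = FALSE) {
  if (!length(restraints)) return(0)
  e <- 0
  n <- nrow(coords)
  for (rs in restraints) {
    if (any(rs$atoms < 1L | rs$atoms > n))
      stop("restraint references bead outside 1..", n)
    if (rs$type == "dihedral") {
      th <- dihedral_angle(coords[rs$atoms[1], ], coords[rs$atoms[2], ],
                           coords[rs$atoms[3], ], coords[rs$atoms[4], ])
      d <- wrap_deviation(th - rs$theta0)
      e <- e + rs$k * d^2
    } else {
      dd <- sqrt(sum((coords[rs$atoms[1], ] - coords[rs$atoms[2], ])^2))
      ex <- max(0, abs(dd - rs$d0) - rs$flat_bottom)
      e <- e + rs$k * ex^2
    }
  }
  if (half) e / 2 else e
}

#' Rigid-body dihedral restraints for a dimer system
#'
#' One restraint per internal chain dihedral (beads i..i+3), with the
#' reference angle taken from the current configuration and force
#' constant \code{k}; the first and last \code{skip_terminal} dihedrals
#' of each chain are omitted, mirroring leaving the terminal residues
#' unrestrained.
#'
#' @param system a \code{dimer_system}.
#' @param skip_terminal dihedrals omitted at each chain end; >= 0.
#' @param k force constant, kcal/(mol deg^2), default 25.
#' @return list of \code{dihedral_restraint}.
#' @export
make_rigid_body_restraints <- function(system, skip_terminal = 2, k = 25) {
  stopifnot(inherits(system, "dimer_system"), skip_terminal >= 0)
  nc <- system$n_chain
  ndih <- nc - 3L
  if (ndih - 2L * skip_terminal < 1L)
    stop("chains too short: need more than ", 2 * skip_terminal + 3,
         " beads for skip_terminal = ", skip_terminal)
  keep <- (skip_terminal + 1L):(ndih - skip_terminal)
  out <- list()
  for (offset in c(0L, nc)) {
    for (i in keep) {
      at <- offset + i + 0:3
      th0 <- dihedral_angle(system$xyz[at[1], ], system$xyz[at[2], ],
                            system$xyz[at[3], ], system$xyz[at[4], ])
      out[[length(out) + 1L]] <- dihedral_restraint(at, th0, k)
    }
  }
  out
}
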