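# Synthetic energy models with analytically known (or brute-force
# computable) reference behaviour.  These stand in for all-atom systems:
# a 1D double well and an isotropic harmonic well validate the samplers
# against closed forms and quadrature; a dihedral chain exercises dPCA;
# a patchy two-chain "dimer" with explicit solvent beads exercises the
# hybrid-solvent machinery and the docking/mutant analysis.

#' Construct a potential specification
#'
#' A \code{potential_spec} bundles an energy function with everything the
#' propagators need: optional analytic gradient, domain bounds, angular
#' wrapping, a default starting configuration, and (for particle systems)
#' a per-particle move-energy routine.
#'
#' @param kind one of \code{"double_well_1d"}, \code{"harmonic_nd"},
#'   \code{"dihedral_chain"}, \code{"patchy_dimer"}.
#' @param parameters named list of the constants the kind requires.
#' @param energy function(x) returning kcal/mol; must be finite on the
#'   declared domain.
#' @param grad optional function(x) returning the gradient.
#' @param init default starting coordinates.
#' @param lower,upper domain bounds (recycled over coordinates); moves
#'   outside are rejected.
#' @param wrap optional function applied to proposed coordinates
#'   (angular systems).
#' @param particle logical; if TRUE coordinates are an n x 3 matrix and
#'   \code{delta_move} must be supplied.
#' @param delta_move function(x, i, newp) returning the energy change of
#'   moving particle i to newp (particle systems only).
#' @param ... extra fields stored on the object.
#' @return object of class \code{potential_spec}.
#' @export
potential_spec <- function(kind, parameters, energy, grad = NULL, init,
                           lower = -Inf, upper = Inf, wrap = NULL,
                           particle = FALSE, delta_move = NULL, ...) {
  kind <- match.arg(kind, c("double_well_1d", "harmonic_nd",
                            "dihedral_chain", "patchy_dimer"))
  stopifnot(is.function(energy))
  if (particle && !is.function(delta_move))
    stop("particle potentials need a delta_move routine")
  e0 <- energy(init)
  if (!is.finite(e0))
    stop("energy not finite at the initial configuration")
  structure(list(kind = kind, parameters = parameters, energy = energy,
                 grad = grad, init = init, lower = lower, upper = upper,
                 wrap = wrap, particle = particle, delta_move = delta_move,
                 ...),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("potential_spec:", x$kind, "\n")
  cat("  parameters:", paste(names(x$parameters),
                             vapply(x$parameters, function(p)
                               paste(format(p), collapse = ","), ""),
                             sep = "=", collapse = "  "), "\n")
  cat("  dof:", length(x$init) * if (x$particle) 3L else 1L, "\n")
  invisible(x)
}

#' One-dimensional double well
#'
#' V(x) = barrier (x^2 - 1)^2 + asymmetry x / 2 on x in [-2.5, 2.5] nm.
#' For small asymmetry the minima sit near x = -1 and x = +1; positive
#' asymmetry favours the left well.
#'
#' @param barrier barrier height, kcal/mol; must be > 0.
#' @param asymmetry tilt, kcal/mol.
#' @return a \code{potential_spec} of kind \code{double_well_1d}.
#' @examples
#' dw <- make_double_well(1, 0)
#' dw$energy(c(-1)); dw$energy(0)
#' @export
make_double_well <- function(barrier, asymmetry = 0) {
  if (!is.numeric(barrier) || length(barrier) != 1L || barrier <= 0)
    stop("barrier must be a positive scalar (kcal/mol)")
  potential_spec(
    kind = "double_well_1d",
    parameters = list(barrier = barrier, asymmetry = asymmetry),
    energy = function(x) barrier * (x[1]^2 - 1)^2 + asymmetry * x[1] / 2,
    grad = function(x) 4 * barrier * x[1] * (x[1]^2 - 1) + asymmetry / 2,
    init = -1, lower = -2.5, upper = 2.5)
}

#' Isotropic harmonic well in d dimensions
#'
#' V(x) = (k/2) sum x_i^2.  At temperature T each coordinate is Gaussian
#' with variance k_B T / k and the mean potential energy is d k_B T / 2.
#'
#' @param k spring constant, kcal/(mol nm^2).
#' @param d dimensionality.
#' @return a \code{potential_spec} of kind \code{harmonic_nd}.
#' @export
make_harmonic <- function(k = 1, d = 1) {
  stopifnot(k > 0, d >= 1)
  potential_spec(
    kind = "harmonic_nd",
    parameters = list(k = k, d = d),
    energy = function(x) 0.5 * k * sum(x^2),
    grad = function(x) k * x,
    init = rep(0, d))
}

#' Chain of independent two-well dihedral angles
#'
#' Each angle (degrees) feels V(t) = (barrier/2)(1 - cos 2t) +
#' (asymmetry/2)(1 - cos t): wells at 0 and 180 degrees separated by
#' \code{barrier}, with the 180-degree well raised by \code{asymmetry}.
#' Conformers (well-assignment patterns) separate cleanly in dPCA space.
#'
#' @param n_angles number of dihedrals.
#' @param barrier per-angle barrier, kcal/mol.
#' @param asymmetry well offset, kcal/mol.
#' @return a \code{potential_spec} of kind \code{dihedral_chain};
#'   coordinates are angles in degrees, wrapped to (-180, 180].
#' @export
make_dihedral_chain <- function(n_angles = 4, barrier = 2, asymmetry = 0.5) {
  stopifnot(n_angles >= 1, barrier > 0)
  wrap_deg <- function(x) {
    w <- ((x + 180) %% 360) - 180
    w[w == -180] <- 180
    w
  }
  potential_spec(
    kind = "dihedral_chain",
    parameters = list(n_angles = n_angles, barrier = barrier,
                      asymmetry = asymmetry),
    energy = function(x) {
      tr <- x * pi / 180
      sum((barrier / 2) * (1 - cos(2 * tr)) +
          (asymmetry / 2) * (1 - cos(tr)))
    },
    init = rep(0, n_angles), wrap = wrap_deg)
}

# ---------------------------------------------------------------------
# Patchy dimer fixture

#' Patchy two-chain dimer with explicit solvent
#'
#' Builds two identical 10-bead chains in a bound pose (interface beads
#' facing at the interaction radius) plus \code{n_solvent} soft-sphere
#' bath particles in a periodic cubic box.  Three beads per chain
#' (positions 4, 6, 8) are typed \code{"I"} and carry a deep attractive
#' cross-chain well; backbone beads are \code{"B"}; solvent is
#' \code{"W"} with weak mutual attraction so that first-shell versus
#' bulk placement is energetically meaningful.  Deterministic given
#' \code{seed}.
#'
#' @param seed integer seed for solvent placement.
#' @param n_solvent number of solvent particles (>= 0).
#' @param box cubic box side, nm; default 5 leaves more than one
#'   interaction radius of clearance around the chains.
#' @return object of class \code{dimer_system} with fields \code{xyz}
#'   (n x 3 nm), \code{type}, \code{chain} ("A"/"B"/"S"), \code{bonds},
#'   \code{interface} (global indices), \code{interaction}
#'   (depth/radius matrices, kcal/mol and nm), \code{box}, and
#'   \code{n_chain}.
#' @export
make_dimer_fixture <- function(seed, n_solvent = 0, box = 5) {
  stopifnot(n_solvent >= 0, box > 0)
  n_chain <- 10L
  spacing <- 0.38           # bead-bead bond length, nm (CA-like)
  r0 <- 0.47                # interaction radius, nm
  iface <- c(4L, 6L, 8L)

  # slight zigzag in z keeps every chain dihedral well defined
  zig <- 0.06 * (-1)^(seq_len(n_chain))
  xs <- cumsum(c(0, rep(sqrt(spacing^2 - (2 * 0.06)^2), n_chain - 1)))
  xs <- xs - mean(xs) + box / 2
  chainA <- cbind(xs, box / 2 - r0 / 2, box / 2 + zig)
  chainB <- cbind(xs, box / 2 + r0 / 2, box / 2 + zig)
  type_chain <- rep("B", n_chain)
  type_chain[iface] <- "I"

  types <- c("B", "I", "W")
  depth <- matrix(c(0.05, 0.05, 0.05,
                    0.05, 1.50, 0.20,
                    0.05, 0.20, 0.10),
                  3, 3, dimnames = list(types, types))
  radius <- matrix(r0, 3, 3, dimnames = list(types, types))

  xyz <- rbind(chainA, chainB)
  type <- c(type_chain, type_chain)
  chain <- rep(c("A", "B"), each = n_chain)

  if (n_solvent > 0) {
    s <- rng_stream(seed)
    solv <- matrix(NA_real_, n_solvent, 3)
    placed <- xyz
    with_stream(s, {
      for (i in seq_len(n_solvent)) {
        for (att in 1:2000) {
          p <- runif(3, 0, box)
          d <- .min_image_dist(placed, p, box)
          if (min(d) >= 0.25) break
        }
        solv[i, ] <- p
        placed <- rbind(placed, p)
      }
    })
    xyz <- rbind(xyz, solv)
    type <- c(type, rep("W", n_solvent))
    chain <- c(chain, rep("S", n_solvent))
  }
  dimnames(xyz) <- NULL

  angles <- .chain_angles(n_chain)
  th0 <- apply(angles, 1, function(a)
    .bend_angle(chainA[((a[1] - 1) %% n_chain) + 1, ],
                chainA[((a[2] - 1) %% n_chain) + 1, ],
                chainA[((a[3] - 1) %% n_chain) + 1, ]))

  structure(list(xyz = xyz, type = type, chain = chain,
                 bonds = .chain_bonds(n_chain),
                 angles = angles, angle_theta0 = th0, angle_k = 100,
                 interface = c(iface, iface + n_chain),
                 interaction = list(types = types, depth = depth,
                                    radius = radius),
                 box = box, n_chain = n_chain,
                 bond_length = spacing, bond_k = 1000,
                 repulsion = list(A = 20, sigma = 0.12),
                 seed = seed),
            class = "dimer_system")
}

.chain_bonds <- function(n_chain) {
  b <- cbind(1:(n_chain - 1), 2:n_chain)
  rbind(b, b + n_chain)
}

# consecutive-triple bending angles per chain; together with the bonds
# they leave torsion as the chains' only soft internal degree of
# freedom, so dihedral restraints genuinely rigidify a chain
.chain_angles <- function(n_chain) {
  a <- cbind(1:(n_chain - 2), 2:(n_chain - 1), 3:n_chain)
  rbind(a, a + n_chain)
}

.bend_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cs)))
}

.min_image_dist <- function(mat, p, box) {
  dx <- sweep(mat, 2, p)
  dx <- dx - box * round(dx / box)
  sqrt(rowSums(dx^2))
}

#' @export
print.dimer_system <- function(x, ...) {
  ns <- sum(x$chain == "S")
  cat("dimer_system: 2 x", x$n_chain, "beads,", ns, "solvent, box",
      x$box, "nm\n")
  cat("  interface beads:", paste(x$interface, collapse = " "), "\n")
  invisible(x)
}

#' Indices of solute (chain) and solvent beads
#'
#' @param system a \code{dimer_system}.
#' @return list with integer vectors \code{solute} and \code{solvent}.
#' @export
dimer_indices <- function(system) {
  list(solute = which(system$chain %in% c("A", "B")),
       solvent = which(system$chain == "S"))
}

# Truncated-and-shifted pair well: a soft Gaussian core plus a Gaussian
# attraction centred at r0 (width r0/3), shifted to zero at the cutoff
# 2 r0.  Smooth, bounded, parameterised by (depth, radius) per type pair.
.pair_well <- function(r, depth, r0, repA, repS) {
  w <- r0 / 3
  rc <- 2 * r0
  v <- repA * exp(-r^2 / (2 * repS^2)) -
       depth * exp(-(r - r0)^2 / (2 * w^2))
  vc <- repA * exp(-rc^2 / (2 * repS^2)) -
        depth * exp(-(rc - r0)^2 / (2 * w^2))
  out <- v - vc
  out[r >= rc] <- 0
  out
}

#' Potential energy of a dimer system configuration
#'
#' Sums the non-bonded pair wells (minimum image if \code{pbc}), the
#' harmonic chain bonds, and any restraint energy, optionally over a
#' subset of beads only (pairs entirely inside the subset) -- the
#' subset form is what the hybrid solvent energy evaluates.
#'
#' @param system a \code{dimer_system}.
#' @param x n x 3 coordinate matrix (defaults to the system's own).
#' @param indices optional bead subset.
#' @param pbc apply minimum-image convention (default TRUE).
#' @param restraints optional restraint list (see
#'   \code{\link{restraint_energy}}); only restraints whose beads all
#'   lie inside \code{indices} contribute.
#' @return energy in kcal/mol.
#' @export
dimer_energy <- function(system, x = system$xyz, indices = NULL,
                         pbc = TRUE, restraints = NULL) {
  n <- nrow(system$xyz)
  if (is.null(indices)) indices <- seq_len(n)
  keep <- rep(FALSE, n); keep[indices] <- TRUE
  ti <- match(system$type, system$interaction$types)
  pr <- .subset_pairs(system, indices)
  e <- 0
  if (length(pr$ii)) {
    dx <- x[pr$ii, , drop = FALSE] - x[pr$jj, , drop = FALSE]
    if (pbc) dx <- dx - system$box * round(dx / system$box)
    r <- sqrt(rowSums(dx^2))
    dep <- system$interaction$depth[cbind(ti[pr$ii], ti[pr$jj])]
    rad <- system$interaction$radius[cbind(ti[pr$ii], ti[pr$jj])]
    e <- e + sum(.pair_well(r, dep, rad, system$repulsion$A,
                            system$repulsion$sigma))
  }
  bnd <- system$bonds[keep[system$bonds[, 1]] & keep[system$bonds[, 2]], ,
                      drop = FALSE]
  if (nrow(bnd)) {
    dx <- x[bnd[, 1], , drop = FALSE] - x[bnd[, 2], , drop = FALSE]
    if (pbc) dx <- dx - system$box * round(dx / system$box)
    r <- sqrt(rowSums(dx^2))
    e <- e + sum(system$bond_k * (r - system$bond_length)^2)
  }
  if (!is.null(system$angles)) {
    ang_in <- keep[system$angles[, 1]] & keep[system$angles[, 2]] &
              keep[system$angles[, 3]]
    for (r in which(ang_in)) {
      a <- system$angles[r, ]
      th <- .bend_angle(x[a[1], ], x[a[2], ], x[a[3], ])
      e <- e + system$angle_k * (th - system$angle_theta0[r])^2
    }
  }
  if (!is.null(restraints) && length(restraints)) {
    inside <- vapply(restraints, function(rs) all(keep[rs$atoms]), TRUE)
    if (any(inside))
      e <- e + restraint_energy(x, restraints[inside])
  }
  e
}

# i<j non-bonded pairs restricted to a bead subset
.subset_pairs <- function(system, indices) {
  idx <- sort(unique(as.integer(indices)))
  m <- length(idx)
  if (m < 2) return(list(ii = integer(0), jj = integer(0)))
  cmb <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ii <- idx[cmb[, 1]]; jj <- idx[cmb[, 2]]
  bkey <- paste(system$bonds[, 1], system$bonds[, 2])
  keep <- !(paste(pmin(ii, jj), pmax(ii, jj)) %in% bkey)
  list(ii = ii[keep], jj = jj[keep])
}

#' Build a sampler-ready potential from a dimer system
#'
#' Wraps \code{\link{dimer_energy}} into a \code{potential_spec} of kind
#' \code{patchy_dimer} with an O(n) per-particle move-energy routine, so
#' the Monte Carlo propagator can sweep single-bead displacements.
#'
#' @param system a \code{dimer_system}.
#' @param restraints optional restraint list added to the potential.
#' @param pbc minimum-image convention (default TRUE).
#' @return a \code{potential_spec}.
#' @export
dimer_potential <- function(system, restraints = NULL, pbc = TRUE) {
  n <- nrow(system$xyz)
  L <- system$box
  ti <- match(system$type, system$interaction$types)
  depM <- system$interaction$depth
  radM <- system$interaction$radius
  repA <- system$repulsion$A; repS <- system$repulsion$sigma
  bk <- system$bond_k; b0 <- system$bond_length

  # per-bead non-bonded partners (bonds excluded), bond partners,
  # restraint membership
  bonded <- vector("list", n)
  for (r in seq_len(nrow(system$bonds))) {
    a <- system$bonds[r, 1]; b <- system$bonds[r, 2]
    bonded[[a]] <- c(bonded[[a]], b)
    bonded[[b]] <- c(bonded[[b]], a)
  }
  partners <- lapply(seq_len(n), function(i)
    setdiff(seq_len(n), c(i, bonded[[i]])))
  pdep <- lapply(seq_len(n), function(i) depM[cbind(ti[i], ti[partners[[i]]])])
  prad <- lapply(seq_len(n), function(i) radM[cbind(ti[i], ti[partners[[i]]])])
  amap <- if (!is.null(system$angles))
    lapply(seq_len(n), function(i)
      which(system$angles[, 1] == i | system$angles[, 2] == i |
            system$angles[, 3] == i))
  else NULL
  rmap <- if (length(restraints))
    lapply(seq_len(n), function(i)
      which(vapply(restraints, function(rs) i %in% rs$atoms, TRUE)))
  else NULL

  bead_env <- function(x, i, p) {
    js <- partners[[i]]
    dx <- sweep(x[js, , drop = FALSE], 2, p)
    if (pbc) dx <- dx - L * round(dx / L)
    r <- sqrt(rowSums(dx^2))
    e <- sum(.pair_well(r, pdep[[i]], prad[[i]], repA, repS))
    for (b in bonded[[i]]) {
      d <- p - x[b, ]
      if (pbc) d <- d - L * round(d / L)
      e <- e + bk * (sqrt(sum(d^2)) - b0)^2
    }
    if (!is.null(amap) && length(amap[[i]])) {
      xt <- x; xt[i, ] <- p
      for (r in amap[[i]]) {
        a <- system$angles[r, ]
        th <- .bend_angle(xt[a[1], ], xt[a[2], ], xt[a[3], ])
        e <- e + system$angle_k * (th - system$angle_theta0[r])^2
      }
    }
    if (!is.null(rmap) && length(rmap[[i]])) {
      xt <- x; xt[i, ] <- p
      e <- e + restraint_energy(xt, restraints[rmap[[i]]])
    }
    e
  }

  potential_spec(
    kind = "patchy_dimer",
    parameters = list(n = n, box = L, pbc = pbc,
                      n_restraints = length(restraints)),
    energy = function(x) dimer_energy(system, x, pbc = pbc,
                                      restraints = restraints),
    init = system$xyz,
    particle = TRUE,
    delta_move = function(x, i, newp)
      bead_env(x, i, newp) - bead_env(x, i, x[i, ]),
    system = system, restraints = restraints, pbc = pbc)
}

# ---------------------------------------------------------------------
# Mutations

#' Describe a per-bead mutation
#'
#' @param bead_index global bead index; must lie in chain A or B.  The
#'   edit is applied symmetrically to the same position of both chains
#'   (homodimer convention).
#' @param new_type label of the bead's new type.
#' @param depth named numeric vector: well depth of the new type against
#'   every existing type (and itself), kcal/mol.  Required when
#'   \code{new_type} is not already in the interaction matrix.
#' @param radius like \code{depth} for the interaction radius, nm;
#'   defaults to the system's common radius.
#' @return object of class \code{mutation_edit}.
#' @export
mutation_edit <- function(bead_index, new_type, depth = NULL, radius = NULL) {
  structure(list(bead_index = as.integer(bead_index), new_type = new_type,
                 depth = depth, radius = radius),
            class = "mutation_edit")
}

#' Alanine-like deletion edit: all well depths of the bead set to zero
#'
#' @param bead_index global bead index.
#' @param label type label for the neutralised bead.
#' @return a \code{mutation_edit}.
#' @export
alanine_edit <- function(bead_index, label = "A0") {
  mutation_edit(bead_index, label, depth = NA)  # NA marks "all zero"
}

#' Apply a mutation to a dimer system
#'
#' Returns a new system; the input is unchanged.  Homodimer edits are
#' applied symmetrically: the bead at the same within-chain position of
#' both chains takes the new type.  The interaction matrix is extended
#' (symmetrically) when the new type is unknown.
#'
#' @param system a \code{dimer_system}.
#' @param edit a \code{mutation_edit}.
#' @return a new \code{dimer_system}.
#' @export
apply_mutation <- function(system, edit) {
  stopifnot(inherits(system, "dimer_system"), inherits(edit, "mutation_edit"))
  i <- edit$bead_index
  nsolute <- 2L * system$n_chain
  if (i < 1L || i > nsolute)
    stop("bead index ", i, " does not exist in either chain")
  pos <- ((i - 1L) %% system$n_chain) + 1L
  out <- system
  types <- out$interaction$types
  nt <- edit$new_type
  if (!nt %in% types) {
    k <- length(types)
    dep <- out$interaction$depth
    rad <- out$interaction$radius
    if (is.null(edit$depth))
      stop("new type '", nt, "' needs a depth row")
    newdep <- if (length(edit$depth) == 1L && is.na(edit$depth))
      setNames(rep(0, k + 1L), c(types, nt))
    else edit$depth
    r0 <- rad[1, 1]
    newrad <- if (is.null(edit$radius))
      setNames(rep(r0, k + 1L), c(types, nt)) else edit$radius
    dep2 <- rbind(cbind(dep, newdep[types]), c(newdep[types], newdep[nt]))
    rad2 <- rbind(cbind(rad, newrad[types]), c(newrad[types], newrad[nt]))
    dimnames(dep2) <- dimnames(rad2) <- list(c(types, nt), c(types, nt))
    out$interaction <- list(types = c(types, nt), depth = dep2,
                            radius = rad2)
  } else if (!is.null(edit$depth) && !(length(edit$depth) == 1L &&
                                       is.na(edit$depth))) {
    dep <- out$interaction$depth
    dep[nt, names(edit$depth)] <- edit$depth
    dep[names(edit$depth), nt] <- edit$depth
    out$interaction$depth <- dep
  }
  out$type[c(pos, pos + system$n_chain)] <- nt
  out
}

# ---------------------------------------------------------------------
# Oracles and synthetic score distributions

#' Boltzmann quadrature oracle for 1D potentials
#'
#' Trapezoid quadrature of exp(-V/kT) on a uniform grid over the
#' declared domain: partition function, well populations (split at
#' \code{split}), moments, CDF and an inverse-CDF sampler.  This is the
#' independent reference all 1D sampler tests are checked against.
#'
#' @param potential a 1D \code{potential_spec}.
#' @param temperature K.
#' @param n grid points (default 10001).
#' @param split domain split point for the two well populations.
#' @return list with \code{x}, \code{density}, \code{p_low} (mass below
#'   \code{split}), \code{p_high}, \code{mean}, \code{var}, \code{cdf},
#'   and \code{quantile} (inverse CDF function).
#' @export
boltzmann_quadrature <- function(potential, temperature, n = 10001,
                                 split = 0) {
  stopifnot(length(potential$init) == 1L, is.finite(potential$lower),
            is.finite(potential$upper))
  x <- seq(potential$lower, potential$upper, length.out = n)
  v <- vapply(x, function(xx) potential$energy(xx), 0)
  w <- exp(-(v - min(v)) / kT(temperature))
  dx <- x[2] - x[1]
  tw <- w; tw[c(1, n)] <- tw[c(1, n)] / 2
  Z <- sum(tw) * dx
  dens <- w / Z
  cdf <- cumsum(tw) * dx / Z
  cdf <- pmin(cdf / cdf[n], 1)
  p_low <- sum(tw[x < split]) * dx / Z
  m1 <- sum(tw * x) * dx / Z
  m2 <- sum(tw * x^2) * dx / Z
  qf <- approxfun(cdf, x, ties = "ordered", rule = 2)
  list(x = x, density = dens, p_low = p_low, p_high = 1 - p_low,
       mean = m1, var = m2 - m1^2, cdf = cdf, quantile = qf)
}

#' Inverse-CDF samples from a quadrature oracle
#'
#' @param oracle result of \code{\link{boltzmann_quadrature}}.
#' @param n number of samples.
#' @param stream optional \code{rng_stream}.
#' @return numeric vector of n exact (up to quadrature) Boltzmann draws.
#' @export
rboltzmann <- function(oracle, n, stream = NULL) {
  u <- if (is.null(stream)) runif(n) else with_stream(stream, runif(n))
  oracle$quantile(u)
}

#' Synthetic two-basin score distribution with a designed Delta-Delta-G
#'
#' Draws 2D "principal component scores" from a two-component Gaussian
#' mixture whose component weights are set so the free-energy difference
#' between the two basin minima (equal covariances) equals
#' \code{delta_g} at temperature \code{temperature}.  Used to validate
#' Boltzmann-inversion landscapes end to end.
#'
#' @param n frames.
#' @param delta_g designed basin free-energy gap, kcal/mol (basin 2
#'   higher).
#' @param temperature K (sets kT for the weight design).
#' @param seed integer seed.
#' @param centers 2 x 2 matrix of basin centres (rows).
#' @param sigma common isotropic standard deviation.
#' @return n x 2 score matrix with attributes \code{weights},
#'   \code{centers}, \code{sigma}.
#' @export
make_two_basin_scores <- function(n, delta_g = 1.0, temperature = 280,
                                  seed = 1,
                                  centers = rbind(c(-1.5, 0), c(1.5, 0)),
                                  sigma = 0.5) {
  w1 <- exp(delta_g / kT(temperature))
  w1 <- w1 / (1 + w1)
  s <- rng_stream(seed)
  sc <- with_stream(s, {
    lab <- 1L + (runif(n) > w1)
    centers[lab, , drop = FALSE] + matrix(rnorm(2 * n, 0, sigma), n, 2)
  })
  structure(sc, weights = c(w1, 1 - w1), centers = centers, sigma = sigma)
}
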