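# Ensemble analysis: dihedral PCA (sin/cos images of the angles, so
# periodicity never bites), inter-chain pairwise-distance PCA for dimer
# poses, Boltzmann-inversion free-energy landscapes on the first two
# principal components, minimax barrier heights, and projection of a
# second (mutant) ensemble onto reference (wild-type) axes so both
# occupy one comparable landscape.

#' Dihedral PCA features
#'
#' Maps each angle theta (degrees) to the pair (cos theta, sin theta);
#' no further normalization is applied.
#'
#' @param dihedrals frames x angles matrix, degrees.
#' @return a \code{feature_matrix} with 2 x angles columns
#'   (cos1, sin1, cos2, sin2, ...).
#' @export
dpca_features <- function(dihedrals) {
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) < 2L) stop("need at least 2 frames")
  na <- ncol(dihedrals)
  rad <- dihedrals * pi / 180
  out <- matrix(NA_real_, nrow(dihedrals), 2L * na)
  out[, seq(1, 2 * na, 2)] <- cos(rad)
  out[, seq(2, 2 * na, 2)] <- sin(rad)
  colnames(out) <- as.vector(rbind(paste0("cos", seq_len(na)),
                                   paste0("sin", seq_len(na))))
  .feature_matrix(out, center = rep(0, 2 * na), scale = rep(1, 2 * na),
                  flagged = logical(2 * na), type = "dpca")
}

#' Inter-chain pairwise-distance features
#'
#' One feature per (a in chain A, b in chain B) bead pair: the
#' Euclidean (minimum-image if \code{box} given) distance.  With
#' \code{normalize = TRUE} each feature is z-scored by its ensemble
#' mean and standard deviation, which are recorded on the matrix;
#' zero-variance features are kept, scaled by 1, and flagged.
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param chain_a,chain_b bead index vectors; both non-empty.
#' @param normalize z-score the features (default TRUE).
#' @param box optional cubic box side for minimum-image distances.
#' @return a \code{feature_matrix} with |A| x |B| columns.
#' @export
interchain_distance_features <- function(frames, chain_a, chain_b,
                                         normalize = TRUE, box = NULL) {
  if (!length(chain_a) || !length(chain_b))
    stop("both chains must be non-empty")
  if (!length(frames)) stop("need at least one frame")
  pairs <- expand.grid(b = chain_b, a = chain_a)[, c("a", "b")]
  raw <- vapply(frames, function(x) {
    dx <- x[pairs$a, , drop = FALSE] - x[pairs$b, , drop = FALSE]
    if (!is.null(box)) dx <- dx - box * round(dx / box)
    sqrt(rowSums(dx^2))
  }, numeric(nrow(pairs)))
  raw <- if (is.null(dim(raw))) matrix(raw, ncol = 1) else t(raw)
  colnames(raw) <- paste0("d", pairs$a, "_", pairs$b)
  nf <- ncol(raw)
  if (normalize) {
    ctr <- colMeans(raw)
    scl <- apply(raw, 2, sd)
    flagged <- !is.finite(scl) | scl == 0
    scl[flagged] <- 1
    z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
    .feature_matrix(z, center = ctr, scale = scl, flagged = flagged,
                    type = "distance")
  } else {
    .feature_matrix(raw, center = rep(0, nf), scale = rep(1, nf),
                    flagged = logical(nf), type = "distance")
  }
}

.feature_matrix <- function(x, center, scale, flagged, type) {
  structure(x, center = center, scale = scale, flagged = flagged,
            feature_type = type, class = c("feature_matrix", "matrix",
                                           "array"))
}

#' Fit principal axes
#'
#' Mean-centred PCA (SVD via \code{stats::prcomp}) of a feature matrix;
#' components are sorted by explained variance and the sign of each is
#' fixed so its largest-magnitude loading is positive.  The per-feature
#' normalization statistics of the fitting ensemble are stored so other
#' ensembles can be projected onto the same axes.
#'
#' @param features a \code{feature_matrix}.
#' @param n_components number of axes to keep; <= feature count and
#'   < frame count.
#' @return object of class \code{principal_axes}: \code{mean},
#'   \code{components} (features x n_components, orthonormal),
#'   \code{explained_variance}, \code{center}/\code{scale}
#'   (feature normalization), \code{flagged}.
#' @export
fit_pca <- function(features, n_components = 2) {
  x <- unclass(features)
  if (n_components > ncol(x))
    stop("n_components exceeds the feature count")
  if (nrow(x) <= n_components)
    stop("need more frames than components")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  comp <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = pc$center,
                 components = comp,
                 explained_variance = pc$sdev^2,
                 center = attr(features, "center"),
                 scale = attr(features, "scale"),
                 flagged = attr(features, "flagged"),
                 n_components = n_components),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  ev <- x$explained_variance
  cat("principal_axes:", x$n_components, "components over",
      length(x$mean), "features\n")
  cat("  explained variance fraction:",
      paste(signif(ev[seq_len(x$n_components)] / sum(ev), 3),
            collapse = " "), "\n")
  invisible(x)
}

#' Project features onto reference principal axes
#'
#' The features are first brought back to their raw scale (inverting
#' their own normalization, if any), then normalized with the axes'
#' stored per-feature statistics, centred by the axes' mean, and
#' projected.  Projecting the fitting ensemble itself reproduces the
#' fit-time scores.
#'
#' @param features a \code{feature_matrix} of matching dimensionality.
#' @param axes a \code{principal_axes}.
#' @return frames x n_components score matrix.
#' @export
project <- function(features, axes) {
  x <- unclass(features)
  if (ncol(x) != length(axes$mean))
    stop("feature dimensionality (", ncol(x),
         ") does not match the axes (", length(axes$mean), ")")
  raw <- sweep(sweep(x, 2, attr(features, "scale"), "*"), 2,
               attr(features, "center"), "+")
  z <- sweep(sweep(raw, 2, axes$center), 2, axes$scale, "/")
  sweep(z, 2, axes$mean) %*% axes$components
}

#' Boltzmann-inversion free-energy landscape
#'
#' 2D histogram of the first two score columns at \code{bins} x
#' \code{bins} resolution; bin probabilities are converted to free
#' energies by Boltzmann inversion, delta G = -kT ln(p / p_max), so the
#' modal bin sits at 0.  Empty bins are masked (no pseudo-count).
#' Passing \code{axes_range} imposes reference bin edges so that, e.g.,
#' mutant landscapes share the wild-type grid; frames outside the range
#' are dropped and probabilities renormalized over the retained ones.
#'
#' @param scores frames x >=2 score matrix.
#' @param bins bins per axis; >= 2 (default 30).
#' @param kt thermal energy kcal/mol; defaults to k_B x 280 K, the
#'   baseline temperature.
#' @param axes_range optional list(x = c(lo, hi), y = c(lo, hi)).
#' @return object of class \code{tiger_landscape}: \code{xedges},
#'   \code{yedges}, \code{prob}, \code{delta_g}, \code{mask} (TRUE for
#'   empty bins), \code{kt}, \code{n} (frames binned).
#' @export
boltzmann_landscape <- function(scores, bins = 30, kt = kT(280),
                                axes_range = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) stop("need at least one frame")
  if (bins < 2L) stop("need at least 2 bins per axis")
  x <- scores[, 1]; y <- scores[, 2]
  rng <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    r + c(-1, 1) * diff(r) * 1e-8
  }
  xr <- if (is.null(axes_range)) rng(x) else axes_range$x
  yr <- if (is.null(axes_range)) rng(y) else axes_range$y
  xe <- seq(xr[1], xr[2], length.out = bins + 1L)
  ye <- seq(yr[1], yr[2], length.out = bins + 1L)
  ix <- findInterval(x, xe, rightmost.closed = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= bins & iy >= 1L & iy <= bins
  counts <- matrix(0, bins, bins)
  if (any(ok)) {
    tb <- table(factor(ix[ok], levels = seq_len(bins)),
                factor(iy[ok], levels = seq_len(bins)))
    counts <- matrix(as.numeric(tb), bins, bins)
  }
  n_in <- sum(counts)
  if (n_in == 0) stop("no frames fall inside the imposed axes range")
  prob <- counts / n_in
  mask <- counts == 0
  dg <- matrix(NA_real_, bins, bins)
  pmax_ <- max(prob)
  dg[!mask] <- -kt * log(prob[!mask] / pmax_)
  structure(list(xedges = xe, yedges = ye, prob = prob, delta_g = dg,
                 mask = mask, kt = kt, n = n_in,
                 n_total = nrow(scores)),
            class = "tiger_landscape")
}

#' @export
print.tiger_landscape <- function(x, ...) {
  b <- nrow(x$prob)
  cat("tiger_landscape:", b, "x", b, "bins,", x$n, "frames,",
      sum(!x$mask), "occupied bins, kT =", signif(x$kt, 4),
      "kcal/mol\n")
  invisible(x)
}

#' Modal (global-minimum) bin of a landscape
#'
#' @param landscape a \code{tiger_landscape}.
#' @return integer c(row, col) of the bin with delta G = 0.
#' @export
landscape_min_bin <- function(landscape) {
  which(landscape$delta_g == 0, arr.ind = TRUE)[1, ]
}

#' Occupancy of one landscape bin by a score set
#'
#' Fraction of frames whose first two scores fall in the given bin of
#' the landscape's grid.
#'
#' @param scores frames x >=2 score matrix.
#' @param landscape reference \code{tiger_landscape} (its edges are
#'   used).
#' @param bin integer c(row, col).
#' @return fraction in [0, 1] of all supplied frames.
#' @export
score_occupancy <- function(scores, landscape, bin) {
  scores <- as.matrix(scores)
  ix <- findInterval(scores[, 1], landscape$xedges,
                     rightmost.closed = TRUE)
  iy <- findInterval(scores[, 2], landscape$yedges,
                     rightmost.closed = TRUE)
  mean(ix == bin[1] & iy == bin[2])
}

#' Free-energy minima of the two halves of a landscape
#'
#' Minimum delta G among unmasked bins whose first-axis bin centre lies
#' below/above \code{split}; the difference recovers a designed basin
#' free-energy gap.
#'
#' @param landscape a \code{tiger_landscape}.
#' @param split first-axis dividing value (default 0).
#' @return named vector c(low, high), kcal/mol.
#' @export
landscape_basin_minima <- function(landscape, split = 0) {
  b <- nrow(landscape$prob)
  cx <- (landscape$xedges[-1] + landscape$xedges[-(b + 1)]) / 2
  low <- landscape$delta_g[cx < split, , drop = FALSE]
  high <- landscape$delta_g[cx >= split, , drop = FALSE]
  c(low = min(low, na.rm = TRUE), high = min(high, na.rm = TRUE))
}

#' Minimax barrier height between two landscape bins
#'
#' Over all 8-connected paths through unmasked bins from \code{bin_a}
#' to \code{bin_b}, the minimum of the maximum delta G along the path,
#' minus delta G at \code{bin_a}.  Signals an error when no unmasked
#' path exists (disconnected basins).
#'
#' @param landscape a \code{tiger_landscape}.
#' @param bin_a,bin_b integer c(row, col); both unmasked.
#' @return barrier in kcal/mol (0 when \code{bin_a == bin_b}).
#' @export
barrier_height <- function(landscape, bin_a, bin_b) {
  dg <- landscape$delta_g
  nr <- nrow(dg); nc <- ncol(dg)
  a_id <- (bin_a[2] - 1L) * nr + bin_a[1]
  b_id <- (bin_b[2] - 1L) * nr + bin_b[1]
  if (landscape$mask[bin_a[1], bin_a[2]] ||
      landscape$mask[bin_b[1], bin_b[2]])
    stop("both endpoint bins must be unmasked")
  if (a_id == b_id) return(0)
  n <- nr * nc
  best <- rep(Inf, n)
  done <- rep(FALSE, n)
  best[a_id] <- dg[bin_a[1], bin_a[2]]
  repeat {
    vals <- ifelse(done, Inf, best)
    u <- which.min(vals)
    if (!is.finite(vals[u])) stop("disconnected basins: no unmasked path")
    if (u == b_id) return(best[u] - dg[bin_a[1], bin_a[2]])
    done[u] <- TRUE
    ui <- ((u - 1L) %% nr) + 1L; uj <- ((u - 1L) %/% nr) + 1L
    for (di in -1:1) for (dj in -1:1) {
      vi <- ui + di; vj <- uj + dj
      if ((di == 0 && dj == 0) || vi < 1L || vi > nr || vj < 1L ||
          vj > nc)
        next
      if (landscape$mask[vi, vj]) next
      v <- (vj - 1L) * nr + vi
      cand <- max(best[u], dg[vi, vj])
      if (cand < best[v]) best[v] <- cand
    }
  }
}
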