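# Independent oracles used across the suite.  Each is deliberately a
# different route from the implementation it checks: plain trapezoid
# integration, covariance eigendecomposition, exhaustive path
# enumeration, threshold flood-fill connectivity, and O(n m) distance
# sorting.

# trapezoid quadrature of exp(-V/kT), written independently of
# boltzmann_quadrature()
oracle_well_populations <- function(vfun, temperature, lower, upper,
                                    n = 10000, split = 0) {
  kt <- 0.0019872041 * temperature
  x <- seq(lower, upper, length.out = n)
  w <- exp(-vapply(x, vfun, 0) / kt)
  dx <- x[2] - x[1]
  tw <- w; tw[c(1, n)] <- tw[c(1, n)] / 2
  z <- sum(tw) * dx
  c(p_low = sum(tw[x < split]) * dx / z,
    mean = sum(tw * x) * dx / z,
    var = sum(tw * x^2) * dx / z - (sum(tw * x) * dx / z)^2)
}

# covariance eigendecomposition PCA oracle
oracle_pca <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / (nrow(x) - 1)
  eigen(C, symmetric = TRUE)
}

# minimax barrier via exhaustive simple-path enumeration (small grids)
oracle_barrier_paths <- function(dg, mask, a, b) {
  nr <- nrow(dg); nc <- ncol(dg)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(i, j, mx) {
    mx <- max(mx, dg[i, j])
    if (mx >= best) return(invisible(NULL))
    if (i == b[1] && j == b[2]) { best <<- mx; return(invisible(NULL)) }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- i + di; vj <- j + dj
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (mask[vi, vj] || visited[vi, vj]) next
      dfs(vi, vj, mx)
    }
    visited[i, j] <<- FALSE
  }
  dfs(a[1], a[2], -Inf)
  best - dg[a[1], a[2]]
}

# minimax barrier via threshold flood-fill connectivity: the barrier
# level is the smallest delta G level t such that a and b are connected
# through unmasked bins with delta G <= t
oracle_barrier_threshold <- function(dg, mask, a, b) {
  lv <- sort(unique(dg[!mask]))
  lv <- lv[lv >= max(dg[a[1], a[2]], dg[b[1], b[2]])]
  nr <- nrow(dg); nc <- ncol(dg)
  for (t in lv) {
    open <- !mask & dg <= t
    if (!open[a[1], a[2]] || !open[b[1], b[2]]) next
    # BFS from a
    reach <- matrix(FALSE, nr, nc)
    reach[a[1], a[2]] <- TRUE
    queue <- list(a)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        vi <- p[1] + di; vj <- p[2] + dj
        if ((di == 0 && dj == 0) || vi < 1 || vi > nr || vj < 1 ||
            vj > nc) next
        if (open[vi, vj] && !reach[vi, vj]) {
          reach[vi, vj] <- TRUE
          queue[[length(queue) + 1L]] <- c(vi, vj)
        }
      }
    }
    if (reach[b[1], b[2]]) return(t - dg[a[1], a[2]])
  }
  Inf
}

# brute-force O(n m) nearest-solute shell selection
oracle_shell <- function(solute, solvent, n, box = NULL) {
  d <- vapply(seq_len(nrow(solvent)), function(i) {
    dd <- Inf
    for (j in seq_len(nrow(solute))) {
      dx <- solute[j, ] - solvent[i, ]
      if (!is.null(box)) dx <- dx - box * round(dx / box)
      dd <- min(dd, sqrt(sum(dx^2)))
    }
    dd
  }, 0)
  order(d, seq_len(nrow(solvent)))[seq_len(n)]
}

# wrap a bare delta-G grid as a landscape object for barrier tests
fake_landscape <- function(dg, mask = NULL, kt = kT(280)) {
  if (is.null(mask)) mask <- !is.finite(dg)
  dg[mask] <- NA_real_
  b <- nrow(dg)
  structure(list(xedges = 0:b, yedges = 0:b,
                 prob = matrix(1 / sum(!mask), b, ncol(dg)),
                 delta_g = dg, mask = mask, kt = kt, n = 1L,
                 n_total = 1L),
            class = "tiger_landscape")
}

# effective-sample-size-aware standard error of a binary sequence,
# via batch means
batch_se <- function(x, n_batch = 25) {
  n <- length(x)
  bs <- floor(n / n_batch)
  m <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(m) / sqrt(n_batch)
}
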