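# Analysis stack: feature construction, PCA against the eigen oracle,
# cross-ensemble projection, Boltzmann inversion, and minimax barriers
# against exhaustive oracles.

test_that("dPCA features are the unit-circle images of the angles", {
  d <- rbind(c(0, 90, 180), c(360, -90, 45))
  f <- dpca_features(d)
  expect_identical(ncol(f), 6L)
  expect_equal(f[1, 1:2], c(cos1 = 1, sin1 = 0), tolerance = 1e-12)
  expect_equal(f[1, 3:4], c(cos2 = 0, sin2 = 1), tolerance = 1e-12)
  # theta and theta + 360 are the same feature
  expect_equal(unname(f[2, 1:2]), c(1, 0), tolerance = 1e-12)
  f5 <- dpca_features(matrix(runif(20, -180, 180), 4, 5))
  expect_identical(ncol(f5), 10L)
  expect_error(dpca_features(matrix(0, 1, 3)), "2 frames")
})

test_that("inter-chain distances match hand-computed values and z-scoring", {
  fr <- list(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                   c(0, 0, 2), c(1, 1, 1), c(3, 0, 0)),
             rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                   c(0, 0, 1), c(2, 0, 0), c(0, 3, 0)))
  f <- interchain_distance_features(fr, 1:3, 4:6, normalize = FALSE)
  expect_identical(ncol(f), 9L)
  expect_equal(unname(f[1, 1]), 2)                    # bead1 - bead4
  expect_equal(unname(f[1, 2]), sqrt(3))              # bead1 - bead5
  expect_equal(unname(f[2, 3]), 3)                    # bead1 - bead6
  expect_equal(unname(f[2, 1]), 1)
  fz <- interchain_distance_features(fr, 1:3, 4:6, normalize = TRUE)
  expect_equal(unname(colMeans(fz)), rep(0, 9), tolerance = 1e-12)
  keep <- !attr(fz, "flagged")
  expect_equal(unname(apply(fz[, keep], 2, sd)),
               rep(1, sum(keep)), tolerance = 1e-12)
  # a zero-variance feature is kept, unit-scaled and flagged
  fr2 <- list(rbind(c(0, 0, 0), c(0, 0, 1)),
              rbind(c(1, 0, 0), c(1, 0, 1)))
  fz2 <- interchain_distance_features(fr2, 1, 2, normalize = TRUE)
  expect_true(attr(fz2, "flagged")[1])
  expect_equal(unname(attr(fz2, "scale")[1]), 1)
})

test_that("fit_pca matches the covariance eigendecomposition oracle", {
  st <- rng_stream(3)
  for (p in c(3, 5, 6)) {
    x <- with_stream(st, {
      A <- matrix(rnorm(p * p), p)
      matrix(rnorm(60 * p), 60) %*% A
    })
    fm <- structure(x, center = rep(0, p), scale = rep(1, p),
                    flagged = logical(p),
                    class = c("feature_matrix", "matrix", "array"))
    ax <- fit_pca(fm, p)
    ref <- oracle_pca(x)
    expect_equal(ax$explained_variance, ref$values, tolerance = 1e-8)
    for (j in seq_len(p))   # subspaces aligned up to sign
      expect_equal(abs(sum(ax$components[, j] * ref$vectors[, j])), 1,
                   tolerance = 1e-6)
    # orthonormal to 1e-8, variances non-increasing
    expect_equal(crossprod(ax$components), diag(p), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(ax$explained_variance) <= 1e-10))
    # sign convention: dominant loading positive
    for (j in seq_len(p))
      expect_gt(ax$components[which.max(abs(ax$components[, j])), j], 0)
  }
})

test_that("PCA degenerate geometries behave as expected", {
  st <- rng_stream(9)
  # isotropic Gaussian: explained variances equal within sampling error
  x <- with_stream(st, matrix(rnorm(4000 * 3), 4000, 3))
  fm <- structure(x, center = rep(0, 3), scale = rep(1, 3),
                  flagged = logical(3),
                  class = c("feature_matrix", "matrix", "array"))
  ax <- fit_pca(fm, 3)
  expect_lt(diff(range(ax$explained_variance)) /
            mean(ax$explained_variance), 0.2)
  # rank-1 data: first component carries > 99.9% of the variance
  t1 <- with_stream(st, rnorm(500))
  x1 <- cbind(t1, 2 * t1, -t1) + 1e-6
  fm1 <- structure(x1, center = rep(0, 3), scale = rep(1, 3),
                   flagged = logical(3),
                   class = c("feature_matrix", "matrix", "array"))
  ax1 <- fit_pca(fm1, 3)
  expect_gt(ax1$explained_variance[1] / sum(ax1$explained_variance),
            0.999)
  # full basis reconstructs the centred data
  sc <- project(fm, ax)
  rec <- sc %*% t(ax$components)
  expect_equal(rec, sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(fm, 4), "exceeds")
})

test_that("projection is self-consistent, linear and dimension-checked", {
  st <- rng_stream(15)
  x <- with_stream(st, matrix(rnorm(200 * 4), 200, 4))
  fm <- structure(x, center = rep(0, 4), scale = rep(1, 4),
                  flagged = logical(4),
                  class = c("feature_matrix", "matrix", "array"))
  ax <- fit_pca(fm, 2)
  sc <- project(fm, ax)
  pc <- prcomp(x, center = TRUE)
  # same scores as fit time, up to the fixed sign convention
  for (j in 1:2)
    expect_equal(abs(cor(sc[, j], pc$x[, j])), 1, tolerance = 1e-8)
  # constant shift in feature space projects to a constant score shift
  shift <- c(1, -2, 0.5, 3)
  fm2 <- structure(sweep(x, 2, shift, "+"), center = rep(0, 4),
                   scale = rep(1, 4), flagged = logical(4),
                   class = c("feature_matrix", "matrix", "array"))
  sc2 <- project(fm2, ax)
  expect_equal(sc2 - sc,
               matrix(rep(shift %*% ax$components, each = 200), 200),
               tolerance = 1e-8, ignore_attr = TRUE)
  fm3 <- structure(x[, 1:3], center = rep(0, 3), scale = rep(1, 3),
                   flagged = logical(3),
                   class = c("feature_matrix", "matrix", "array"))
  expect_error(project(fm3, ax), "dimensionality")
})

test_that("projection undoes its own normalization before applying the reference's", {
  fr <- lapply(1:50, function(k)
    rbind(c(0, 0, 0), c(0.1 * k, 0, 0), c(0, 1, 0), c(1, 1, 0.05 * k)))
  raw <- interchain_distance_features(fr, 1:2, 3:4, normalize = FALSE)
  nrm <- interchain_distance_features(fr, 1:2, 3:4, normalize = TRUE)
  ax <- fit_pca(nrm, 2)
  expect_equal(project(raw, ax), project(nrm, ax), tolerance = 1e-8)
})

test_that("Boltzmann inversion satisfies its defining identities", {
  # degenerate histogram: a single occupied bin
  one <- matrix(c(0.5, 0.5), 1, 2)
  ls1 <- boltzmann_landscape(rbind(one, one), bins = 5)
  expect_equal(sum(ls1$prob[!ls1$mask]), 1, tolerance = 1e-12)
  expect_equal(ls1$delta_g[!ls1$mask], 0)
  expect_identical(sum(!ls1$mask), 1L)

  # a bin with half the modal probability sits at kT ln 2
  sc <- rbind(matrix(rep(c(0.1, 0.1), 200), ncol = 2, byrow = TRUE),
              matrix(rep(c(0.9, 0.9), 100), ncol = 2, byrow = TRUE))
  ls2 <- boltzmann_landscape(sc, bins = 2, kt = kT(300))
  expect_equal(max(ls2$delta_g, na.rm = TRUE), kT(300) * log(2),
               tolerance = 1e-12)
  expect_equal(kT(300) * log(2), 0.4132, tolerance = 1e-3)

  # default resolution: 30 x 30 = 900 cells, mass conserved, min = 0
  st <- rng_stream(33)
  sc3 <- with_stream(st, matrix(rnorm(4000), ncol = 2))
  ls3 <- boltzmann_landscape(sc3)
  expect_identical(dim(ls3$prob), c(30L, 30L))
  expect_identical(length(ls3$prob), 900L)
  expect_equal(sum(ls3$prob[!ls3$mask]), 1, tolerance = 1e-12)
  expect_equal(min(ls3$delta_g[!ls3$mask]), 0)
  expect_error(boltzmann_landscape(sc3, bins = 1), "2 bins")
})

test_that("imposed axis ranges give shared grids and renormalized mass", {
  st <- rng_stream(44)
  a <- with_stream(st, matrix(rnorm(2000, 0, 1), ncol = 2))
  b <- with_stream(st, matrix(rnorm(2000, 2, 1), ncol = 2))
  lsa <- boltzmann_landscape(a, bins = 10)
  rng <- list(x = range(lsa$xedges), y = range(lsa$yedges))
  lsb <- boltzmann_landscape(b, bins = 10, axes_range = rng)
  expect_identical(lsa$xedges, lsb$xedges)
  expect_equal(sum(lsb$prob[!lsb$mask]), 1, tolerance = 1e-12)
  expect_lt(lsb$n, nrow(b))   # out-of-range frames dropped
})

test_that("minimax barriers agree with exhaustive path enumeration", {
  st <- rng_stream(21)
  # small grids: every simple path enumerated
  for (rep in 1:6) {
    dg <- with_stream(st, matrix(runif(9, 0, 5), 3, 3))
    dg[1, 1] <- 0
    mask <- matrix(FALSE, 3, 3)
    mask[2, 2] <- TRUE
    ls <- fake_landscape(dg, mask)
    a <- c(1, 1); b <- c(3, 3)
    expect_equal(barrier_height(ls, a, b),
                 oracle_barrier_paths(ls$delta_g, mask, a, b),
                 tolerance = 1e-12)
  }
  # larger random grids: exact threshold flood-fill oracle
  for (rep in 1:4) {
    dg <- with_stream(st, matrix(runif(100, 0, 4), 10, 10))
    mask <- with_stream(st, matrix(runif(100) < 0.1, 10, 10))
    dg[1, 1] <- 0; mask[1, 1] <- FALSE; mask[10, 10] <- FALSE
    ls <- fake_landscape(dg, mask)
    got <- tryCatch(barrier_height(ls, c(1, 1), c(10, 10)),
                    error = function(e) Inf)
    expect_equal(got, oracle_barrier_threshold(dg, mask, c(1, 1),
                                               c(10, 10)),
                 tolerance = 1e-10)
  }
  # single-path 1D landscape: 0 -> 2 -> 1 gives a barrier of 2
  dg1 <- matrix(c(0, 2, 1), 1, 3)
  ls1 <- fake_landscape(dg1, matrix(FALSE, 1, 3))
  expect_equal(barrier_height(ls1, c(1, 1), c(1, 3)), 2)
  expect_equal(barrier_height(ls1, c(1, 1), c(1, 1)), 0)
  # disconnected basins signal an error
  dg2 <- matrix(0, 1, 3)
  m2 <- matrix(c(FALSE, TRUE, FALSE), 1, 3)
  expect_error(barrier_height(fake_landscape(dg2, m2), c(1, 1),
                              c(1, 3)),
               "disconnected")
})

test_that("barrier asymmetry equals the endpoint free-energy difference", {
  st <- rng_stream(27)
  for (rep in 1:10) {
    dg <- with_stream(st, matrix(runif(100, 0, 4), 10, 10))
    mask <- with_stream(st, matrix(runif(100) < 0.15, 10, 10))
    dg[1, 1] <- 0; mask[1, 1] <- FALSE; mask[10, 10] <- FALSE
    ls <- fake_landscape(dg, mask)
    ab <- tryCatch(barrier_height(ls, c(1, 1), c(10, 10)),
                   error = function(e) NA)
    if (is.na(ab)) next
    ba <- barrier_height(ls, c(10, 10), c(1, 1))
    expect_equal(ab - ba, dg[10, 10] - dg[1, 1], tolerance = 1e-10)
  }
})

test_that("a designed basin free-energy gap is recovered by inversion", {
  sc <- make_two_basin_scores(2e4, delta_g = 1.0, temperature = 280,
                              seed = 7)
  ls <- boltzmann_landscape(sc, bins = 30, kt = kT(280),
                            axes_range = list(x = c(-3.2, 3.2),
                                              y = c(-1.8, 1.8)))
  gap <- landscape_basin_minima(ls)
  expect_lt(abs((gap["high"] - gap["low"]) - 1.0), 0.25)
})
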