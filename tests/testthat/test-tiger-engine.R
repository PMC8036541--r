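# Exchange schedulers: ladder construction, closed-form acceptance,
# rung conservation, determinism, baseline-ensemble semantics, and the
# exact T-REMD Boltzmann check.

make_states <- function(energies, potential, seed = 1) {
  lapply(seq_along(energies), function(i) {
    st <- replica_state(potential$init, i - 1L, potential,
                       rng_stream(derive_seed(seed, i)))
    st$energy <- energies[i]
    st$id <- i
    st
  })
}

flat <- potential_spec("harmonic_nd", list(), function(x) 0, init = 0)

test_that("temperature ladders are geometric with exact endpoints", {
  l1 <- build_ladder(280, 600, 64)
  expect_equal(l1$temps[1], 280)
  expect_equal(l1$temps[64], 600)
  l2 <- build_ladder(280, 450, 11)
  expect_identical(l2$m, 11L)
  expect_equal(range(l2$temps), c(280, 450))
  r <- 1.17
  l3 <- build_ladder(300, 300 * r^3, 4)
  expect_equal(diff(log(l3$temps)), rep(log(r), 3), tolerance = 1e-12)
  expect_error(build_ladder(280, 600, 1), "at least 2")
  expect_error(build_ladder(-1, 600, 4), "0 < t_min")
  expect_error(build_ladder(600, 280, 4), "0 < t_min")
})

test_that("T-REMD neighbour exchange follows the Metropolis closed form", {
  lad <- build_ladder(280, 600, 4)
  # equal energies: every attempted swap accepted with probability 1
  sts <- make_states(rep(3.2, 4), flat)
  ex <- tremd_exchange(sts, lad, parity = 0, rng_stream(2))
  expect_true(all(ex$decisions$p == 1))
  expect_true(all(ex$decisions$accepted))
  # rung multiset conserved
  expect_identical(sort(vapply(ex$states, function(s) s$rung, 0L)), 0:3)

  # an unfavourable pair with delta-beta * delta-E = -ln 2 accepts at 0.5
  lad2 <- build_ladder(280, 560, 2)
  dbeta <- 1 / kT(280) - 1 / kT(560)
  dE <- log(2) / dbeta          # E_low - E_high, chosen unfavourable
  sts2 <- make_states(c(5 - dE, 5), flat)
  s <- rng_stream(31)
  acc <- logical(1e4)
  for (i in seq_len(1e4))
    acc[i] <- tremd_exchange(sts2, lad2, 0, s)$decisions$accepted
  expect_equal(tremd_exchange(sts2, lad2, 0, s)$decisions$p, 0.5,
               tolerance = 1e-12)
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("TIGER exchange chains the winner and reassigns rungs by energy rank", {
  # all energies equal: every attempt accepted, one displaced frame per
  # candidate
  sts <- make_states(rep(1.5, 5), flat)
  ex <- tiger_exchange(sts, rep(1.5, 5), 280, rng_stream(7))
  expect_length(ex$accepted, 4L)
  expect_true(all(ex$decisions$p == 1))
  expect_identical(sort(vapply(ex$states, function(s) s$rung, 0L)), 0:4)
  expect_identical(ex$baseline_from_rung, 4L)

  # downhill candidates are certain
  sts2 <- make_states(c(2, 1), flat)
  ex2 <- tiger_exchange(sts2, c(2, 1), 280, rng_stream(8))
  expect_equal(ex2$decisions$p, 1)
  expect_true(ex2$decisions$accepted)

  # a candidate uphill by kT ln 2 accepts at exactly one half
  dE <- kT(280) * log(2)
  s <- rng_stream(9)
  sts3 <- make_states(c(0, dE), flat)
  expect_equal(tiger_exchange(sts3, c(0, dE), 280, s)$decisions$p, 0.5,
               tolerance = 1e-12)
  acc <- vapply(seq_len(1e4), function(i)
    tiger_exchange(sts3, c(0, dE), 280, s)$decisions$accepted, TRUE)
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 1e4))

  # energy-rank reassignment: lowest quenched energy to rung 1
  e <- c(5, 9, 2, 7)
  sts4 <- make_states(e, flat)
  s4 <- rng_stream(10)
  ex4 <- tiger_exchange(sts4, e, 280, s4)
  non_base <- vapply(ex4$states[-1], function(st) st$id, 0L)
  expect_identical(non_base,
                   setdiff(order(e), ex4$states[[1]]$id))
  expect_error(tiger_exchange(sts4, e[-1], 280, s4), "mismatched")
})

test_that("rung occupancy is conserved through random exchange sequences", {
  s <- rng_stream(77)
  for (rep in 1:50) {
    e <- with_stream(s, rnorm(6, 0, 2))
    sts <- make_states(e, flat, seed = rep)
    ex <- tiger_exchange(sts, e, 280, s)
    expect_identical(sort(vapply(ex$states, function(st) st$rung, 0L)),
                     0:5)
    expect_identical(sort(vapply(ex$states, function(st) st$id, 0L)),
                     1:6)
  }
})

test_that("a degenerate flat system accepts everything: ensemble size = cycles x replicas", {
  lad <- build_ladder(280, 600, 5)
  sch <- cycle_schedule(2, 1, 0.1)
  ens <- run_protocol("tiger2", flat, lad, sch, n_cycles = 12,
                      master_seed = 3, burnin_cycles = 2)
  expect_length(ens$frames, 12L * 5L)
  expect_true(all(ens$exchanges$p == 1))
})

test_that("runs are bit-reproducible from the master seed", {
  dw <- make_double_well(2, 0.8)
  lad <- build_ladder(280, 600, 4)
  sch <- cycle_schedule(5, 3, 0.3)
  e1 <- run_protocol("tiger2", dw, lad, sch, 40, master_seed = 99,
                     burnin_cycles = 5)
  e2 <- run_protocol("tiger2", dw, lad, sch, 40, master_seed = 99,
                     burnin_cycles = 5)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$exchanges, e2$exchanges)
  expect_identical(e1$info, e2$info)
  e3 <- run_protocol("tiger2", dw, lad, sch, 40, master_seed = 100,
                     burnin_cycles = 5)
  expect_false(identical(e1$frames, e3$frames))
})

test_that("T-REMD baseline ensemble is Boltzmann at the baseline temperature", {
  dw <- make_double_well(2, 0.8)
  q <- boltzmann_quadrature(dw, 280)
  lad <- build_ladder(280, 600, 8)
  sch <- cycle_schedule(20, 0, 0.3)
  ens <- run_protocol("tremd", dw, lad, sch, n_cycles = 2500,
                      master_seed = 17, burnin_cycles = 250)
  x <- ensemble_matrix(ens)[, 1]
  occ <- x < 0
  se <- batch_se(occ)
  expect_lt(abs(mean(occ) - q$p_low), 3 * se)
  ref <- rboltzmann(q, 2500, rng_stream(55))
  ks <- suppressWarnings(stats::ks.test(x[seq(1, length(x), by = 3)],
                                        ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("TIGER2 preserves an exact symmetry of the target", {
  dw <- make_double_well(2, 0)
  lad <- build_ladder(280, 600, 8)
  sch <- cycle_schedule(20, 10, 0.3)
  ens <- run_protocol("tiger2", dw, lad, sch, n_cycles = 1200,
                      master_seed = 23, burnin_cycles = 120)
  x <- ensemble_matrix(ens)[, 1]
  occ <- x < 0
  se <- batch_se(occ)
  expect_lt(abs(mean(occ) - 0.5), 3 * se)
})

test_that("replica temperature traces visit the whole ladder", {
  hm <- make_harmonic(k = 1, d = 1)
  lad <- build_ladder(280, 600, 5)
  sch <- cycle_schedule(5, 3, 0.3)
  ens <- run_protocol("tiger2", hm, lad, sch, n_cycles = 300,
                      master_seed = 2, burnin_cycles = 20)
  tr <- ens$replica_trace
  for (id in 1:5) {
    expect_true(any(tr[, 1] == id))          # touched the baseline rung
    expect_true(any(tr[, 5] == id))          # touched the top rung
  }
})

test_that("protocol/system incompatibilities are rejected", {
  dw <- make_double_well(1, 0)
  lad <- build_ladder(280, 600, 4)
  sch <- cycle_schedule(2, 1, 0.1)
  expect_error(run_protocol("tiger2hs", dw, lad, sch, 2, 1),
               "dimer_system")
  vac <- make_dimer_fixture(1, 0)
  expect_error(run_protocol("tiger2hs", vac, lad, sch, 2, 1),
               "solvent")
  wet <- make_dimer_fixture(1, 5)
  expect_error(run_protocol("tiger2hs", wet, lad, sch, 2, 1,
                            shell = shell_spec(0.4, 10)),
               "exceeds")
})
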