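# The exact CTMC oracle and the event-driven simulator are developed
# independently and cross-checked here on lattices small enough to
# enumerate.

test_that("exact oracle reproduces hand-solved chains", {
  # n=2, s=1, all rates 1: states (00,10,01,11) have stationary probabilities
  # (1/5, 2/5, 1/5, 1/5); flux = P(site 2 occupied) * 1 = 2/5
  g <- gene_model("tiny", c(1, 1), 1, footprint = 1)
  ex <- exact_small_lattice_rate(g, details = TRUE)
  expect_equal(ex$rate, 0.4, tolerance = 1e-12)
  expect_equal(ex$mean_ribosomes, 1.0, tolerance = 1e-12)

  # n=3, s=2, rates 1, lambda0=1: 5-state chain with stationary weights
  # (1,2,2,1,1)/7 over ({}, {1}, {2}, {3}, {1,3}); flux = (1+1)/7
  g2 <- gene_model("tiny2", c(1, 1, 1), 1, footprint = 2)
  expect_equal(exact_small_lattice_rate(g2), 2 / 7, tolerance = 1e-12)

  # initiation-limited: flux -> lambda0 as lambda0 -> 0
  g3 <- gene_model("lim", c(1, 1), 1e-4, footprint = 1)
  expect_equal(exact_small_lattice_rate(g3), 1e-4, tolerance = 1e-3)

  expect_error(exact_small_lattice_rate(
    gene_model("big", rep(1, 30), 1, footprint = 1), max_states = 100),
    "state space too large")
})

test_that("simulator agrees with the exact oracle on random small instances", {
  set.seed(4)
  hits <- 0L
  for (i in 1:5) {
    n <- sample(6:12, 1)
    s <- sample(1:3, 1)
    g <- gene_model(paste0("r", i), runif(n, 0.5, 2), runif(1, 0.1, 2),
                    footprint = s)
    ex <- exact_small_lattice_rate(g)
    r <- simulate_tasep(g, sim_config(seed = i, replicates = 10,
                                      burn_in_terminations = 1000,
                                      measure_terminations = 3000))
    hits <- hits + (abs(r$tr_mean - ex) <= r$tr_ci95)
  }
  expect_gte(hits, 4L)
})

test_that("event accounting conserves ribosomes and exclusion holds", {
  g <- uniform_gene(60, lambda0 = 0.5)
  r <- simulate_tasep(g, fast_cfg(seed = 3, replicates = 5,
                                  check_exclusion = TRUE))
  with(r$replicates,
       expect_equal(init_total, term_total + bound_at_end))
  expect_true(all(r$replicates$tr > 0))
  expect_true(r$mean_ribosomes >= 0 && r$mean_ribosomes <= 60 / 9)
})

test_that("occupancy profile is a per-codon fraction in [0, 1]", {
  g <- uniform_gene(40, lambda0 = 1)
  r <- simulate_tasep(g, fast_cfg(seed = 5, collect_occupancy = TRUE))
  expect_length(r$occupancy, 40L)
  expect_true(all(r$occupancy >= 0 & r$occupancy <= 1))
  # dense traffic: most codons covered a substantial fraction of the time
  expect_gt(mean(r$occupancy), 0.3)
})

test_that("simulation is bit-reproducible and replicate-count invariant", {
  g <- uniform_gene(80, lambda0 = 0.2)
  r1 <- simulate_tasep(g, fast_cfg(seed = 11, replicates = 3))
  r2 <- simulate_tasep(g, fast_cfg(seed = 11, replicates = 3))
  expect_identical(r1$replicates$tr, r2$replicates$tr)
  # replicate k does not depend on how many replicates are requested
  r5 <- simulate_tasep(g, fast_cfg(seed = 11, replicates = 5))
  expect_identical(r1$replicates$tr, r5$replicates$tr[1:3])
  # a different seed gives a different trajectory
  r3 <- simulate_tasep(g, fast_cfg(seed = 12, replicates = 3))
  expect_false(identical(r1$replicates$tr, r3$replicates$tr))
})

test_that("translation rate approaches lambda0 at low initiation and saturates", {
  g <- uniform_gene(500, lambda0 = 0.01)
  r <- simulate_tasep(g, fast_cfg(seed = 2, replicates = 6, terms = 1000))
  expect_lt(abs(r$tr_mean - 0.01) / 0.01, 0.12)
  # saturation: pushing lambda0 beyond the maximal-current point changes
  # nothing within CI
  g10 <- uniform_gene(500, lambda0 = 10)
  g40 <- uniform_gene(500, lambda0 = 40)
  r10 <- simulate_tasep(g10, fast_cfg(seed = 6, replicates = 5, terms = 1500))
  r40 <- simulate_tasep(g40, fast_cfg(seed = 7, replicates = 5, terms = 1500))
  expect_lt(abs(r40$tr_mean - r10$tr_mean),
            2 * (r10$tr_ci95 + r40$tr_ci95))
})

test_that("hitting max_time flags the result as low confidence", {
  g <- uniform_gene(50, lambda0 = 0.05)
  r <- simulate_tasep(g, sim_config(seed = 1, replicates = 2,
                                    measure_terminations = 100000,
                                    max_time = 2000))
  expect_true(r$low_confidence)
  expect_true(all(r$replicates$low_confidence))
  expect_true(is.finite(r$tr_mean)) # still returns the partial estimate
})

test_that("mean ribosome count matches the exact chain and is monotone", {
  g <- gene_model("tiny", c(1, 1), 1, footprint = 1)
  m <- estimate_mean_ribosomes(g, fast_cfg(seed = 8, replicates = 6,
                                           terms = 3000))
  expect_equal(m, 1.0, tolerance = 0.03)
  lo <- estimate_mean_ribosomes(uniform_gene(100, lambda0 = 0.01),
                                fast_cfg(seed = 9))
  hi <- estimate_mean_ribosomes(uniform_gene(100, lambda0 = 10),
                                fast_cfg(seed = 9))
  expect_gt(hi, lo)
})
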