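test_that("kinase radius appends the domain radius to the center distance", {
  expect_equal(kinase_radius(matrix(c(10.35, 0), 1), hub_center = c(0, 0)),
               12.6)
  # degenerate: kinase at the hub center still reports the appended radius
  expect_equal(kinase_radius(matrix(c(0, 0), 1), hub_center = c(0, 0)), 2.25)
  expect_error(kinase_radius(matrix(numeric(0), 0, 2), hub_center = c(0, 0)),
               "malformed")
})

test_that("linker extension is the subtract-(2.25 + 5.5 + 2.25) convention", {
  expect_equal(linker_extension(16.8), 6.8)
  expect_equal(linker_extension(12.6), 2.6)
  expect_equal(linker_extension(10.0), 0.0)  # compact cutoff = zero extension
  # negative extensions are reported as-is
  expect_lt(linker_extension(9.0), 0)
  # append/subtract identity: extension == raw center distance - 5.5 - 2.25
  ens <- simulate_ensemble(beta_config(dimer_fraction = 0.1,
                                       compact_fraction = 0.05),
                           30, seed = 2)
  for (p in ens$particles) {
    raw <- sqrt(rowSums(sweep(p$kinase_centers, 2, p$hub_center)^2))
    expect_equal(linker_extension(kinase_radius(p)), raw - 5.5 - 2.25,
                 tolerance = 1e-12)
  }
})

test_that("clockwise neighbor separations match the chord-formula oracle", {
  p <- ring_particle(k = 6L, radius_center = 10.35)  # 12 equally spaced
  sep <- neighbor_separation(p)
  chord <- 2 * 10.35 * sin(pi / 12)  # 2 r sin(15 deg)
  expect_equal(sep, rep(chord, 12), tolerance = 1e-9)
  # two coincident centers
  two <- matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(neighbor_separation(two, hub_center = c(0, 0)), c(0, 0))
  expect_error(neighbor_separation(matrix(c(1, 0), 1), hub_center = c(0, 0)),
               "at least 2")
  # every subunit contributes exactly one clockwise distance; the multiset
  # of separations is therefore reversal-invariant
  set.seed(31)
  pts <- cbind(rnorm(9, 0, 6), rnorm(9, 0, 6))
  s1 <- neighbor_separation(pts, hub_center = c(0, 0))
  s2 <- neighbor_separation(pts %*% diag(c(1, -1)), hub_center = c(0, 0))
  expect_equal(sort(s1), sort(s2), tolerance = 1e-9)
})

test_that("beta-like ensemble separations sit near the measured 9.4 nm", {
  ens <- simulate_ensemble(beta_config(), 800, seed = 6)
  seps <- unlist(lapply(ens$particles, neighbor_separation))
  # model-dependent agreement: uniform azimuths, no excluded volume
  expect_gt(mean(seps), 8)
  expect_lt(mean(seps), 10.5)
})

test_that("compact classification counts radii under the cutoff", {
  got <- classify_compact(c(9, 11, 12))
  expect_equal(got$fraction, 1 / 3)
  expect_equal(got$flags, c(TRUE, FALSE, FALSE))
  expect_equal(classify_compact(c(10, 11, 15))$fraction, 0)
  expect_error(classify_compact(numeric(0)), "empty")
})

test_that("dimer fractions are nested across cut-offs for any input", {
  got <- classify_dimers(c(4.0, 4.4, 5.9))
  expect_equal(unname(got$fractions["4.5"]), 2 / 3)
  expect_error(classify_dimers(numeric(0)), "empty")
  expect_error(classify_dimers(c(1, 2), cutoffs = c(-1, 5)), "positive")
  set.seed(17)
  for (i in 1:25) {
    seps <- rgamma(50, shape = runif(1, 0.5, 4), rate = runif(1, 0.1, 1))
    fr <- classify_dimers(seps)$fractions
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("symmetry calls are exact on noiseless rings of all three orders", {
  for (k in c(6L, 7L, 8L)) {
    p <- ring_particle(k = k, phase = 0.3)
    expect_equal(as.character(classify_stoichiometry(p)), as.character(k))
  }
  # degenerate vertices
  expect_error(classify_stoichiometry(matrix(0, 6, 2), hub_center = c(0, 0)),
               "degenerate")
  expect_error(classify_stoichiometry(matrix(1, 4, 2)), "at least 5")
})

test_that("sevenfold hubs at 0.4 nm vertex noise are called in >= 99% of trials", {
  set.seed(55)
  n_trials <- 1000
  hit <- 0
  for (t in seq_len(n_trials)) {
    p <- ring_particle(k = 7L, phase = runif(1, 0, 2 * pi))
    p$hub_vertices <- p$hub_vertices + matrix(rnorm(14, 0, 0.4), 7, 2)
    if (as.character(classify_stoichiometry(p)) == "7") hit <- hit + 1
  }
  expect_gte(hit / n_trials, 0.99)
})

test_that("cluster detection agrees with the brute-force all-pairs oracle", {
  set.seed(99)
  for (i in 1:6) {
    n <- sample(20:200, 1)
    centers <- cbind(runif(n, 0, 800), runif(n, 0, 800))
    got <- detect_clusters(centers, diameter = 25.2)
    oracle <- brute_cluster_oracle(centers, diameter = 25.2)
    expect_equal(got$clustered, oracle$clustered)
    # same partition up to relabeling
    expect_equal(length(unique(got$components)),
                 length(unique(oracle$components)))
    expect_true(all(tapply(oracle$components, got$components,
                           function(x) length(unique(x))) == 1))
  }
  # trivial cases
  expect_equal(detect_clusters(matrix(c(0, 0), 1), diameter = 25)$fraction, 0)
  two <- matrix(c(0, 0, 20, 0), 2, 2, byrow = TRUE)
  expect_equal(detect_clusters(two, diameter = 25.2)$fraction, 1)  # 20 < 37.8
})

test_that("local concentration follows the closed-form sphere calculus", {
  expect_equal(local_concentration(12, 16.8), 1.0, tolerance = 0.005)
  expect_equal(local_concentration(12, 12.6), 2.38, tolerance = 0.005)
  # cubic scaling
  expect_equal(local_concentration(12, 10) / local_concentration(12, 20), 8)
  expect_error(local_concentration(12, -1), "positive")
})

test_that("all measurements are invariant under rigid motion", {
  ens <- simulate_ensemble(beta_config(dimer_fraction = 0.15,
                                       compact_fraction = 0.03),
                           10, seed = 13)
  for (p in ens$particles) {
    q <- transform_particle(p, angle = 1.234, shift = c(-310.5, 42.1))
    expect_equal(kinase_radius(q), kinase_radius(p), tolerance = 1e-9)
    expect_equal(sort(neighbor_separation(q)), sort(neighbor_separation(p)),
                 tolerance = 1e-9)
    expect_equal(as.character(classify_stoichiometry(q)),
                 as.character(classify_stoichiometry(p)))
  }
})

test_that("measurement tables carry per-subunit and per-particle calls", {
  ens <- simulate_ensemble(beta_config(dimer_fraction = 0.2,
                                       compact_fraction = 0.05),
                           40, seed = 19)
  mt <- measure_particles(ens)
  expect_s3_class(mt, "measurement_table")
  expect_equal(nrow(mt), sum(vapply(ens$particles, function(p) {
    2L * p$symmetry_order
  }, integer(1))))
  expect_true(all(c("kinase_radius_nm", "linker_extension_nm",
                    "neighbor_separation_nm", "compact_flag",
                    "dimer_flag_4.5nm", "dimer_flag_5nm", "dimer_flag_6nm",
                    "symmetry_call", "label_truth") %in% names(mt)))
  # nesting holds row-wise
  expect_true(all(!mt$dimer_flag_4.5nm | mt$dimer_flag_5nm))
  expect_true(all(!mt$dimer_flag_5nm | mt$dimer_flag_6nm))
  # compact flag is consistent with the radius column
  expect_equal(mt$compact_flag, mt$kinase_radius_nm < 10)
})
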