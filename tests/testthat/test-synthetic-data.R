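test_that("config validation rejects impossible parameter combinations", {
  expect_error(simulation_config(stoichiometry_mix = c("12" = 0)),
               "sums to 0")
  expect_error(simulation_config(stoichiometry_mix = c("10" = 1)), "named")
  expect_error(simulation_config(dimer_fraction = 0.7, compact_fraction = 0.5),
               "exceed 1")
  expect_error(simulation_config(radius_mean = 6), "radius_mean")
  expect_error(simulation_config(dimer_fraction = -0.1), "\\[0, 1\\]")
})

test_that("degenerate SD with zero noise gives exact kinase radii", {
  cfg <- simulation_config(radius_mean = 12.6, radius_sd = 1e-12,
                           noise_sd = 0, dimer_fraction = 0,
                           compact_fraction = 0)
  ens <- simulate_ensemble(cfg, 20, seed = 11)
  r <- unlist(lapply(ens$particles, kinase_radius))
  expect_equal(r, rep(12.6, length(r)), tolerance = 1e-9)
})

test_that("same config and seed reproduce a bit-identical ensemble", {
  cfg <- beta_config(dimer_fraction = 0.1, compact_fraction = 0.02)
  a <- simulate_ensemble(cfg, 40, seed = 123)
  b <- simulate_ensemble(cfg, 40, seed = 123)
  expect_identical(a, b)
  f1 <- simulate_field(cfg, 30, extent = 1500, cluster_fraction = 0.4,
                       seed = 5)
  f2 <- simulate_field(cfg, 30, extent = 1500, cluster_fraction = 0.4,
                       seed = 5)
  expect_identical(f1$table, f2$table)
  d1 <- simulate_dose_response(1, 15e-9, 1.6, seed = 9)
  d2 <- simulate_dose_response(1, 15e-9, 1.6, seed = 9)
  expect_identical(d1, d2)
})

test_that("beta-like ensemble mean radius lands within 3 SEM of 16.8 nm", {
  ens <- simulate_ensemble(beta_config(), 1000, seed = 42)
  r <- unlist(lapply(ens$particles, kinase_radius))
  sem <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 16.8), 3 * sem + 0.03)  # +truncation-at-7.75 bias
})

test_that("noiseless geometry is exact: vertex spacing and dimer separation", {
  cfg <- beta_config(noise_sd = 0, dimer_fraction = 0.3)
  ens <- simulate_ensemble(cfg, 25, seed = 3)
  for (p in ens$particles) {
    k <- p$symmetry_order
    th <- sort(atan2(p$hub_vertices[, 2], p$hub_vertices[, 1]))
    gaps <- diff(c(th, th[1] + 2 * pi))
    expect_equal(gaps, rep(2 * pi / k, k), tolerance = 1e-9)
    for (pr in seq_len(nrow(true_dimer_pairs(p)))) {
      ij <- true_dimer_pairs(p)[pr, ]
      d <- sqrt(sum((p$kinase_centers[ij[1], ] - p$kinase_centers[ij[2], ])^2))
      expect_equal(d, cfg$dimer_separation, tolerance = 1e-9)
    }
  }
})

test_that("stoichiometry mix and subunit labels are conserved in distribution", {
  # pooled over 50 seeds; exact binomial test at alpha = 0.01
  cfg <- simulation_config(stoichiometry_mix = c("12" = 0.7, "14" = 0.3),
                           dimer_fraction = 0.15, compact_fraction = 0.05)
  n_12 <- 0; n_tot <- 0; n_dimer_pairs <- 0; n_pairs <- 0
  n_compact <- 0; n_free <- 0
  for (s in 1:50) {
    ens <- simulate_ensemble(cfg, 20, seed = 1000 + s)
    for (p in ens$particles) {
      n_tot <- n_tot + 1
      if (p$symmetry_order == 6) n_12 <- n_12 + 1
      n_pairs <- n_pairs + p$symmetry_order
      n_dimer_pairs <- n_dimer_pairs + sum(p$subunit_labels == "dimer") / 2
      nf <- sum(p$subunit_labels != "dimer")
      n_free <- n_free + nf
      n_compact <- n_compact + sum(p$subunit_labels == "compact")
    }
  }
  expect_gt(binom.test(n_12, n_tot, 0.7)$p.value, 0.01)
  expect_gt(binom.test(n_dimer_pairs, n_pairs, 0.15)$p.value, 0.01)
  p_c_cond <- 0.05 / (1 - 0.15)
  expect_gt(binom.test(n_compact, n_free, p_c_cond)$p.value, 0.01)
})

test_that("measurement round-trip recovers the generating radial moments", {
  cfg <- beta_config(noise_sd = 0)
  ens <- simulate_ensemble(cfg, 800, seed = 77)
  r <- unlist(lapply(ens$particles, kinase_radius))
  n <- length(r)
  expect_lt(abs(mean(r) - 16.8), 3 * 3.3 / sqrt(n) + 0.03)
  expect_lt(abs(sd(r) - 3.3), 3 * 3.3 / sqrt(2 * n) + 0.02)
})

test_that("chain radial model anchors subunits at hub vertices", {
  cfg <- simulation_config(radial_model = "chain", linker_residues = 92,
                           radius_mean = 16.8, noise_sd = 0)
  ens <- simulate_ensemble(cfg, 400, seed = 8)
  # projected displacement from the anchor vertex has RMS b*sqrt(2N/3)
  d <- unlist(lapply(ens$particles, function(p) {
    anchor <- rep(seq_len(p$symmetry_order), each = 2)
    sqrt(rowSums((p$kinase_centers - p$hub_vertices[anchor, ])^2))
  }))
  rms_expect <- cfg$step_length_b * sqrt(2 * cfg$linker_residues / 3)
  expect_lt(abs(sqrt(mean(d^2)) / rms_expect - 1), 0.03)
})

test_that("ambiguous remainder class is generated and flagged", {
  cfg <- simulation_config(stoichiometry_mix = c("12" = 0.8))
  ens <- simulate_ensemble(cfg, 400, seed = 21)
  amb <- vapply(ens$particles, `[[`, logical(1), "ambiguous")
  expect_gt(binom.test(sum(amb), length(amb), 0.2)$p.value, 0.01)
})

test_that("field generator honors cluster fraction and hard-core spacing", {
  cfg <- alpha_config()
  # trivial cases
  f0 <- simulate_field(cfg, 40, extent = 3000, cluster_fraction = 0, seed = 2,
                       particles = FALSE)
  expect_equal(detect_clusters(f0)$fraction, 0)
  two <- data.frame(holoenzyme_id = 1:2, hub_x_nm = c(0, 100),
                    hub_y_nm = c(0, 0))
  expect_equal(detect_clusters(two, diameter = 25)$fraction, 0)
  # clustered truth is recovered by detection (same rule both ways)
  f <- simulate_field(cfg, 150, extent = 3500, cluster_fraction = 0.5,
                      seed = 4, particles = FALSE)
  det <- detect_clusters(f)
  expect_equal(det$clustered, f$table$clustered_truth)
  expect_error(simulate_field(cfg, 500, extent = 300, cluster_fraction = 0),
               "packing|extent")
})

test_that("rendered blobs carry total intensity and recover positions", {
  cfg <- beta_config(noise_sd = 0)
  p <- simulate_ensemble(cfg, 1, seed = 14)$particles[[1]]
  img <- render_micrograph(p, pixel_size = 0.437, box_px = 144,
                           sigma_hub = 1.2, sigma_kinase = 1.6)
  # sum of Gaussian integrals: n_blobs * 2*pi*sigma^2 / pixel area
  expected <- (nrow(p$hub_vertices) * 2 * pi * 1.2^2 +
               nrow(p$kinase_centers) * 2 * pi * 1.6^2) / 0.437^2
  expect_lt(abs(sum(img) / expected - 1), 0.01)
  # empty field renders to zero
  f_empty <- structure(list(particles = list(), extent = 20,
                            config = cfg, table = NULL),
                       class = "field_set")
  expect_true(all(render_micrograph(f_empty, pixel_size = 0.5,
                                    box_px = 40) == 0))
  # single centered blob: centroid at the blob position within 0.1 px
  q <- p
  q$hub_vertices <- matrix(numeric(0), 0, 2)
  q$kinase_centers <- matrix(q$hub_center, 1, 2)
  img1 <- render_micrograph(q, pixel_size = 0.437, box_px = 144)
  half <- 144 * 0.437 / 2
  cen <- image_centroid(img1)
  expect_lt(sqrt(sum((cen - c(half, half))^2)), 0.1 * 0.437)
  # centroid picking on a full render recovers each kinase radius
  half_pt <- c(half, half)
  rec <- vapply(seq_len(nrow(p$kinase_centers)), function(i) {
    target <- p$kinase_centers[i, ] - p$hub_center + half_pt
    got <- image_centroid(img, center = target, radius = 2.5)
    sqrt(sum((got - half_pt)^2)) + 2.25
  }, numeric(1))
  truth <- kinase_radius(p)
  expect_lt(max(abs(rec - truth)), 0.437 + cfg$noise_sd)
})

test_that("MRC export writes a well-formed mode-2 header and data block", {
  p <- simulate_ensemble(alpha_config(), 1, seed = 5)$particles[[1]]
  img <- render_micrograph(p, pixel_size = 0.437, box_px = 64)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(img, path)
  expect_equal(file.size(path), 1024 + 4 * 64 * 64)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 4, size = 4)
  expect_equal(hdr, c(64L, 64L, 1L, 2L))  # nx, ny, nz, mode
  seek(con, 1024)
  dat <- readBin(con, "numeric", 64 * 64, size = 4)
  expect_equal(matrix(dat, 64, 64), unclass(img), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("dose-response generator hits the Hill landmarks", {
  d_half <- simulate_dose_response(0.8, 20e-9, 1.7,
                                   concentrations = 20e-9, noise_sd = 0,
                                   replicates = 1)
  expect_equal(d_half$activity, 0.4)
  d_sat <- simulate_dose_response(0.8, 20e-9, 1.7, concentrations = 1e-3,
                                  noise_sd = 0, replicates = 1)
  expect_equal(d_sat$activity, 0.8, tolerance = 1e-6)
  expect_error(simulate_dose_response(1, -1e-9, 1.6), "ec50")
  expect_error(simulate_dose_response(1, 1e-9, 1.6, concentrations = c(0, 1)),
               "positive")
})
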