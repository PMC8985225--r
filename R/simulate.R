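#' Simulate one holoenzyme particle
#'
#' Draws a single particle in the 2D projection plane: a hub ring of
#' equally spaced vertices (radius `hub_radius`, random phase) and
#' `2 * symmetry_order` tethered kinase-domain centers, with per-subunit
#' ground-truth state labels recorded before measurement noise is added.
#'
#' Placement rules, in order:
#' * the symmetry order is drawn from `stoichiometry_mix`; with
#'   probability `1 - sum(mix)` the particle is flagged ambiguous and its
#'   hub vertices later receive 3x positional jitter;
#' * dimer pairs form between angularly adjacent subunits: the pair
#'   midpoint sits at a radius drawn from the extended-state model and
#'   the two centers straddle it at `dimer_separation`, pair axis
#'   uniform;
#' * compact subunits are placed so that the measured kinase radius is
#'   Uniform(hub_radius + kinase_radius, compact_cutoff);
#' * extended subunits are placed at measured radius
#'   `r ~ Normal(radius_mean, radius_sd)` truncated below at
#'   `hub_radius + kinase_radius` (gaussian_radius model), or by a
#'   projected 3D Gaussian-chain displacement from the subunit's anchor
#'   vertex (chain model); azimuths are uniform;
#' * isotropic Gaussian noise of SD `noise_sd` is added to every
#'   coordinate last.
#'
#' The hub center is the origin of the particle frame. Uses the current
#' RNG state; seed via [simulate_ensemble()] for reproducible ensembles.
#'
#' @param config a [simulation_config()].
#' @return A `holo_particle`: list with `hub_center`, `symmetry_order`,
#'   `hub_vertices` (k x 2), `kinase_centers` (2k x 2), `subunit_labels`
#'   (`"extended"`, `"dimer"`, `"compact"`), `ambiguous` flag.
#' @export
simulate_particle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mix <- config$stoichiometry_mix
  p_amb <- 1 - sum(mix)
  u <- stats::runif(1)
  if (u < p_amb) {
    ambiguous <- TRUE
    k <- sample(c(6L, 7L, 8L), 1)
  } else {
    ambiguous <- FALSE
    n_mer <- as.integer(names(mix)[findInterval(u - p_amb, cumsum(c(0, mix)),
                                                rightmost.closed = TRUE)])
    k <- n_mer %/% 2L
  }
  n_sub <- 2L * k
  phase <- stats::runif(1, 0, 2 * pi)
  vang <- phase + 2 * pi * (seq_len(k) - 1) / k
  vertices <- config$hub_radius * cbind(cos(vang), sin(vang))

  # state labels: adjacent index pairs (1,2),(3,4),... become dimers with
  # prob dimer_fraction; remaining subunits compact at the conditional rate
  # that keeps the marginal compact fraction at compact_fraction
  labels <- rep("extended", n_sub)
  pair_is_dimer <- stats::runif(k) < config$dimer_fraction
  labels[rep(pair_is_dimer, each = 2)] <- "dimer"
  free <- labels == "extended"
  if (config$compact_fraction > 0 && any(free)) {
    p_c <- min(1, config$compact_fraction / max(1e-12, 1 - config$dimer_fraction))
    labels[free][stats::runif(sum(free)) < p_c] <- "compact"
  }

  rmin <- config$hub_radius + config$kinase_radius
  draw_radius <- function(n) {
    if (config$radial_model == "gaussian_radius") {
      r <- stats::rnorm(n, config$radius_mean, config$radius_sd)
      while (any(bad <- r <= rmin)) {
        r[bad] <- stats::rnorm(sum(bad), config$radius_mean, config$radius_sd)
      }
      r
    } else {
      # chain model radii are produced per-subunit from anchors; unused here
      rep(config$radius_mean, n)
    }
  }

  centers <- matrix(NA_real_, n_sub, 2)
  anchor_of <- rep(seq_len(k), each = 2)     # subunit j anchored at vertex ceil(j/2)

  ext_idx <- which(labels == "extended")
  if (length(ext_idx)) {
    if (config$radial_model == "chain") {
      sdax <- config$step_length_b * sqrt(config$linker_residues / 3)
      disp <- matrix(stats::rnorm(2 * length(ext_idx), 0, sdax), ncol = 2)
      centers[ext_idx, ] <- vertices[anchor_of[ext_idx], , drop = FALSE] + disp
    } else {
      d <- draw_radius(length(ext_idx)) - config$kinase_radius
      a <- stats::runif(length(ext_idx), 0, 2 * pi)
      centers[ext_idx, ] <- d * cbind(cos(a), sin(a))
    }
  }
  cmp_idx <- which(labels == "compact")
  if (length(cmp_idx)) {
    rmeas <- stats::runif(length(cmp_idx), rmin, config$compact_cutoff)
    d <- rmeas - config$kinase_radius
    a <- stats::runif(length(cmp_idx), 0, 2 * pi)
    centers[cmp_idx, ] <- d * cbind(cos(a), sin(a))
  }
  dim_pairs <- which(pair_is_dimer)
  for (p in dim_pairs) {
    i <- 2L * p - 1L
    d_mid <- draw_radius(1) - config$kinase_radius
    a_mid <- stats::runif(1, 0, 2 * pi)
    mid <- d_mid * c(cos(a_mid), sin(a_mid))
    ax <- stats::runif(1, 0, 2 * pi)
    half <- (config$dimer_separation / 2) * c(cos(ax), sin(ax))
    centers[i, ] <- mid + half
    centers[i + 1L, ] <- mid - half
  }

  if (config$noise_sd > 0) {
    vj <- config$noise_sd * (if (ambiguous) 3 else 1)
    vertices <- vertices + matrix(stats::rnorm(2 * k, 0, vj), ncol = 2)
    centers <- centers + matrix(stats::rnorm(2 * n_sub, 0, config$noise_sd), ncol = 2)
  }

  structure(list(
    hub_center = c(0, 0),
    symmetry_order = k,
    hub_vertices = vertices,
    kinase_centers = centers,
    subunit_labels = labels,
    ambiguous = ambiguous
  ), class = "holo_particle")
}

#' Simulate an ensemble of holoenzyme particles
#'
#' @param config a [simulation_config()].
#' @param n_particles number of independent particles (>= 1).
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   (config, seed) pairs give identical ensembles.
#' @return A `particle_set`: list with `particles` (list of
#'   `holo_particle`) and `config`.
#' @export
#' @examples
#' ens <- simulate_ensemble(alpha_config(), 50, seed = 1)
#' length(ens$particles)
simulate_ensemble <- function(config, n_particles, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_particles) || n_particles < 1) {
    stop("n_particles must be >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  particles <- vector("list", n_particles)
  for (i in seq_len(n_particles)) particles[[i]] <- simulate_particle(config)
  structure(list(particles = particles, config = config, seed = seed),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  k <- vapply(x$particles, `[[`, integer(1), "symmetry_order")
  cat(sprintf("<particle_set> %d particles (%d subunits), orders: %s\n",
              length(x$particles), sum(2L * k),
              paste(names(table(k)), table(k), sep = "x", collapse = ", ")))
  invisible(x)
}

#' Simulate a field of holoenzymes with controlled clustering
#'
#' Places `n_holoenzymes` hub centers in a square field of side `extent`
#' nm. A fraction `cluster_fraction` is laid down in pairs (plus one
#' triple when the count is odd) whose members sit within
#' `factor * diameter` of each other, emulating self-associated
#' holoenzyme pairs and small clusters; the remainder is placed so that
#' every neighbor is beyond that distance. Ground-truth clustered flags
#' are recorded for benchmarking [detect_clusters()].
#'
#' @param config a [simulation_config()]; per-holoenzyme particles are
#'   generated from it and translated to their hub positions.
#' @param n_holoenzymes number of holoenzymes.
#' @param extent field side length (nm).
#' @param cluster_fraction target fraction of clustered holoenzymes.
#' @param seed integer seed.
#' @param factor clustering distance factor (default 1.5, the
#'   1.5x-particle-diameter rule).
#' @param diameter particle diameter (nm); default `2 * radius_mean`.
#' @param hardcore minimum hub-center distance (nm) between clustered
#'   partners; default `0.5 * diameter` (kinase halos interpenetrate in
#'   a contacting pair, hubs do not).
#' @param max_tries rejection-sampling retry bound per holoenzyme.
#' @param particles if `FALSE`, skip generating per-holoenzyme
#'   coordinates (fast path when only hub positions are needed).
#' @return A `field_set`: list with `table` (data.frame holoenzyme_id,
#'   hub_x_nm, hub_y_nm, clustered_truth), `particles`, `diameter`,
#'   `extent`, `config`.
#' @export
simulate_field <- function(config, n_holoenzymes, extent, cluster_fraction = 0,
                           seed = config$seed, factor = 1.5,
                           diameter = 2 * config$radius_mean,
                           hardcore = 0.5 * diameter,
                           max_tries = 2000, particles = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_holoenzymes >= 1, extent > 0,
            cluster_fraction >= 0, cluster_fraction <= 1, diameter > 0)
  if (!is.null(seed)) set.seed(seed)
  d_clust <- factor * diameter
  if (extent < 2 * d_clust) {
    stop("extent too small for the requested clustering geometry")
  }
  n_clustered <- round(cluster_fraction * n_holoenzymes)
  if (n_clustered == 1) n_clustered <- 2  # a clustered holoenzyme needs a partner
  n_clustered <- min(n_clustered, n_holoenzymes)
  centers <- matrix(NA_real_, n_holoenzymes, 2)
  clustered <- logical(n_holoenzymes)
  n_placed <- 0

  dist_to_placed <- function(pt) {
    if (n_placed == 0) return(numeric(0))
    dx <- centers[seq_len(n_placed), 1] - pt[1]
    dy <- centers[seq_len(n_placed), 2] - pt[2]
    sqrt(dx * dx + dy * dy)
  }
  place_isolated <- function() {
    for (t in seq_len(max_tries)) {
      pt <- stats::runif(2, 0, extent)
      if (all(dist_to_placed(pt) >= d_clust)) return(pt)
    }
    stop("infeasible packing: could not place holoenzyme after ", max_tries,
         " tries (extent too small for requested count)")
  }

  # clustered holoenzymes in groups of 2 (one group of 3 if the count is odd)
  group_sizes <- rep(2L, n_clustered %/% 2L)
  if (n_clustered %% 2L == 1L && length(group_sizes)) {
    group_sizes[length(group_sizes)] <- 3L
  }
  for (gs in group_sizes) {
    anchor <- place_isolated()
    n_placed <- n_placed + 1
    centers[n_placed, ] <- anchor
    clustered[n_placed] <- TRUE
    group_rows <- n_placed
    for (j in seq_len(gs - 1L)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, hardcore, 0.95 * d_clust)
        pt <- anchor + rad * c(cos(ang), sin(ang))
        if (any(pt < 0 | pt > extent)) next
        dd <- dist_to_placed(pt)
        outside_group <- setdiff(seq_len(n_placed), group_rows)
        if (all(dd >= hardcore) &&
            (length(outside_group) == 0 || all(dd[outside_group] >= d_clust))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible packing of clustered group after ",
                    max_tries, " tries")
      n_placed <- n_placed + 1
      centers[n_placed, ] <- pt
      clustered[n_placed] <- TRUE
      group_rows <- c(group_rows, n_placed)
    }
  }
  while (n_placed < n_holoenzymes) {
    pt <- place_isolated()
    n_placed <- n_placed + 1
    centers[n_placed, ] <- pt
    clustered[n_placed] <- FALSE
  }

  tab <- data.frame(
    holoenzyme_id = seq_len(n_holoenzymes),
    hub_x_nm = centers[, 1],
    hub_y_nm = centers[, 2],
    clustered_truth = clustered
  )
  parts <- NULL
  if (particles) {
    parts <- vector("list", n_holoenzymes)
    for (h in seq_len(n_holoenzymes)) {
      p <- simulate_particle(config)
      p$hub_center <- centers[h, ]
      p$hub_vertices <- sweep(p$hub_vertices, 2, centers[h, ], `+`)
      p$kinase_centers <- sweep(p$kinase_centers, 2, centers[h, ], `+`)
      parts[[h]] <- p
    }
  }
  structure(list(table = tab, particles = parts, diameter = diameter,
                 extent = extent, factor = factor, config = config),
            class = "field_set")
}

#' Render a synthetic micrograph from a holoenzyme field
#'
#' Draws every hub vertex and kinase center as an isotropic Gaussian
#' blob on a pixel grid — an idealized stand-in for a negative-stain
#' image (no contrast transfer function or stain granularity). Useful
#' for centroid-based re-measurement benchmarks and for visual checks.
#'
#' @param field a `field_set` from [simulate_field()], or a single
#'   `holo_particle` (rendered centered in the box).
#' @param pixel_size pixel size in nm (default from the field's config).
#' @param box_px grid side in pixels; default covers the field extent.
#' @param sigma_hub,sigma_kinase blob SDs in nm.
#' @param amp_hub,amp_kinase blob peak amplitudes.
#' @return Numeric `box_px x box_px` matrix of intensities; attribute
#'   `pixel_size` carries the calibration.
#' @export
render_micrograph <- function(field, pixel_size = NULL, box_px = NULL,
                              sigma_hub = 1.2, sigma_kinase = 1.6,
                              amp_hub = 1, amp_kinase = 1) {
  if (inherits(field, "holo_particle")) {
    pixel_size <- pixel_size %||% 0.437
    box_px <- box_px %||% 144L
    half <- box_px * pixel_size / 2
    pts <- rbind(field$hub_vertices, field$kinase_centers)
    pts <- sweep(pts, 2, field$hub_center, `-`)
    pts <- sweep(pts, 2, c(half, half), `+`)
    amps <- c(rep(amp_hub, nrow(field$hub_vertices)),
              rep(amp_kinase, nrow(field$kinase_centers)))
    sigs <- c(rep(sigma_hub, nrow(field$hub_vertices)),
              rep(sigma_kinase, nrow(field$kinase_centers)))
  } else {
    stopifnot(inherits(field, "field_set"))
    pixel_size <- pixel_size %||% field$config$pixel_size
    box_px <- box_px %||% as.integer(ceiling(field$extent / pixel_size))
    pts <- NULL; amps <- NULL; sigs <- NULL
    for (p in field$particles) {
      pts <- rbind(pts, p$hub_vertices, p$kinase_centers)
      amps <- c(amps, rep(amp_hub, nrow(p$hub_vertices)),
                rep(amp_kinase, nrow(p$kinase_centers)))
      sigs <- c(sigs, rep(sigma_hub, nrow(p$hub_vertices)),
                rep(sigma_kinase, nrow(p$kinase_centers)))
    }
  }
  if (pixel_size <= 0) stop("pixel_size must be positive")
  img <- matrix(0, box_px, box_px)
  if (is.null(pts) || nrow(pts) == 0) {
    attr(img, "pixel_size") <- pixel_size
    return(img)
  }
  # pixel-center coordinates in nm
  ax <- (seq_len(box_px) - 0.5) * pixel_size
  for (b in seq_len(nrow(pts))) {
    gx <- exp(-((ax - pts[b, 1])^2) / (2 * sigs[b]^2))
    gy <- exp(-((ax - pts[b, 2])^2) / (2 * sigs[b]^2))
    img <- img + amps[b] * outer(gx, gy)
  }
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Intensity-weighted centroid of an image region
#'
#' Companion to [render_micrograph()]: recovers a blob position (nm)
#' from pixel intensities, optionally within a circular window.
#'
#' @param img matrix with a `pixel_size` attribute (nm).
#' @param center,radius optional window center (nm, length 2) and radius
#'   (nm) restricting the centroid to one blob.
#' @return length-2 numeric, centroid in nm.
#' @export
image_centroid <- function(img, center = NULL, radius = NULL) {
  px <- attr(img, "pixel_size")
  stopifnot(!is.null(px))
  ax <- (seq_len(nrow(img)) - 0.5) * px
  ay <- (seq_len(ncol(img)) - 0.5) * px
  w <- img
  if (!is.null(center) && !is.null(radius)) {
    m <- outer(ax, ay, function(x, y) (x - center[1])^2 + (y - center[2])^2)
    w[m > radius^2] <- 0
  }
  s <- sum(w)
  if (s <= 0) stop("empty window: no intensity to take a centroid of")
  c(sum(rowSums(w) * ax), sum(colSums(w) * ay)) / s
}

#' Write a 2D image as an MRC file
#'
#' Minimal MRC2014 writer (mode 2, 32-bit float) for exporting rendered
#' synthetic micrographs; no R MRC package is available, so the 1024-byte
#' header is written directly.
#'
#' @param img matrix with a `pixel_size` attribute (nm).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(img, path) {
  px_ang <- attr(img, "pixel_size") * 10  # nm -> Angstrom
  con <- file(path, "wb")
  on.exit(close(con))
  nx <- nrow(img); ny <- ncol(img)
  writeBin(as.integer(c(nx, ny, 1L, 2L, 0L, 0L, 0L, nx, ny, 1L)), con, size = 4)
  writeBin(c(nx * px_ang, ny * px_ang, px_ang, 90, 90, 90), con, size = 4)
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4)
  writeBin(c(min(img), max(img), mean(img)), con, size = 4)
  writeBin(as.integer(c(0L, 0L)), con, size = 4)  # ispg, nsymbt
  writeBin(rep(0L, 25), con, size = 4)          # extra
  writeBin(c(0, 0, 0), con, size = 4)           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  writeBin(stats::sd(as.numeric(img)), con, size = 4)
  writeBin(0L, con, size = 4)                   # nlabl
  writeBin(raw(800), con)                       # labels
  writeBin(as.numeric(img), con, size = 4)      # column-major = x fastest
  invisible(path)
}

#' Simulate a CaM dose-response dataset
#'
#' Generates replicate activity measurements from the variable-slope
#' Hill model `v = vmax * c^h / (ec50^h + c^h)` with additive Gaussian
#' noise, emulating in-vitro kinase activation assays across a CaM
#' titration.
#'
#' @param vmax maximal activity (fraction of Vmax scale; typically 1).
#' @param ec50 half-maximal CaM concentration (molar).
#' @param hill_h Hill slope (> 0).
#' @param concentrations CaM concentrations (molar, strictly positive);
#'   default 12 log-spaced points over 0.6 nM - 6 uM, the assay range.
#' @param noise_sd additive noise SD on the activity scale.
#' @param replicates replicate measurements per concentration.
#' @param seed integer seed.
#' @return A `dose_response` data.frame with columns `cam_molar`,
#'   `replicate`, `activity`; generating parameters in
#'   `attr(, "generating_params")`.
#' @export
#' @examples
#' dr <- simulate_dose_response(1, 14.6e-9, 1.64, noise_sd = 0, seed = 1)
#' head(dr)
simulate_dose_response <- function(vmax, ec50, hill_h,
                                   concentrations = 10^seq(log10(0.6e-9),
                                                           log10(6e-6),
                                                           length.out = 12),
                                   noise_sd = 0.02, replicates = 3, seed = NULL) {
  if (ec50 <= 0) stop("ec50 must be positive")
  if (hill_h <= 0) stop("hill_h must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  concentrations <- sort(concentrations)
  if (!is.null(seed)) set.seed(seed)
  cc <- rep(concentrations, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(concentrations))
  v <- vmax * cc^hill_h / (ec50^hill_h + cc^hill_h)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  out <- data.frame(cam_molar = cc, replicate = rep_id, activity = v)
  attr(out, "generating_params") <- list(vmax = vmax, ec50 = ec50,
                                         hill_h = hill_h, noise_sd = noise_sd)
  class(out) <- c("dose_response", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
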