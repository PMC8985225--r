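#' Kinase radius of every subunit of a particle
#'
#' The measurement convention for negative-stain particle images: the
#' distance from the hub-ring center to each kinase-domain center, plus
#' an appended kinase-domain radius (2.25 nm by default) so the value
#' represents the full radial extension of the subunit.
#'
#' @param particle a `holo_particle`, or a 2-column matrix of kinase
#'   centers (nm) with `hub_center` supplied separately.
#' @param hub_center hub center (nm, length 2); taken from the particle
#'   when one is given.
#' @param kinase_radius appended kinase-domain radius (nm).
#' @return Numeric vector of per-subunit radii (nm).
#' @export
#' @examples
#' kinase_radius(matrix(c(10.35, 0), 1), hub_center = c(0, 0))  # 12.6
kinase_radius <- function(particle, hub_center = NULL, kinase_radius = 2.25) {
  if (inherits(particle, "holo_particle")) {
    centers <- particle$kinase_centers
    hub_center <- particle$hub_center
  } else {
    centers <- as.matrix(particle)
    if (is.null(hub_center)) stop("hub_center required for a bare coordinate matrix")
  }
  if (is.null(dim(centers)) || ncol(centers) != 2 || nrow(centers) < 1) {
    stop("malformed particle: kinase centers must be an n x 2 matrix, n >= 1")
  }
  sqrt((centers[, 1] - hub_center[1])^2 +
       (centers[, 2] - hub_center[2])^2) + kinase_radius
}

#' Linker extension from a kinase radius
#'
#' Edge-to-edge hub-to-kinase distance: the hub ring radius (5.5 nm) and
#' twice the kinase-domain radius (2.25 nm; once because it was appended
#' to the raw measurement, once for the domain's own extent) are
#' subtracted from the kinase radius. Negative values are possible for
#' compact subunits and are returned as-is.
#'
#' @param radius_nm kinase radius (nm), as from [kinase_radius()].
#' @param hub_radius hub ring radius (nm).
#' @param kinase_radius kinase-domain radius (nm).
#' @return Linker extension (nm); `radius - 2*kinase_radius - hub_radius`.
#' @export
#' @examples
#' linker_extension(16.8)  # 6.8 nm, the beta-isoform mean
linker_extension <- function(radius_nm, hub_radius = 5.5, kinase_radius = 2.25) {
  if (any(radius_nm < 0)) stop("radius must be nonnegative")
  radius_nm - 2 * kinase_radius - hub_radius
}

#' Nearest-clockwise-neighbor kinase separations
#'
#' For each kinase center, the Euclidean center-to-center distance to
#' the angularly next kinase center in clockwise order about the hub
#' center. Every subunit contributes exactly one distance, so the
#' statistic does not depend on whether "clockwise" is taken in the
#' image frame (y down) or the mathematical frame. Angular ties are
#' broken by radius, then by index.
#'
#' @inheritParams kinase_radius
#' @return Numeric vector: separation of each subunit to its clockwise
#'   neighbor, in input order.
#' @export
neighbor_separation <- function(particle, hub_center = NULL) {
  if (inherits(particle, "holo_particle")) {
    centers <- particle$kinase_centers
    hub_center <- particle$hub_center
  } else {
    centers <- as.matrix(particle)
    if (is.null(hub_center)) stop("hub_center required for a bare coordinate matrix")
  }
  n <- nrow(centers)
  if (n < 2) stop("neighbor separation needs at least 2 kinase centers")
  dx <- centers[, 1] - hub_center[1]
  dy <- centers[, 2] - hub_center[2]
  theta <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  ord <- order(-theta, r, seq_len(n))  # decreasing angle = clockwise sweep
  nxt <- ord[c(seq_len(n)[-1], 1)]     # clockwise successor of ord[i]
  sep <- numeric(n)
  sep[ord] <- sqrt((centers[ord, 1] - centers[nxt, 1])^2 +
                   (centers[ord, 2] - centers[nxt, 2])^2)
  sep
}

#' Classify compact subunits by kinase radius
#'
#' A subunit whose kinase radius falls below the cutoff (10 nm) is close
#' enough for steric contact between the kinase domain and the hub: the
#' compact, activation-incompetent state.
#'
#' @param radii kinase radii (nm).
#' @param cutoff compact-state radius cutoff (nm).
#' @return List with `flags` (logical per subunit) and `fraction`.
#' @export
classify_compact <- function(radii, cutoff = 10) {
  if (length(radii) == 0) stop("empty radii")
  flags <- radii < cutoff
  list(flags = flags, fraction = mean(flags))
}

#' Classify kinase-domain dimers by neighbor separation
#'
#' Neighbor separations below a center-to-center cutoff are consistent
#' with kinase-domain dimer formation. The 4.5 nm cutoff matches the
#' crystal-structure dimer; 5 and 6 nm are progressively permissive
#' (6 nm being the maximal possible interaction distance), so flagged
#' fractions are nested across cutoffs.
#'
#' @param separations neighbor separations (nm).
#' @param cutoffs positive cutoffs (nm).
#' @return List with `fractions` (named by cutoff) and `flags` (logical
#'   matrix, one column per cutoff).
#' @export
classify_dimers <- function(separations, cutoffs = c(4.5, 5, 6)) {
  if (length(separations) == 0) stop("empty separations")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  cutoffs <- sort(cutoffs)
  flags <- vapply(cutoffs, function(ct) separations < ct,
                  logical(length(separations)))
  flags <- matrix(flags, ncol = length(cutoffs),
                  dimnames = list(NULL, format(cutoffs)))
  list(fractions = stats::setNames(colMeans(flags), format(cutoffs)),
       flags = flags)
}

#' Hub symmetry call from vertex coordinates
#'
#' Coordinate-domain replacement for focused 2D class-average symmetry
#' assignment: the angular Fourier power
#' `P(k) = |sum_j exp(i k theta_j)|^2 / m` of the vertex azimuths
#' `theta_j` about the hub center is evaluated at candidate orders
#' k = 6, 7, 8. The best order is called only when (a) its power exceeds
#' the runner-up by the confidence ratio (default 2) and (b) it reaches
#' an absolute coherence floor, `min_power_frac * m` (default: half the
#' vertices in phase). The floor is what rejects heavily jittered hubs:
#' with only three candidate orders, pure angular noise produces a
#' ratio-2 chance spike often enough to contaminate a rare class like
#' the eightfold call, while coherent rings at realistic noise sit far
#' above half power. Particles failing either criterion are "ambiguous".
#'
#' @param particle a `holo_particle` or an m x 2 vertex matrix (nm).
#' @param hub_center hub center when a bare matrix is given.
#' @param orders candidate symmetry orders.
#' @param ratio confidence ratio P(best)/P(second) required for a call.
#' @param min_power_frac absolute floor on P(best), as a fraction of the
#'   vertex count.
#' @return Character scalar: `"6"`, `"7"`, `"8"` or `"ambiguous"`, with
#'   attribute `power` (named numeric).
#' @export
classify_stoichiometry <- function(particle, hub_center = NULL,
                                   orders = c(6L, 7L, 8L), ratio = 2,
                                   min_power_frac = 0.5) {
  if (inherits(particle, "holo_particle")) {
    v <- particle$hub_vertices
    hub_center <- particle$hub_center
  } else {
    v <- as.matrix(particle)
    if (is.null(hub_center)) hub_center <- colMeans(v)
  }
  if (nrow(v) < 5) stop("need at least 5 hub vertices for a symmetry call")
  dx <- v[, 1] - hub_center[1]
  dy <- v[, 2] - hub_center[2]
  if (all(dx^2 + dy^2 < 1e-12)) stop("degenerate vertices: all coincident")
  theta <- atan2(dy, dx)
  m <- length(theta)
  power <- vapply(orders, function(k) {
    Mod(sum(exp(1i * k * theta)))^2 / m
  }, numeric(1))
  names(power) <- as.character(orders)
  o <- order(power, decreasing = TRUE)
  call <- if (power[o[1]] / max(power[o[2]], .Machine$double.eps) >= ratio &&
              power[o[1]] >= min_power_frac * m) {
    names(power)[o[1]]
  } else {
    "ambiguous"
  }
  structure(call, power = power)
}

#' Stoichiometry census over a particle set
#'
#' Runs [classify_stoichiometry()] on every particle and tabulates the
#' percentage of the population called at each symmetry order.
#'
#' @param particle_set a `particle_set` (or list of `holo_particle`).
#' @inheritParams classify_stoichiometry
#' @return Data.frame with columns `call`, `n`, `percent`.
#' @export
stoichiometry_census <- function(particle_set, orders = c(6L, 7L, 8L),
                                 ratio = 2, min_power_frac = 0.5) {
  particles <- if (inherits(particle_set, "particle_set")) {
    particle_set$particles
  } else {
    particle_set
  }
  calls <- vapply(particles, function(p) {
    as.character(classify_stoichiometry(p, orders = orders, ratio = ratio,
                                        min_power_frac = min_power_frac))
  }, character(1))
  lev <- c(as.character(orders), "ambiguous")
  tab <- table(factor(calls, levels = lev))
  data.frame(call = lev, n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(calls))
}

#' Detect inter-holoenzyme clustering in a field
#'
#' A holoenzyme is clustered when any neighbor's hub center lies within
#' `factor` times the particle diameter (the 1.5x-diameter rule).
#' Clusters are the connected components of that proximity graph
#' (transitive closure), computed with igraph.
#'
#' @param field a `field_set`, a data.frame with `hub_x_nm`/`hub_y_nm`
#'   columns, or an n x 2 matrix of hub centers (nm).
#' @param diameter particle diameter (nm); defaults to the field's
#'   recorded diameter (2 x mean kinase radius).
#' @param factor clustering distance factor.
#' @return List with `clustered` (logical), `fraction`, `components`
#'   (integer component labels), `n_components` (multi-member clusters).
#' @export
detect_clusters <- function(field, diameter = NULL, factor = 1.5) {
  if (inherits(field, "field_set")) {
    centers <- as.matrix(field$table[, c("hub_x_nm", "hub_y_nm")])
    diameter <- diameter %||% field$diameter
  } else if (is.data.frame(field)) {
    centers <- as.matrix(field[, c("hub_x_nm", "hub_y_nm")])
  } else {
    centers <- as.matrix(field)
  }
  if (is.null(diameter) || diameter <= 0) stop("a positive diameter is required")
  n <- nrow(centers)
  if (n == 1) {
    return(list(clustered = FALSE, fraction = 0, components = 1L,
                n_components = 0L))
  }
  adj <- as.matrix(stats::dist(centers)) < factor * diameter
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clustered <- comp$csize[comp$membership] > 1
  list(clustered = clustered,
       fraction = mean(clustered),
       components = as.integer(comp$membership),
       n_components = sum(comp$csize > 1))
}

#' Local kinase-domain concentration of a holoenzyme
#'
#' Concentration of kinase domains inside the spherical volume swept by
#' the tethered subunits: `c = n / (N_A * (4/3) pi r^3)`, reported in
#' millimolar with r in nm.
#'
#' @param n_kinases number of kinase domains (12 for a dodecamer).
#' @param radius_nm sphere radius (nm), the average kinase radius.
#' @return Concentration in mM.
#' @export
#' @examples
#' local_concentration(12, 16.8)  # ~1.0 mM (beta)
#' local_concentration(12, 12.6)  # ~2.4 mM (alpha)
local_concentration <- function(n_kinases = 12, radius_nm) {
  if (any(radius_nm <= 0)) stop("radius must be positive")
  if (n_kinases < 1) stop("n_kinases must be >= 1")
  avogadro <- 6.02214076e23
  vol_litre <- (4 / 3) * pi * radius_nm^3 * 1e-24  # nm^3 -> L
  1000 * n_kinases / (avogadro * vol_litre)        # mol/L -> mM
}

#' Per-subunit measurement table for a particle set
#'
#' Applies the full measurement convention to every particle: kinase
#' radius (with appended domain radius), linker extension, nearest
#' clockwise neighbor separation, the compact flag, dimer flags at each
#' cutoff, and a per-particle symmetry call.
#'
#' @param particle_set a `particle_set` or list of `holo_particle`.
#' @param hub_radius,kinase_radius measurement constants (nm).
#' @param compact_cutoff compact-state cutoff (nm).
#' @param dimer_cutoffs dimer cutoffs (nm).
#' @param ratio symmetry-call confidence ratio.
#' @return A `measurement_table` data.frame, one row per subunit.
#' @export
#' @examples
#' ens <- simulate_ensemble(alpha_config(), 20, seed = 7)
#' mt <- measure_particles(ens)
#' mean(mt$kinase_radius_nm)
measure_particles <- function(particle_set, hub_radius = 5.5,
                              kinase_radius = 2.25, compact_cutoff = 10,
                              dimer_cutoffs = c(4.5, 5, 6), ratio = 2) {
  particles <- if (inherits(particle_set, "particle_set")) {
    particle_set$particles
  } else {
    particle_set
  }
  dimer_cutoffs <- sort(dimer_cutoffs)
  rows <- lapply(seq_along(particles), function(i) {
    p <- particles[[i]]
    r <- holokin::kinase_radius(p, kinase_radius = kinase_radius)
    sep <- neighbor_separation(p)
    sym <- as.character(classify_stoichiometry(p, ratio = ratio))
    n_sub <- length(r)
    out <- data.frame(
      particle_id = i,
      subunit_id = seq_len(n_sub),
      symmetry_order = p$symmetry_order,
      symmetry_call = sym,
      kinase_radius_nm = r,
      linker_extension_nm = linker_extension(r, hub_radius, kinase_radius),
      neighbor_separation_nm = sep,
      compact_flag = r < compact_cutoff,
      label_truth = p$subunit_labels
    )
    for (ct in dimer_cutoffs) {
      out[[sprintf("dimer_flag_%gnm", ct)]] <- sep < ct
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("measurement_table", "data.frame")
  res
}
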