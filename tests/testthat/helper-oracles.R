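# Test oracles and fixture builders, independent of the implementation paths
# they check.

# Noiseless ring particle: 2k kinase centers equally spaced on a circle of
# center-to-center radius `radius_center` about `hub_center`, hub vertices at
# `hub_radius`.
ring_particle <- function(k = 6L, radius_center = 10.35, hub_radius = 5.5,
                          hub_center = c(0, 0), phase = 0) {
  n_sub <- 2L * k
  va <- phase + 2 * pi * (seq_len(k) - 1) / k
  ka <- phase + 2 * pi * (seq_len(n_sub) - 1) / n_sub
  structure(list(
    hub_center = hub_center,
    symmetry_order = k,
    hub_vertices = sweep(hub_radius * cbind(cos(va), sin(va)), 2,
                         hub_center, `+`),
    kinase_centers = sweep(radius_center * cbind(cos(ka), sin(ka)), 2,
                           hub_center, `+`),
    subunit_labels = rep("extended", n_sub),
    ambiguous = FALSE
  ), class = "holo_particle")
}

# Rigid motion of a particle: rotate by `angle` about the origin, then shift.
transform_particle <- function(p, angle = 0, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  move <- function(m) sweep(m %*% t(rot), 2, shift, `+`)
  p$hub_center <- as.numeric(rot %*% p$hub_center) + shift
  p$hub_vertices <- move(p$hub_vertices)
  p$kinase_centers <- move(p$kinase_centers)
  p
}

# Brute-force transitive-closure clustering oracle: repeated neighbor
# expansion on the all-pairs distance matrix.
brute_cluster_oracle <- function(centers, diameter, factor = 1.5) {
  n <- nrow(centers)
  adj <- as.matrix(stats::dist(centers)) < factor * diameter
  diag(adj) <- FALSE
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) && any(comp[nb] != comp[i])) {
        new_id <- min(comp[c(i, nb)])
        comp[comp %in% comp[c(i, nb)]] <- new_id
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  list(clustered = as.integer(sizes[as.character(comp)]) > 1, components = comp)
}

# Textbook Welch statistic: t, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# Ground-truth dimer pairs of a simulated particle: dimer-labelled subunits
# come in adjacent index pairs (1,2), (3,4), ...
true_dimer_pairs <- function(p) {
  idx <- which(p$subunit_labels == "dimer")
  matrix(idx, ncol = 2, byrow = TRUE)
}
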