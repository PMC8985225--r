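#' Simulation configuration for synthetic holoenzyme ensembles
#'
#' Bundles every knob of the synthetic-particle generator: the hub
#' stoichiometry mixture, the radial placement model for tethered kinase
#' domains, the fractions of dimerized and compact subunits, measurement
#' noise, and the fixed geometric constants of the particle architecture.
#'
#' The hub is a ring of `symmetry_order` vertices (6, 7 or 8, i.e. a
#' 12-, 14- or 16-mer holoenzyme: each vertex is a vertical dimer of
#' association domains carrying two kinase subunits). Kinase domains are
#' tethered by flexible linkers; their projected radial positions are
#' drawn either directly from a Gaussian in measured radius
#' (`radial_model = "gaussian_radius"`, the default, matching the
#' apparently Gaussian radius distributions seen in negative-stain EM) or
#' from a projected 3D Gaussian-chain displacement anchored at the hub
#' edge (`radial_model = "chain"`, the polymer null).
#'
#' @param stoichiometry_mix named numeric vector mapping subunit counts
#'   (`"12"`, `"14"`, `"16"`) to population fractions. Must sum to at
#'   most 1; the remainder is generated as "ambiguous" particles whose
#'   hub vertices receive 3x positional jitter, giving the census stage a
#'   rejection class.
#' @param radial_model `"gaussian_radius"` or `"chain"`.
#' @param radius_mean,radius_sd mean and SD (nm) of the measured kinase
#'   radius for extended subunits (gaussian_radius model). Defaults are
#'   the alpha-isoform values 12.6 and 1.6 nm.
#' @param linker_residues number of linker residues (chain model);
#'   31 for alpha-like, 92 for beta-like linkers.
#' @param step_length_b effective per-residue step length b (nm) of the
#'   random-chain model. Default `NULL` calibrates b from
#'   `radius_mean` via [calibrate_step()] so both radial models share a
#'   mean extension.
#' @param dimer_fraction expected fraction of subunits in kinase-domain
#'   dimer pairs (pairs form between angularly adjacent subunits).
#' @param dimer_separation center-to-center distance (nm) of a dimer
#'   pair before noise; 4.5 nm matches the crystal-structure dimer.
#' @param compact_fraction expected fraction of subunits in the compact
#'   state (measured radius below 10 nm, kinase docked near the hub).
#' @param noise_sd isotropic Gaussian positional noise SD (nm) added to
#'   every coordinate last; default 0.437 nm = one pixel at the 4.37
#'   Angstrom calibration.
#' @param hub_radius hub ring radius (nm); 5.5 nm gives the ~11 nm hub
#'   outer diameter.
#' @param kinase_radius kinase domain radius (nm); 2.25 nm, the value
#'   appended to raw center-to-center measurements.
#' @param compact_cutoff measured-radius cutoff (nm) defining the
#'   compact state.
#' @param pixel_size pixel size (nm) for rendered micrographs.
#' @param box_px box size (pixels) for rendered micrographs.
#' @param seed optional default seed carried with the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [alpha_config()], [beta_config()], [simulate_ensemble()]
#' @export
#' @examples
#' cfg <- beta_config()
#' cfg$radius_mean
simulation_config <- function(stoichiometry_mix = c("12" = 1),
                              radial_model = c("gaussian_radius", "chain"),
                              radius_mean = 12.6,
                              radius_sd = 1.6,
                              linker_residues = 31,
                              step_length_b = NULL,
                              dimer_fraction = 0,
                              dimer_separation = 4.5,
                              compact_fraction = 0,
                              noise_sd = 0.437,
                              hub_radius = 5.5,
                              kinase_radius = 2.25,
                              compact_cutoff = 10,
                              pixel_size = 0.437,
                              box_px = 144,
                              seed = NULL) {
  radial_model <- match.arg(radial_model)
  mix <- as.numeric(stoichiometry_mix)
  names(mix) <- names(stoichiometry_mix)
  if (is.null(names(mix)) || !all(names(mix) %in% c("12", "14", "16"))) {
    stop("stoichiometry_mix must be named with subunit counts \"12\", \"14\", \"16\"")
  }
  if (any(mix < 0)) stop("stoichiometry_mix fractions must be nonnegative")
  if (sum(mix) > 1 + 1e-12) stop("stoichiometry_mix must sum to at most 1")
  if (sum(mix) == 0) stop("stoichiometry_mix sums to 0: no particle class to generate")
  stopifnot(radius_sd >= 0, noise_sd >= 0, hub_radius > 0, kinase_radius > 0,
            dimer_separation > 0, linker_residues >= 1)
  for (f in c(dimer_fraction, compact_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (dimer_fraction + compact_fraction > 1) {
    stop("dimer_fraction + compact_fraction must not exceed 1")
  }
  if (radius_mean <= hub_radius + kinase_radius) {
    stop("radius_mean must exceed hub_radius + kinase_radius (kinase outside the hub)")
  }
  if (is.null(step_length_b)) {
    # share the mean linker extension between the two radial models
    ext <- radius_mean - 2 * kinase_radius - hub_radius
    step_length_b <- calibrate_step(ext, linker_residues)
  }
  structure(list(
    stoichiometry_mix = mix,
    radial_model = radial_model,
    radius_mean = radius_mean,
    radius_sd = radius_sd,
    linker_residues = linker_residues,
    step_length_b = step_length_b,
    dimer_fraction = dimer_fraction,
    dimer_separation = dimer_separation,
    compact_fraction = compact_fraction,
    noise_sd = noise_sd,
    hub_radius = hub_radius,
    kinase_radius = kinase_radius,
    compact_cutoff = compact_cutoff,
    pixel_size = pixel_size,
    box_px = box_px,
    seed = seed
  ), class = "sim_config")
}

#' Isoform preset configurations
#'
#' `alpha_config()` parameterizes the generator at the alpha-isoform
#' ensemble statistics (radius 12.6 +/- 1.6 nm, 31-residue linker,
#' 12/14-mer census 88/5.2%); `beta_config()` at the beta-isoform values
#' (16.8 +/- 3.3 nm, 92-residue linker, 12/14/16-mer census
#' 92.7/5.5/0.4%).
#'
#' @param ... overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
alpha_config <- function(...) {
  defaults <- list(
    stoichiometry_mix = c("12" = 0.88, "14" = 0.052),
    radius_mean = 12.6, radius_sd = 1.6, linker_residues = 31
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

#' @rdname alpha_config
#' @export
beta_config <- function(...) {
  defaults <- list(
    stoichiometry_mix = c("12" = 0.927, "14" = 0.055, "16" = 0.004),
    radius_mean = 16.8, radius_sd = 3.3, linker_residues = 92
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  mix <- paste(sprintf("%s-mer: %.1f%%", names(x$stoichiometry_mix),
                       100 * x$stoichiometry_mix), collapse = ", ")
  cat("  stoichiometry:", mix, "\n")
  cat(sprintf("  radial model: %s (mean %.2f nm, SD %.2f nm; chain N=%d, b=%.3f nm)\n",
              x$radial_model, x$radius_mean, x$radius_sd,
              x$linker_residues, x$step_length_b))
  cat(sprintf("  dimer fraction %.3f (sep %.2f nm), compact fraction %.3f\n",
              x$dimer_fraction, x$dimer_separation, x$compact_fraction))
  cat(sprintf("  noise SD %.3f nm; hub radius %.2f nm; kinase radius %.2f nm\n",
              x$noise_sd, x$hub_radius, x$kinase_radius))
  invisible(x)
}
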