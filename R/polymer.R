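#' Expected end-to-end distance of a random-chain linker
#'
#' Freely jointed (Gaussian) chain null model for the disordered linker
#' tethering each kinase domain: with N steps of effective length b, the
#' root-mean-square end-to-end distance is `b * sqrt(N)`. One step per
#' residue; b is an effective parameter absorbing all chain physics.
#'
#' @param n_residues number of linker residues N (>= 1).
#' @param step_length_b effective step length b (nm, > 0).
#' @return RMS end-to-end distance (nm).
#' @export
#' @examples
#' expected_end_to_end(92, 0.709) / expected_end_to_end(31, 0.709)  # ~1.72
expected_end_to_end <- function(n_residues, step_length_b) {
  if (any(n_residues < 1)) stop("n_residues must be >= 1")
  if (any(step_length_b <= 0)) stop("step_length_b must be positive")
  step_length_b * sqrt(n_residues)
}

#' Calibrate the effective step length from an observed extension
#'
#' Inverts the sqrt-N law: `b = extension / sqrt(N)`. Used to anchor the
#' chain radial model to a measured mean linker extension (e.g. 6.8 nm
#' over 92 residues, or 2.7 nm over 31).
#'
#' @param observed_extension_nm mean linker extension (nm, > 0).
#' @param n_residues number of linker residues.
#' @return Effective step length b (nm).
#' @export
calibrate_step <- function(observed_extension_nm, n_residues) {
  if (any(observed_extension_nm <= 0)) stop("extension must be positive")
  if (any(n_residues < 1)) stop("n_residues must be >= 1")
  observed_extension_nm / sqrt(n_residues)
}

#' Sample Gaussian-chain end-to-end extensions
#'
#' Draws 3D Gaussian end-to-end vectors (per-axis SD `b * sqrt(N/3)`)
#' and returns their lengths; with `projected = TRUE` one axis is
#' dropped first, giving the in-plane extension seen in a 2D projection
#' (RMS `b * sqrt(2N/3)` instead of `b * sqrt(N)`).
#'
#' @inheritParams expected_end_to_end
#' @param n_samples number of chains to draw.
#' @param seed integer seed.
#' @param projected drop one axis before taking the length?
#' @return Numeric vector of extensions (nm).
#' @export
sample_chain_extensions <- function(n_residues, step_length_b, n_samples,
                                    seed = NULL, projected = FALSE) {
  if (n_residues < 1 || step_length_b <= 0) stop("invalid chain parameters")
  if (!is.null(seed)) set.seed(seed)
  sdax <- step_length_b * sqrt(n_residues / 3)
  k <- if (projected) 2 else 3
  comps <- matrix(stats::rnorm(k * n_samples, 0, sdax), ncol = k)
  sqrt(rowSums(comps^2))
}
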