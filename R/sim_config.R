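#' Simulation configuration for two-epoch catFISH ground truth
#'
#' Bundles the generative parameters used by [simulate_labels()],
#' [place_cells()] and [render_stack()]. Each simulated neuron is active in
#' epoch 1 and/or epoch 2 according to a bivariate Bernoulli law with
#' marginals `p1`, `p2` and joint probability
#' \deqn{P(E_1 \cap E_2) = p_1 p_2 + \kappa\,(\min(p_1,p_2) - p_1 p_2),}
#' so that the expected similarity score of the generated population equals
#' `kappa` exactly: `kappa = 0` gives two statistically independent
#' ensembles, `kappa = 1` a single faithfully reactivated ensemble.
#'
#' Intensities are on a \[0, 1\] scale throughout (TIFF-native). Defaults
#' emulate hippocampal pyramidal-layer stacks: roughly a quarter to a third
#' of neurons active per epoch, 40 optical sections, dim textured neuronal
#' nuclei against solid bright glial nuclei, paired intranuclear
#' transcription foci spanning several planes, and perinuclear cytoplasmic
#' rings.
#'
#' @param n_cells number of nuclei (neurons + glia) to simulate.
#' @param p1,p2 marginal activation probabilities for epoch 1 (cytoplasmic
#'   signal at sacrifice) and epoch 2 (intranuclear foci), in \[0, 1\].
#' @param kappa overlap parameter; must lie in the feasible interval given by
#'   [kappa_bounds()] (Frechet constraints on the joint probability).
#' @param glia_fraction proportion of nuclei that are glial, in \[0, 1).
#'   Glia are never Arc-active.
#' @param stack_shape integer `(z, y, x)` voxel counts of the rendered stack.
#' @param noise_sd additive Gaussian noise scale, intensity units.
#' @param foci_planes number of consecutive z-planes a transcription focus
#'   spans (default 4, above the classification minimum of 3).
#' @param ring_planes number of consecutive z-planes a cytoplasmic ring
#'   spans (default 5, above the classification minimum of 4).
#' @param ring_coverage angular fraction of the nucleus perimeter covered by
#'   the cytoplasmic ring, in \[0, 1\]. Rendered arcs are quantized to whole
#'   10-degree sectors so that the rendered coverage is exactly
#'   `round(ring_coverage * 36) / 36`.
#' @param nucleus_radius in-plane nucleus radius, pixels.
#' @param z_ratio ratio of the nucleus z-half-extent (in planes) to
#'   `nucleus_radius`; models confocal z-anisotropy.
#' @param neuron_mean mean counterstain intensity of neuronal nuclei.
#' @param glia_brightness glial counterstain intensity as a multiple of
#'   `neuron_mean` (glia look solid and bright).
#' @param speckle_cv coefficient of variation of the multiplicative speckle
#'   texture inside neuronal nuclei; glia are rendered near-uniform.
#' @param arc_amp peak intensity of rendered Arc signal (foci and rings).
#' @param foci_radius in-plane radius of a transcription focus, pixels.
#' @param ring_thickness radial thickness of the cytoplasmic ring, pixels.
#' @param z_step optical section thickness in micrometers (metadata only).
#' @param seed integer RNG seed; the same config yields bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [kappa_bounds()], [simulate_labels()], [render_stack()]
#' @examples
#' cfg <- sim_config(n_cells = 50, p1 = 0.33, p2 = 0.25, kappa = 0.5, seed = 1)
#' cfg$kappa
#' @export
sim_config <- function(n_cells = 1000, p1 = 0.33, p2 = 0.25, kappa = 0.5,
                       glia_fraction = 0.25,
                       stack_shape = c(40L, 256L, 256L),
                       noise_sd = 0.05,
                       foci_planes = 4L, ring_planes = 5L,
                       ring_coverage = 0.9,
                       nucleus_radius = 8, z_ratio = 0.5,
                       neuron_mean = 0.35, glia_brightness = 1.8,
                       speckle_cv = 0.30,
                       arc_amp = 0.8, foci_radius = 2, ring_thickness = 3,
                       z_step = 0.3, seed = NULL) {
  stopifnot(length(n_cells) == 1, n_cells >= 1, n_cells == round(n_cells))
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("`p1` and `p2` must lie in [0, 1]", call. = FALSE)
  if (glia_fraction < 0 || glia_fraction >= 1)
    stop("`glia_fraction` must lie in [0, 1)", call. = FALSE)
  if (ring_coverage < 0 || ring_coverage > 1)
    stop("`ring_coverage` must lie in [0, 1]", call. = FALSE)
  if (length(stack_shape) != 3 || any(stack_shape < 1))
    stop("`stack_shape` must be positive (z, y, x) counts", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  bounds <- kappa_bounds(p1, p2)
  if (kappa < bounds[1] - 1e-12 || kappa > bounds[2] + 1e-12)
    stop(sprintf(
      "infeasible `kappa` = %g for p1 = %g, p2 = %g: feasible interval is [%.6g, %.6g]",
      kappa, p1, p2, bounds[1], bounds[2]), call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells), p1 = p1, p2 = p2, kappa = kappa,
    glia_fraction = glia_fraction,
    stack_shape = as.integer(stack_shape),
    noise_sd = noise_sd,
    foci_planes = as.integer(foci_planes),
    ring_planes = as.integer(ring_planes),
    ring_coverage = ring_coverage,
    nucleus_radius = nucleus_radius, z_ratio = z_ratio,
    neuron_mean = neuron_mean, glia_brightness = glia_brightness,
    speckle_cv = speckle_cv,
    arc_amp = arc_amp, foci_radius = foci_radius,
    ring_thickness = ring_thickness,
    z_step = z_step, seed = seed), class = "sim_config")
}

#' Feasible interval of the overlap parameter
#'
#' The joint activation probability of a bivariate Bernoulli is constrained
#' by the Frechet bounds `max(0, p1 + p2 - 1) <= P(E1 E2) <= min(p1, p2)`.
#' Under the parameterization
#' `P(E1 E2) = p1 p2 + kappa (min(p1, p2) - p1 p2)` the upper bound maps to
#' `kappa = 1` and the lower bound to
#' `kappa_min = (max(0, p1 + p2 - 1) - p1 p2) / (min(p1, p2) - p1 p2)`.
#'
#' @param p1,p2 marginal activation probabilities.
#' @return Numeric length-2 vector `c(kappa_min, 1)`. When the margins are
#'   degenerate (`min(p1, p2) == p1 * p2`, i.e. one margin is 0 or 1) the
#'   joint probability is forced and any kappa is vacuously feasible;
#'   `c(0, 1)` is returned.
#' @export
kappa_bounds <- function(p1, p2) {
  denom <- min(p1, p2) - p1 * p2
  if (denom <= 0) return(c(0, 1))
  c((max(0, p1 + p2 - 1) - p1 * p2) / denom, 1)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("catFISH simulation config\n")
  cat(sprintf("  cells: %d (glia fraction %.2f)\n", x$n_cells, x$glia_fraction))
  cat(sprintf("  activation: p1 = %.3f, p2 = %.3f, kappa = %.3f\n",
              x$p1, x$p2, x$kappa))
  cat(sprintf("  stack: %d x %d x %d (z, y, x), noise sd %.3f\n",
              x$stack_shape[1], x$stack_shape[2], x$stack_shape[3], x$noise_sd))
  cat(sprintf("  foci span %d planes, ring span %d planes, ring coverage %.2f\n",
              x$foci_planes, x$ring_planes, x$ring_coverage))
  invisible(x)
}
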