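#' Simulate two-epoch activation ground truth
#'
#' Draws per-cell activation labels from the bivariate Bernoulli model of
#' [sim_config()]: each neuron is epoch-1 active with probability `p1`,
#' epoch-2 active with probability `p2`, and doubly active with probability
#' `p1 p2 + kappa (min(p1, p2) - p1 p2)`. Glial cells are never active.
#'
#' Sampling uses the conditional decomposition `P(E2 | E1) = p11 / p1`,
#' `P(E2 | not E1) = (p2 - p11) / (1 - p1)`, which is exact for any feasible
#' joint probability. Spatial placement columns (`z`, `y`, `x`, `r`) are
#' left `NA`; [place_cells()] (or [render_stack()], which calls it) fills
#' them by rejection sampling.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` of class `cat_truth` with columns `cell_id`,
#'   `is_neuron`, `e1`, `e2` (logical activation flags), and placement
#'   columns `z`, `y`, `x` (voxel centroid, `NA` until placed) and `r`
#'   (in-plane nucleus radius, pixels).
#' @examples
#' truth <- simulate_labels(sim_config(n_cells = 200, seed = 7))
#' mean(truth$e1[truth$is_neuron])
#' @export
simulate_labels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  with_seed(config$seed, {
    is_neuron <- runif(n) >= config$glia_fraction
    p1 <- config$p1; p2 <- config$p2
    p11 <- joint_prob(p1, p2, config$kappa)
    e1 <- is_neuron & (runif(n) < p1)
    # conditional epoch-2 probability given the epoch-1 outcome
    pc <- ifelse(e1,
                 if (p1 > 0) p11 / p1 else 0,
                 if (p1 < 1) (p2 - p11) / (1 - p1) else 0)
    e2 <- is_neuron & (runif(n) < pc)
    truth <- data.frame(
      cell_id = seq_len(n),
      is_neuron = is_neuron,
      e1 = e1, e2 = e2,
      z = NA_real_, y = NA_real_, x = NA_real_,
      r = config$nucleus_radius)
    class(truth) <- c("cat_truth", "data.frame")
    truth
  })
}

joint_prob <- function(p1, p2, kappa) {
  p1 * p2 + kappa * (min(p1, p2) - p1 * p2)
}

#' Tally ground-truth labels into classification counts
#'
#' Maps each neuron's activation flags onto the four catFISH staining
#' classes: epoch-2-only activity produces intranuclear foci (`nuc`),
#' epoch-1-only activity produces cytoplasmic staining (`cyt`), activity in
#' both epochs produces double staining (`dob`), and inactivity `neg`.
#' Glial cells are excluded, mirroring the analysis rule.
#'
#' @param truth a `cat_truth` data frame from [simulate_labels()].
#' @param ... optional metadata columns passed to [cell_counts()]
#'   (`animal_id`, `region`, `condition`, `pretreatment`).
#' @return A one-row [cell_counts()] data frame.
#' @export
truth_counts <- function(truth, ...) {
  stopifnot(is.data.frame(truth))
  nrn <- truth[truth$is_neuron, , drop = FALSE]
  cell_counts(
    neg = sum(!nrn$e1 & !nrn$e2),
    nuc = sum(!nrn$e1 & nrn$e2),
    cyt = sum(nrn$e1 & !nrn$e2),
    dob = sum(nrn$e1 & nrn$e2),
    ...)
}

#' Place simulated nuclei in the stack volume
#'
#' Fills the `z`, `y`, `x` columns of a ground-truth table by rejection
#' sampling: centers are drawn uniformly within the stack margins and
#' accepted only if their in-plane distance to every previously placed
#' nucleus exceeds `2 r + clearance`, which guarantees non-overlapping
#' nuclei and keeps each cell's perinuclear annulus free of its neighbors'
#' rings. Centroid z is an integer plane chosen so the nucleus (and its
#' foci/ring spans) fits in the stack.
#'
#' @param truth a `cat_truth` data frame.
#' @param config a [sim_config()] object.
#' @param clearance minimum in-plane gap between nucleus rims, pixels
#'   (default 10, which keeps each cell's measurement annulus clear of its
#'   neighbors' rings).
#' @param max_tries placement attempts per cell before giving up.
#' @return `truth` with placement columns filled.
#' @export
place_cells <- function(truth, config, clearance = 10, max_tries = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  shp <- config$stack_shape  # (z, y, x)
  r <- config$nucleus_radius
  zr <- max(1L, as.integer(round(r * config$z_ratio)))
  margin <- r + config$ring_thickness + 2
  if (shp[2] <= 2 * margin || shp[3] <= 2 * margin)
    stop("stack xy extent too small for the nucleus radius", call. = FALSE)
  half_span <- max(zr, config$ring_planes %/% 2 + 1, config$foci_planes %/% 2 + 1)
  zlo <- half_span + 1L
  zhi <- shp[1] - half_span
  if (zhi < zlo)
    stop("stack has too few planes for the nucleus z-extent", call. = FALSE)
  mind2 <- (2 * r + clearance)^2
  seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n); zs <- integer(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, margin + 1, shp[3] - margin)
        y <- runif(1, margin + 1, shp[2] - margin)
        if (i > 1) {
          d2 <- (xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2
          if (min(d2) < mind2) next
        }
        xs[i] <- x; ys[i] <- y
        zs[i] <- sample(zlo:zhi, 1L)
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "could not place %d non-overlapping nuclei of radius %g in a %d x %d field (failed at cell %d after %d tries); enlarge the stack or reduce n_cells",
          n, r, shp[2], shp[3], i, max_tries), call. = FALSE)
    }
    truth$z <- zs; truth$y <- ys; truth$x <- xs
    truth$r <- r
    truth
  })
}

#' Criterion-implied class labels for rendered ground truth
#'
#' Returns the label the classification criteria assign to each cell given
#' how it was rendered. This accounts for boundary renderings: an
#' epoch-2-active neuron whose foci were rendered across fewer than
#' `min_foci_planes` planes is expected `negative`, a ring spanning fewer
#' than `min_ring_planes` planes or covering at most `coverage_min` of the
#' perimeter does not count as cytoplasmic. Rendered ring arcs are
#' quantized to whole angular sectors, so the effective coverage is
#' `round(ring_coverage * n_sectors) / n_sectors`.
#'
#' Per-cell rendering overrides (columns `foci_planes`, `ring_planes`,
#' `ring_coverage` in `truth`) take precedence over the config values.
#'
#' @param truth a `cat_truth` data frame.
#' @param config the [sim_config()] used for rendering.
#' @param min_foci_planes,min_ring_planes,coverage_min,n_sectors the
#'   classification thresholds (defaults match [classify_options()]).
#' @return Character vector of expected labels (`"negative"`, `"nuclear"`,
#'   `"cytoplasmic"`, `"double"`); `NA` for glial cells (excluded).
#' @export
expected_labels <- function(truth, config, min_foci_planes = 3L,
                            min_ring_planes = 4L, coverage_min = 0.6,
                            n_sectors = 36L) {
  fp <- truth$foci_planes %||% rep(config$foci_planes, nrow(truth))
  rp <- truth$ring_planes %||% rep(config$ring_planes, nrow(truth))
  rc <- truth$ring_coverage %||% rep(config$ring_coverage, nrow(truth))
  cov_eff <- round(rc * n_sectors) / n_sectors
  nuclear <- truth$e2 & fp >= min_foci_planes
  cyto <- truth$e1 & rp >= min_ring_planes & cov_eff > coverage_min
  lab <- ifelse(nuclear & cyto, "double",
         ifelse(nuclear, "nuclear",
         ifelse(cyto, "cytoplasmic", "negative")))
  lab[!truth$is_neuron] <- NA_character_
  lab
}
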