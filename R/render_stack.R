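#' Two-channel 3D image stack
#'
#' Container for a catFISH acquisition: a nuclear counterstain channel and
#' an Arc (Cy3) channel, stored as `(y, x, z)` arrays on a \[0, 1\]
#' intensity scale, plus the optical section spacing.
#'
#' @param counterstain,arc numeric `(y, x, z)` arrays of equal dimension.
#' @param z_step optical section thickness, micrometers per plane.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(counterstain, arc, z_step = 0.3) {
  stopifnot(length(dim(counterstain)) == 3,
            identical(dim(counterstain), dim(arc)))
  if (dim(counterstain)[3] < 3)
    stop("an image stack needs at least 3 planes", call. = FALSE)
  if (min(counterstain) < 0 || min(arc) < 0)
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(counterstain = counterstain, arc = arc, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$counterstain)
  cat(sprintf("image_stack: %d x %d (y, x) pixels, %d planes, z step %.2f um\n",
              d[1], d[2], d[3], x$z_step))
  cat(sprintf("  counterstain range [%.3f, %.3f], arc range [%.3f, %.3f]\n",
              min(x$counterstain), max(x$counterstain),
              min(x$arc), max(x$arc)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$counterstain)

# Paint a filled disc of radius `rad` centered at continuous (cy, cx) into
# plane matrix `m` (returned); values combined by max.
paint_disc <- function(m, cy, cx, rad, value) {
  if (rad < 0.5) return(m)
  y0 <- max(1L, floor(cy - rad)); y1 <- min(nrow(m), ceiling(cy + rad))
  x0 <- max(1L, floor(cx - rad)); x1 <- min(ncol(m), ceiling(cx + rad))
  if (y0 > y1 || x0 > x1) return(m)
  yy <- y0:y1; xx <- x0:x1
  d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
  sub <- m[yy, xx, drop = FALSE]
  sel <- d2 <= rad^2 & sub < value
  sub[sel] <- value
  m[yy, xx] <- sub
  m
}

# Paint an annular arc (inner <= dist < outer, angle within the sectors in
# `sectors`, 1-based sector indices over n_sectors bins starting at angle 0).
paint_arc <- function(m, cy, cx, inner, outer, sectors, n_sectors, value) {
  y0 <- max(1L, floor(cy - outer)); y1 <- min(nrow(m), ceiling(cy + outer))
  x0 <- max(1L, floor(cx - outer)); x1 <- min(ncol(m), ceiling(cx + outer))
  if (y0 > y1 || x0 > x1) return(m)
  yy <- y0:y1; xx <- x0:x1
  dy <- matrix(yy - cy, length(yy), length(xx))
  dx <- matrix(xx - cx, length(yy), length(xx), byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  sec <- angle_sector(dy, dx, n_sectors)
  sub <- m[yy, xx, drop = FALSE]
  sel <- d >= inner & d < outer & sec %in% sectors & sub < value
  sub[sel] <- value
  m[yy, xx] <- sub
  m
}

# 1-based angular sector index of offsets (dy, dx) in n_sectors bins;
# angle measured from +x axis, y-down image convention.
angle_sector <- function(dy, dx, n_sectors) {
  a <- atan2(dy, dx)               # (-pi, pi]
  a <- (a + 2 * pi) %% (2 * pi)    # [0, 2 pi)
  pmin(floor(a / (2 * pi / n_sectors)), n_sectors - 1) + 1L
}

# Paint a textured disc: intensities mean * (1 + cv * field) where the
# field is spatially correlated unit-variance noise (smoothed white noise)
# clipped to +/- 2 sd, giving the speckled look of neuronal nuclei.
paint_textured_disc <- function(m, cy, cx, rad, mean_val, cv, sigma = 1.5) {
  if (rad < 0.5) return(m)
  y0 <- max(1L, floor(cy - rad)); y1 <- min(nrow(m), ceiling(cy + rad))
  x0 <- max(1L, floor(cx - rad)); x1 <- min(ncol(m), ceiling(cx + rad))
  if (y0 > y1 || x0 > x1) return(m)
  yy <- y0:y1; xx <- x0:x1
  # pad the patch so the Gaussian kernel fits, then crop
  side <- max(length(yy), length(xx)) + 12L
  w <- EBImage::gblur(matrix(rnorm(side * side), side, side), sigma = sigma)
  w <- w / stats::sd(as.vector(w))
  f <- w[seq_along(yy), seq_along(xx), drop = FALSE]
  vals <- mean_val * (1 + cv * pmin(pmax(f, -2), 2))
  d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
  sub <- m[yy, xx, drop = FALSE]
  sel <- d2 <= rad^2 & sub < vals
  sub[sel] <- vals[sel]
  m[yy, xx] <- sub
  m
}

#' Render a catFISH-like two-channel 3D stack from ground truth
#'
#' Produces an [image_stack()] whose appearance mirrors real catFISH
#' acquisitions: in the counterstain channel, neuronal nuclei are dim with
#' multiplicative speckle texture while glial nuclei are solid and bright;
#' in the Arc channel, epoch-2-active neurons carry two bright intranuclear
#' transcription foci each spanning `foci_planes` consecutive planes, and
#' epoch-1-active neurons carry a perinuclear cytoplasmic ring covering
#' `ring_coverage` of the perimeter over `ring_planes` consecutive planes.
#' Nuclei are spheres (z-compressed by `z_ratio`); rings hug the per-plane
#' nucleus outline. Additive Gaussian noise of scale `noise_sd` is applied
#' to both channels and intensities are clipped to \[0, 1\].
#'
#' Per-cell rendering overrides may be supplied as optional `truth` columns
#' `foci_planes`, `ring_planes`, `ring_coverage`; this is how boundary
#' fixtures (e.g. foci spanning only 2 planes) are built.
#'
#' @param truth a `cat_truth` data frame; unplaced cells are placed with
#'   [place_cells()] first.
#' @param config a [sim_config()] object.
#' @return An [image_stack()]; the (possibly placed) truth table is
#'   attached as attribute `"truth"`.
#' @examples
#' cfg <- sim_config(n_cells = 6, stack_shape = c(20L, 128L, 128L),
#'                   noise_sd = 0, seed = 3)
#' st <- render_stack(simulate_labels(cfg), cfg)
#' dim(st)
#' @export
render_stack <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  if (anyNA(truth$z)) truth <- place_cells(truth, config)
  shp <- config$stack_shape
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  nuc <- array(0, c(ny, nx, nz))
  arc <- array(0, c(ny, nx, nz))
  r <- config$nucleus_radius
  zr <- max(1L, as.integer(round(r * config$z_ratio)))
  n_sectors <- 36L
  fp_all <- truth$foci_planes %||% rep(config$foci_planes, nrow(truth))
  rp_all <- truth$ring_planes %||% rep(config$ring_planes, nrow(truth))
  rc_all <- truth$ring_coverage %||% rep(config$ring_coverage, nrow(truth))

  seed <- if (is.null(config$seed)) NULL else config$seed + 2L
  with_seed(seed, {
    glia_val <- config$neuron_mean * config$glia_brightness
    for (i in seq_len(nrow(truth))) {
      cy <- truth$y[i]; cx <- truth$x[i]; cz <- truth$z[i]
      # nucleus: sphere cross-sections
      for (dz in -zr:zr) {
        z <- cz + dz
        if (z < 1 || z > nz) next
        rz <- r * sqrt(max(0, 1 - (dz / zr)^2))
        if (truth$is_neuron[i]) {
          nuc[, , z] <- paint_textured_disc(nuc[, , z], cy, cx, rz,
                                            config$neuron_mean,
                                            config$speckle_cv)
        } else {
          nuc[, , z] <- paint_disc(nuc[, , z], cy, cx, rz, glia_val)
        }
      }
      if (!truth$is_neuron[i]) next
      # epoch-2 activity: two intranuclear transcription foci
      if (truth$e2[i] && fp_all[i] >= 1) {
        # the two alleles' foci sit apart but well interior: the offset keeps
        # them separated even after median filtering while leaving a margin
        # to the thresholded nucleus outline at every plane they span
        theta <- runif(1, 0, 2 * pi)
        off <- 0.45 * r
        z0 <- cz - (fp_all[i] - 1L) %/% 2L
        for (k in c(-1, 1)) {
          fy <- cy + k * off * sin(theta)
          fx <- cx + k * off * cos(theta)
          for (z in z0:(z0 + fp_all[i] - 1L)) {
            if (z < 1 || z > nz) next
            arc[, , z] <- paint_disc(arc[, , z], fy, fx,
                                     config$foci_radius, config$arc_amp)
          }
        }
      }
      # epoch-1 activity: perinuclear cytoplasmic ring (sector-quantized arc)
      if (truth$e1[i] && rp_all[i] >= 1) {
        nsec <- round(rc_all[i] * n_sectors)
        if (nsec >= 1) {
          s0 <- sample.int(n_sectors, 1L)
          sectors <- ((s0 - 1L + seq_len(nsec) - 1L) %% n_sectors) + 1L
          z0 <- cz - (rp_all[i] - 1L) %/% 2L
          for (z in z0:(z0 + rp_all[i] - 1L)) {
            if (z < 1 || z > nz) next
            dz <- z - cz
            rz <- r * sqrt(max(0, 1 - (dz / zr)^2))
            if (rz < 1) rz <- 1
            arc[, , z] <- paint_arc(arc[, , z], cy, cx, rz + 1,
                                    rz + 1 + config$ring_thickness,
                                    sectors, n_sectors, config$arc_amp)
          }
        }
      }
    }
    if (config$noise_sd > 0) {
      nuc <- nuc + array(rnorm(length(nuc), 0, config$noise_sd), dim(nuc))
      arc <- arc + array(rnorm(length(arc), 0, config$noise_sd), dim(arc))
      nuc[nuc < 0] <- 0; nuc[nuc > 1] <- 1
      arc[arc < 0] <- 0; arc[arc > 1] <- 1
    }
    st <- image_stack(nuc, arc, z_step = config$z_step)
    attr(st, "truth") <- truth
    st
  })
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-interleaved in z-major order (plane 1 counterstain,
#' plane 1 arc, plane 2 counterstain, ...), 16-bit. The sidecar
#' (`<path>.json`) records the voxel spacing and channel names.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$counterstain)[3]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- pmin(pmax(stack$counterstain[, , z], 0), 1)
    pages[[2L * z]] <- pmin(pmax(stack$arc[, , z], 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(z_step = stack$z_step, n_planes = nz,
         channels = c("counterstain", "arc"), order = "z-major interleaved"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nz <- as.integer(meta$n_planes)
  stopifnot(length(pages) == 2L * nz)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  nuc <- array(0, c(ny, nx, nz)); arc <- array(0, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    nuc[, , z] <- pages[[2L * z - 1L]]
    arc[, , z] <- pages[[2L * z]]
  }
  image_stack(nuc, arc, z_step = meta$z_step)
}

#' Write / read ground truth as CSV
#'
#' On-disk coordinates are 0-based (z, y, x), y-down, matching the image
#' voxel grid; in-memory tables use R's 1-based convention.
#'
#' @param truth a `cat_truth` data frame.
#' @param path CSV path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the table.
#' @export
write_truth <- function(truth, path) {
  out <- truth[, c("cell_id", "is_neuron", "e1", "e2", "z", "y", "x", "r")]
  out$z <- out$z - 1; out$y <- out$y - 1; out$x <- out$x - 1
  out$is_neuron <- as.integer(out$is_neuron)
  out$e1 <- as.integer(out$e1); out$e2 <- as.integer(out$e2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.csv(path)
  tr$z <- tr$z + 1; tr$y <- tr$y + 1; tr$x <- tr$x + 1
  tr$is_neuron <- as.logical(tr$is_neuron)
  tr$e1 <- as.logical(tr$e1); tr$e2 <- as.logical(tr$e2)
  class(tr) <- c("cat_truth", "data.frame")
  tr
}
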