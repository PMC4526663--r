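#' Default 14-segment hippocampal ROI layout
#'
#' The standard dendritic-lamina parcellation used for synaptophysin/Map2
#' densitometry: CA3 stratum oriens, lucidum, and radiatum each split by
#' proximity to the dentate gyrus (and, for radiatum, to the pyramidal
#' soma), plus CA1 stratum oriens and radiatum — 14 named segments. For
#' the synthetic mosaic the segments are laid out as rectangles on a grid;
#' real analyses supply hand-drawn polygons instead.
#'
#' @param roi_size side length of each square ROI, pixels.
#' @param gap spacing between ROIs, pixels.
#' @return Named list of n x 2 `(x, y)` polygon vertex matrices (1-based
#'   pixel coordinates, y-down).
#' @export
default_roi_spec <- function(roi_size = 120L, gap = 12L) {
  names14 <- c("SOd", "SOm", "SOp", "SLd", "SLm", "SLp",
               "SRdm", "SRmm", "SRpm", "SRdd", "SRmd", "SRpd",
               "CA1_SO", "CA1_SR")
  rois <- list()
  for (i in seq_along(names14)) {
    row <- (i - 1L) %/% 4L
    col <- (i - 1L) %% 4L
    x0 <- gap + col * (roi_size + gap) + 1L
    y0 <- gap + row * (roi_size + gap) + 1L
    rois[[names14[i]]] <- cbind(
      x = c(x0, x0 + roi_size, x0 + roi_size, x0),
      y = c(y0, y0, y0 + roi_size, y0 + roi_size))
  }
  rois
}

mosaic_dims <- function(rois, pad = 12L) {
  xs <- unlist(lapply(rois, function(p) p[, 1]))
  ys <- unlist(lapply(rois, function(p) p[, 2]))
  c(ceiling(max(ys)) + pad, ceiling(max(xs)) + pad)  # (ny, nx)
}

#' Render a synaptophysin/Map2-like mosaic with known area fractions
#'
#' Builds a three-channel 2D mosaic (nuclear counterstain, Map2,
#' synaptophysin) in which each ROI's synaptophysin area fraction is known
#' by construction. Per ROI, a dendritic Map2 field fills the polygon
#' interior (eroded margin); the measurement mask is derived exactly as
#' the analysis does — threshold, then dilation to 110% of the thresholded
#' area — and synaptophysin puncta are placed on randomly chosen mask
#' pixels until they occupy `true_fractions[roi]` percent of the mask.
#' Rasterization keeps the realized fraction within 0.5 percentage points
#' of the request.
#'
#' @param roi_spec named list of ROI polygons (see [default_roi_spec()]).
#' @param true_fractions named numeric vector (percent, in \[0, 100\]),
#'   one entry per ROI.
#' @param seed RNG seed.
#' @param enlargement Map2-ROI enlargement used to define the target mask
#'   (must match the analysis setting; default 0.10).
#' @param map2_level,syn_level,noise_sd rendering intensities (\[0, 1\]
#'   scale) and background noise.
#' @return A list of class `mosaic`: matrices `nuclear`, `map2`, `syn`,
#'   plus `rois` and a `truth` data frame (`roi_name`, `true_fraction`).
#' @examples
#' rois <- default_roi_spec()[1:2]
#' mz <- render_mosaic(rois, c(SOd = 25, SOm = 60), seed = 1)
#' measure_mosaic(mz, mz$rois)$fraction
#' @export
render_mosaic <- function(roi_spec, true_fractions, seed = NULL,
                          enlargement = 0.10, map2_level = 0.6,
                          syn_level = 0.8, noise_sd = 0.02) {
  stopifnot(is.list(roi_spec), length(roi_spec) >= 1)
  if (is.null(names(true_fractions)))
    names(true_fractions) <- names(roi_spec)
  missing_rois <- setdiff(names(roi_spec), names(true_fractions))
  if (length(missing_rois))
    stop("no true_fraction for ROI(s): ", paste(missing_rois, collapse = ", "),
         call. = FALSE)
  if (any(true_fractions < 0 | true_fractions > 100))
    stop("true_fractions must lie in [0, 100] percent", call. = FALSE)
  d <- mosaic_dims(roi_spec)
  with_seed(seed, {
    map2 <- matrix(0, d[1], d[2])
    syn <- matrix(0, d[1], d[2])
    nuclear <- matrix(0, d[1], d[2])
    # internal threshold set reproducing what any between-mode threshold
    # computes on the rendered channels
    thr <- structure(list(map2_threshold = map2_level / 2,
                          syn_threshold = syn_level / 2,
                          calibration_image_id = "render"),
                     class = "threshold_set")
    for (nm in names(roi_spec)) {
      pmask <- polygon_mask(roi_spec[[nm]], d)
      # dendritic field: polygon interior with an eroded margin
      dend <- EBImage::erode(pmask, EBImage::makeBrush(9L, "disc"))
      if (!any(dend)) dend <- pmask
      map2[dend] <- map2_level
      mask <- map2_roi(list(map2 = map2), roi_spec[[nm]], thr, enlargement)
      idx <- which(mask)
      n_on <- round(true_fractions[[nm]] / 100 * length(idx))
      if (n_on > 0) syn[sample(idx, n_on)] <- syn_level
    }
    # sparse decorative nuclei in the counterstain channel
    for (k in seq_len(max(4L, length(roi_spec) * 3L))) {
      cy <- runif(1, 6, d[1] - 6); cx <- runif(1, 6, d[2] - 6)
      nuclear <- paint_disc(nuclear, cy, cx, 3, 0.5)
    }
    if (noise_sd > 0) {
      for (ch in c("map2", "syn", "nuclear")) {
        m <- get(ch) + matrix(rnorm(length(map2), 0, noise_sd), d[1], d[2])
        m[m < 0] <- 0; m[m > 1] <- 1
        assign(ch, m)
      }
    }
    structure(list(nuclear = nuclear, map2 = map2, syn = syn,
                   rois = roi_spec,
                   truth = data.frame(roi_name = names(roi_spec),
                                      true_fraction = unname(
                                        true_fractions[names(roi_spec)]))),
              class = "mosaic")
  })
}

#' Write / read ROI polygons as JSON
#'
#' The on-disk format is a JSON list of `{name, polygon: [[x, y], ...]}`
#' with 0-based pixel coordinates, y-down; in-memory polygons use R's
#' 1-based convention.
#'
#' @param rois named list of n x 2 `(x, y)` polygon matrices.
#' @param path JSON file path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the list.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(names(rois), function(nm) {
    m <- rois[[nm]] - 1
    list(name = nm,
         polygon = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(payload, function(el) {
    m <- do.call(rbind, lapply(el$polygon, function(v) unlist(v))) + 1
    colnames(m) <- c("x", "y")
    m
  })
  names(rois) <- vapply(payload, `[[`, character(1), "name")
  rois
}

#' Write a mosaic as a 3-page TIFF with JSON sidecar
#'
#' Page order: nuclear, Map2, synaptophysin; 16-bit.
#'
#' @param mosaic a `mosaic` list.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path) {
  tiff::writeTIFF(list(pmin(pmax(mosaic$nuclear, 0), 1),
                       pmin(pmax(mosaic$map2, 0), 1),
                       pmin(pmax(mosaic$syn, 0), 1)),
                  path, bits.per.sample = 16L)
  jsonlite::write_json(list(channels = c("nuclear", "map2", "syn")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 3)
  structure(list(nuclear = pages[[1]], map2 = pages[[2]], syn = pages[[3]],
                 rois = NULL, truth = NULL), class = "mosaic")
}
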