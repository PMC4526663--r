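#' Calibrate slide-constant intensity thresholds on a control image
#'
#' Chooses one optical-density threshold per channel (Map2 and
#' synaptophysin) from a control mosaic, by Otsu's between-class-variance
#' rule on the pixels inside the union of the ROI polygons (or the whole
#' image if no polygons are given). The thresholds are then held fixed for
#' every image of the slide, so all measurements on a slide share one
#' calibration.
#'
#' @param control a mosaic list with `map2` and `syn` matrices on \[0, 1\]
#'   (as produced by [render_mosaic()] or assembled from TIFF channels).
#' @param rois optional named list of ROI polygons (n x 2 `(x, y)`
#'   matrices) restricting the calibration pixels.
#' @param calibration_image_id identifier recorded in the result.
#' @return A list of class `threshold_set` with `map2_threshold`,
#'   `syn_threshold`, `calibration_image_id`.
#' @export
calibrate_thresholds <- function(control, rois = NULL,
                                 calibration_image_id = NA_character_) {
  stopifnot(is.matrix(control$map2), is.matrix(control$syn))
  sel <- if (is.null(rois)) rep(TRUE, length(control$map2)) else {
    m <- matrix(FALSE, nrow(control$map2), ncol(control$map2))
    for (pg in rois) m <- m | polygon_mask(pg, dim(control$map2))
    as.vector(m)
  }
  otsu1 <- function(v, channel) {
    if (max(v) - min(v) < .Machine$double.eps^0.5)
      stop(sprintf("cannot calibrate a threshold on a constant-intensity %s channel",
                   channel), call. = FALSE)
    otsu_pooled(v)
  }
  structure(list(map2_threshold = otsu1(as.vector(control$map2)[sel], "Map2"),
                 syn_threshold = otsu1(as.vector(control$syn)[sel], "synaptophysin"),
                 calibration_image_id = calibration_image_id),
            class = "threshold_set")
}

# Rasterize a polygon ((x, y) vertex matrix, 1-based pixel centers) into a
# logical (ny, nx) mask via point-in-polygon on the bounding-box grid.
polygon_mask <- function(polygon, dims) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  ny <- dims[1]; nx <- dims[2]
  x0 <- max(1L, floor(min(polygon[, 1]))); x1 <- min(nx, ceiling(max(polygon[, 1])))
  y0 <- max(1L, floor(min(polygon[, 2]))); y1 <- min(ny, ceiling(max(polygon[, 2])))
  m <- matrix(FALSE, ny, nx)
  if (x0 > x1 || y0 > y1) return(m)
  xx <- x0:x1; yy <- y0:y1
  grid <- cbind(rep(xx, each = length(yy)), rep(yy, times = length(xx)))
  bnd <- rbind(polygon, polygon[1, ])
  inside <- mgcv::in.out(bnd, grid)
  m[cbind(grid[inside, 2], grid[inside, 1])] <- TRUE
  m
}

#' Map2-defined region of interest
#'
#' Builds the measurement ROI for one hippocampal segment: the
#' above-threshold Map2 (dendritic) pixels inside the hand-drawn polygon,
#' then enlarged by morphological dilation until the mask area reaches
#' `(1 + enlargement)` times the thresholded area — the first dilation
#' radius crossing the target is used and any overshoot is recorded. The
#' enlargement covers the perisomatic band where synaptophysin boutons sit
#' just outside the Map2-stained dendrites.
#'
#' @param image mosaic list with a `map2` matrix.
#' @param polygon n x 2 `(x, y)` vertex matrix of the hand-drawn ROI.
#' @param thresholds a `threshold_set` from [calibrate_thresholds()].
#' @param enlargement target fractional area increase (default 0.10).
#' @return A logical mask matrix with attributes `base_area` (thresholded
#'   Map2 area), `dilation_radius` and `overshoot` (achieved/target - 1);
#'   `NULL` with a warning when the polygon contains no Map2 signal.
#' @export
map2_roi <- function(image, polygon, thresholds, enlargement = 0.10) {
  stopifnot(inherits(thresholds, "threshold_set"), enlargement >= 0)
  pmask <- polygon_mask(polygon, dim(image$map2))
  base <- pmask & (image$map2 >= thresholds$map2_threshold)
  base_area <- sum(base)
  if (base_area == 0) {
    warning("no Map2 signal inside the polygon; ROI skipped", call. = FALSE)
    return(NULL)
  }
  target <- (1 + enlargement) * base_area
  mask <- base
  radius <- 0L
  while (sum(mask) < target) {
    radius <- radius + 1L
    mask <- EBImage::dilate(base, EBImage::makeBrush(2L * radius + 1L, "disc"))
  }
  structure(mask, base_area = base_area, dilation_radius = radius,
            overshoot = sum(mask) / target - 1)
}

#' Synaptophysin area fraction of an ROI
#'
#' Counts synaptophysin pixels at or above the calibrated threshold inside
#' the Map2-defined ROI mask and expresses them as a percentage of the ROI
#' area: `fraction = 100 * syn_area / map2_roi_area`.
#'
#' @param image mosaic list with a `syn` matrix.
#' @param roi_mask logical mask from [map2_roi()].
#' @param thresholds a `threshold_set`.
#' @param roi_name,slide_id,animal_id,pretreatment metadata carried into
#'   the result.
#' @return A one-row `data.frame` (class `roi_measure`) with `roi_name`,
#'   `map2_roi_area`, `syn_area`, `fraction`, and the metadata.
#' @export
measure_area_fraction <- function(image, roi_mask, thresholds,
                                  roi_name = NA_character_,
                                  slide_id = NA_character_,
                                  animal_id = NA_character_,
                                  pretreatment = NA_character_) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.null(roi_mask) || sum(roi_mask) == 0)
    stop("empty ROI mask: the area fraction is undefined", call. = FALSE)
  area <- sum(roi_mask)
  syn_area <- sum(image$syn[roi_mask] >= thresholds$syn_threshold)
  out <- data.frame(roi_name = roi_name, slide_id = slide_id,
                    animal_id = animal_id, pretreatment = pretreatment,
                    map2_roi_area = area, syn_area = syn_area,
                    fraction = 100 * syn_area / area)
  class(out) <- c("roi_measure", "data.frame")
  out
}

#' Quantify all ROIs of a mosaic
#'
#' Convenience wrapper: builds the Map2-defined ROI for every polygon and
#' measures its synaptophysin area fraction with one shared
#' [calibrate_thresholds()] set.
#'
#' @param image mosaic list with `map2` and `syn` matrices.
#' @param rois named list of polygons.
#' @param thresholds a `threshold_set`; calibrated on `image` itself if
#'   `NULL` (i.e. the image is its own slide control).
#' @param enlargement passed to [map2_roi()].
#' @param ... metadata passed to [measure_area_fraction()].
#' @return A `roi_measure` data frame, one row per non-empty ROI.
#' @export
measure_mosaic <- function(image, rois, thresholds = NULL,
                           enlargement = 0.10, ...) {
  if (is.null(thresholds)) thresholds <- calibrate_thresholds(image, rois)
  out <- lapply(names(rois), function(nm) {
    mask <- map2_roi(image, rois[[nm]], thresholds, enlargement)
    if (is.null(mask)) return(NULL)
    measure_area_fraction(image, mask, thresholds, roi_name = nm, ...)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Map2-area homogeneity check across pretreatment groups
#'
#' The Map2-stained ROI area is the denominator of every synaptophysin
#' fraction; group differences in it would confound the densitometry. This
#' check runs, per ROI, a one-way ANOVA of `map2_roi_area` across
#' pretreatment groups and reports the F and p alongside the fractions.
#'
#' @param measures a `roi_measure` data frame with `pretreatment` filled,
#'   one row per (animal, ROI).
#' @return A `data.frame` with one row per ROI: `roi_name`, `f`, `df1`,
#'   `df2`, `p`, `degenerate` (TRUE when all values are identical so the
#'   within-group variance vanishes). Returns `NULL` with a message when
#'   fewer than 2 groups are present.
#' @export
map2_area_check <- function(measures) {
  stopifnot(is.data.frame(measures))
  groups <- unique(measures$pretreatment)
  if (length(groups) < 2) {
    message("map2_area_check skipped: fewer than 2 pretreatment groups")
    return(NULL)
  }
  out <- lapply(split(measures, measures$roi_name), function(df) {
    if (stats::var(df$map2_roi_area) == 0)
      return(data.frame(roi_name = df$roi_name[1], f = 0, df1 = NA, df2 = NA,
                        p = NA_real_, degenerate = TRUE))
    res <- one_way_anova(data.frame(value = df$map2_roi_area,
                                    group = df$pretreatment),
                         "value", "group")
    data.frame(roi_name = df$roi_name[1], f = res$statistic,
               df1 = res$df[1], df2 = res$df[2], p = res$p,
               degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
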