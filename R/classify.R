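#' Classification options for catFISH stacks
#'
#' Thresholds and geometry for nucleus segmentation, neuron/glia
#' discrimination, and the compartmental Arc criteria. Intensities are on
#' the \[0, 1\] scale. Defaults were calibrated on synthetic stacks with
#' known ground truth.
#'
#' @param median_radius radius of the per-plane median prefilter applied by
#'   [classify_stack()]; 0 disables filtering.
#' @param nuc_threshold counterstain segmentation threshold; `NULL` selects
#'   it automatically by Otsu's method on the whole stack.
#' @param min_plane_area minimum 2D component area (pixels) retained during
#'   per-plane segmentation.
#' @param min_volume minimum 3D nucleus volume (voxels).
#' @param split_area 2D component area above which watershed splitting of
#'   touching nuclei is attempted on that plane.
#' @param watershed_tolerance tolerance of the distance-map watershed.
#' @param link_overlap minimum fractional overlap (relative to the smaller
#'   component) linking 2D components across consecutive planes.
#' @param cv_min minimum within-mask coefficient of variation of the
#'   counterstain for a nucleus to count as neuronal (neurons are textured).
#' @param brightness_max maximum within-mask mean counterstain intensity
#'   for a neuron (glia are bright).
#' @param dissector_fraction central fraction of planes retained by the
#'   optical dissector.
#' @param focus_threshold minimum Arc intensity of a transcription-focus
#'   pixel.
#' @param focus_min_area,focus_max_area 2D area bounds (pixels) of a focus.
#' @param focus_link_dist maximum centroid displacement (pixels) linking a
#'   focus between consecutive planes.
#' @param min_foci_planes minimum consecutive planes a focus track must
#'   span for the nuclear criterion ("across 3 or more planes").
#' @param ring_threshold minimum Arc intensity of cytoplasmic-ring signal.
#' @param annulus_width width (pixels) of the perinuclear annulus band, a
#'   morphological dilation of the per-plane nucleus mask.
#' @param n_sectors number of angular sectors used to quantify perimeter
#'   coverage (36 sectors of 10 degrees).
#' @param coverage_min perimeter-coverage fraction that must be exceeded
#'   (strictly) for the cytoplasmic criterion ("> 60% surrounded").
#' @param min_ring_planes minimum number of planes (not necessarily
#'   consecutive) with supra-threshold coverage for the cytoplasmic
#'   criterion ("in 4 or more planes").
#' @param ring_consecutive if `TRUE`, require the coverage planes to be
#'   consecutive; off by default (the criterion says "in", not "across").
#' @return A list of class `classify_options`.
#' @export
classify_options <- function(median_radius = 1L,
                             nuc_threshold = NULL,
                             min_plane_area = 10L,
                             min_volume = 400L,
                             split_area = 400L,
                             watershed_tolerance = 2,
                             link_overlap = 0.3,
                             cv_min = 0.10,
                             brightness_max = 0.5,
                             dissector_fraction = 0.30,
                             focus_threshold = 0.4,
                             focus_min_area = 3L,
                             focus_max_area = 200L,
                             focus_link_dist = 3,
                             min_foci_planes = 3L,
                             ring_threshold = 0.4,
                             annulus_width = 5L,
                             n_sectors = 36L,
                             coverage_min = 0.6,
                             min_ring_planes = 4L,
                             ring_consecutive = FALSE) {
  opts <- as.list(environment())
  structure(opts, class = "classify_options")
}

# Otsu threshold over a pooled sample of voxels. EBImage::otsu() computes
# one threshold per frame, so the voxels are packed into a single square
# 2D image first.
otsu_pooled <- function(v) {
  n <- ceiling(sqrt(length(v)))
  img <- EBImage::Image(c(v, rep(v[1], n * n - length(v))), dim = c(n, n))
  unname(EBImage::otsu(img, range = c(0, 1)))
}

#' Median-filter preprocessing
#'
#' Applies a per-plane 2D median filter of the given radius to both
#' channels for noise reduction; radius 0 is the identity.
#'
#' @param stack an [image_stack()].
#' @param radius filter radius in pixels (window is `2 * radius + 1` wide).
#' @return The filtered [image_stack()].
#' @export
preprocess <- function(stack, radius = 1L) {
  stopifnot(inherits(stack, "image_stack"), radius >= 0)
  if (radius == 0) return(stack)
  # EBImage's constant-time median filter quantizes to 2^16 levels on [0,1];
  # a generous histogram cache makes it ~15x faster on full stacks
  f <- function(a) EBImage::medianFilter(pmin(pmax(a, 0), 1), radius,
                                         cacheSize = 4096)
  out <- stack
  out$counterstain <- f(stack$counterstain)
  out$arc <- f(stack$arc)
  out
}

#' Segment nuclei in the counterstain channel
#'
#' Thresholds the counterstain (Otsu by default), labels connected
#' components per plane, splits oversized components with a distance-map
#' watershed, and links components across consecutive planes by pixel
#' overlap into 3D nuclei. Objects below `min_volume` voxels are dropped.
#'
#' @param stack an [image_stack()] (typically after [preprocess()]).
#' @param opts a [classify_options()] list.
#' @return A list of cell records, each a list with `cell_id`, `centroid`
#'   (`z`, `y`, `x`), `volume`, `planes` (plane indices), and `pix` (per-
#'   plane linear pixel indices into the `ny x nx` plane). An empty image
#'   yields an empty list.
#' @export
segment_nuclei <- function(stack, opts = classify_options()) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$counterstain
  d <- dim(a); ny <- d[1]; nx <- d[2]; nz <- d[3]
  thr <- opts$nuc_threshold
  if (is.null(thr)) {
    if (max(a) <= min(a)) return(list())
    thr <- otsu_pooled(as.vector(a))
  }
  # per-plane labeling with optional watershed splitting of merged nuclei
  open_brush <- EBImage::makeBrush(3L, shape = "diamond")
  plane_labels <- vector("list", nz)
  for (z in seq_len(nz)) {
    bw <- a[, , z] >= thr
    if (!any(bw)) { plane_labels[z] <- list(NULL); next }
    # opening removes thin supra-threshold noise clusters that would
    # otherwise attach to nucleus rims and bulge the mask outward over the
    # perinuclear ring; hole-filling then restores the solid nucleus
    # interior where speckle texture dips below threshold
    bw <- EBImage::opening(bw, open_brush)
    bw <- EBImage::fillHull(bw) > 0
    lab <- EBImage::bwlabel(bw)
    areas <- tabulate(lab[lab > 0])
    if (any(areas > opts$split_area)) {
      dm <- EBImage::distmap(bw)
      ws <- EBImage::watershed(dm, tolerance = opts$watershed_tolerance)
      lab <- ws
      areas <- tabulate(lab[lab > 0])
    }
    small <- which(areas < opts$min_plane_area)
    if (length(small)) lab[lab %in% small] <- 0L
    plane_labels[[z]] <- lab
  }
  # link 2D components across planes into 3D objects (union-find)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  comp_pix <- list(); comp_plane <- integer(0)
  idx_of <- new.env(parent = emptyenv())
  add_comp <- function(z, l, pix) {
    k <- length(parent) + 1L
    parent[k] <<- k
    comp_pix[[k]] <<- pix
    comp_plane[k] <<- z
    assign(sprintf("%d_%d", z, l), k, envir = idx_of)
    k
  }
  for (z in seq_len(nz)) {
    lab <- plane_labels[[z]]
    if (is.null(lab)) next
    labs <- setdiff(unique(as.vector(lab)), 0L)
    for (l in labs) {
      pix <- which(lab == l)
      k <- add_comp(z, l, pix)
      if (z > 1 && !is.null(plane_labels[[z - 1]])) {
        prev <- plane_labels[[z - 1]]
        over <- prev[pix]
        over <- over[over > 0]
        if (length(over)) {
          tab <- table(over)
          for (lp in as.integer(names(tab))) {
            kp <- get(sprintf("%d_%d", z - 1L, lp), envir = idx_of)
            ov <- tab[[as.character(lp)]]
            if (ov >= opts$link_overlap * min(length(pix), length(comp_pix[[kp]]))) {
              ra <- find(k); rb <- find(kp)
              if (ra != rb) parent[ra] <- rb
            }
          }
        }
      }
    }
  }
  if (!length(parent)) return(list())
  roots <- vapply(seq_along(parent), find, integer(1))
  cells <- list()
  cid <- 0L
  for (root in unique(roots)) {
    ks <- which(roots == root)
    vol <- sum(lengths(comp_pix[ks]))
    if (vol < opts$min_volume) next
    cid <- cid + 1L
    planes <- comp_plane[ks]
    o <- order(planes)
    ks <- ks[o]; planes <- planes[o]
    # centroid over all member voxels
    sy <- 0; sx <- 0; sz <- 0
    for (j in seq_along(ks)) {
      pix <- comp_pix[[ks[j]]]
      yy <- ((pix - 1L) %% ny) + 1L
      xx <- ((pix - 1L) %/% ny) + 1L
      sy <- sy + sum(yy); sx <- sx + sum(xx); sz <- sz + planes[j] * length(pix)
    }
    cells[[cid]] <- list(
      cell_id = cid,
      centroid = c(z = sz / vol, y = sy / vol, x = sx / vol),
      volume = vol,
      planes = planes,
      pix = comp_pix[ks])
  }
  cells
}

#' Neuron / glia discrimination
#'
#' Neuronal nuclei are textured and dim in the counterstain while glial
#' nuclei are solid and bright; a nucleus counts as neuronal when its
#' within-mask intensity coefficient of variation is at least `cv_min` AND
#' its mean intensity is at most `brightness_max`. Degenerate masks
#' (single voxel, or zero mean, where the CV is undefined) are treated as
#' CV 0 and classified glial with a warning.
#'
#' @param record a cell record from [segment_nuclei()].
#' @param stack the [image_stack()] the record was segmented from.
#' @param opts a [classify_options()] list.
#' @return Logical flag.
#' @export
is_neuron <- function(record, stack, opts = classify_options()) {
  vals <- unlist(mapply(function(z, pix) stack$counterstain[, , z][pix],
                        record$planes, record$pix, SIMPLIFY = FALSE))
  m <- mean(vals)
  if (length(vals) < 2 || m <= 0) {
    warning(sprintf("cell %s: degenerate mask (%d voxel(s)); treated as glial",
                    record$cell_id, length(vals)), call. = FALSE)
    return(FALSE)
  }
  cv <- stats::sd(vals) / m
  cv >= opts$cv_min && m <= opts$brightness_max
}

#' Optical dissector sampling
#'
#' Keeps only cells whose nucleus centroid lies in the central `fraction`
#' of the stack's z-extent, the stereological rule that avoids counting
#' partial cells at the stack faces. In 0-based plane indices the closed
#' window is
#' `[ceiling(n_planes * (1 - fraction) / 2), floor(n_planes * (1 + fraction) / 2)]`
#' (e.g. planes 14..26 of a 40-plane stack at the default fraction);
#' centroids exactly on a boundary plane are kept.
#'
#' @param records list of cell records.
#' @param n_planes number of planes in the stack.
#' @param fraction central fraction retained, in (0, 1\].
#' @return The filtered list of records.
#' @export
optical_dissector <- function(records, n_planes, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  w <- dissector_window(n_planes, fraction)
  Filter(function(rec) {
    z <- rec$centroid["z"]
    z >= w[1] && z <= w[2]
  }, records)
}

#' @rdname optical_dissector
#' @return `dissector_window` returns the closed `(low, high)` plane window
#'   (1-based).
#' @export
dissector_window <- function(n_planes, fraction = 0.30) {
  # 0-based window [ceil(n (1-f)/2), floor(n (1+f)/2)] shifted to 1-based
  lo <- ceiling(n_planes * (1 - fraction) / 2)
  hi <- floor(n_planes * (1 + fraction) / 2)
  c(low = lo + 1L, high = hi + 1L)
}

#' Detect intranuclear transcription foci
#'
#' Per plane of the nucleus, thresholds the Arc channel inside the nucleus
#' mask, keeps connected components whose area lies in
#' `[focus_min_area, focus_max_area]` and whose peak intensity reaches
#' `focus_threshold`, and links detections across consecutive planes by
#' centroid proximity into focus tracks.
#'
#' @param record a cell record from [segment_nuclei()].
#' @param stack the [image_stack()].
#' @param opts a [classify_options()] list.
#' @return A list with `counts` (named integer vector of per-plane focus
#'   counts) and `track_spans` (integer vector: the number of consecutive
#'   planes each linked focus persists).
#' @export
detect_foci <- function(record, stack, opts = classify_options()) {
  ny <- dim(stack$arc)[1]
  counts <- integer(length(record$planes))
  names(counts) <- record$planes
  tracks <- list()  # each: list(last_plane, cy, cx, span)
  # "intranuclear" is judged by component centroid position relative to the
  # nucleus: within 0.85 of the cell's equatorial effective radius (from its
  # largest plane mask, which is stable under noise). This is robust to the
  # thresholded rim wobbling over foci at off-center planes, yet perinuclear
  # ring fragments (which sit beyond the rim) stay excluded.
  r_eff <- sqrt(max(lengths(record$pix)) / pi)
  for (j in seq_along(record$planes)) {
    z <- record$planes[j]
    pix <- record$pix[[j]]
    myy <- ((pix - 1L) %% ny) + 1L
    mxx <- ((pix - 1L) %/% ny) + 1L
    mcy <- mean(myy); mcx <- mean(mxx)
    y0 <- min(myy); y1 <- max(myy); x0 <- min(mxx); x1 <- max(mxx)
    box <- stack$arc[y0:y1, x0:x1, z]
    dets <- list()
    if (any(box >= opts$focus_threshold)) {
      lab <- EBImage::bwlabel(box >= opts$focus_threshold)
      for (l in seq_len(max(lab))) {
        idx <- which(lab == l)
        area <- length(idx)
        if (area < opts$focus_min_area || area > opts$focus_max_area) next
        ly <- ((idx - 1L) %% nrow(box)) + y0
        lx <- ((idx - 1L) %/% nrow(box)) + x0
        if (sqrt((mean(ly) - mcy)^2 + (mean(lx) - mcx)^2) > 0.85 * r_eff) next
        dets[[length(dets) + 1L]] <- c(cy = mean(ly), cx = mean(lx))
      }
    }
    counts[j] <- length(dets)
    # greedy matching of detections to open tracks from the previous plane
    open <- which(vapply(tracks, function(t) t$last_plane == z - 1L, logical(1)))
    used <- logical(length(open))
    for (dt in dets) {
      best <- 0L; bestd <- Inf
      for (oi in seq_along(open)) {
        if (used[oi]) next
        t <- tracks[[open[oi]]]
        dd <- sqrt((t$cy - dt["cy"])^2 + (t$cx - dt["cx"])^2)
        if (dd < bestd) { bestd <- dd; best <- oi }
      }
      if (best > 0L && bestd <= opts$focus_link_dist) {
        ti <- open[best]
        tracks[[ti]]$last_plane <- z
        tracks[[ti]]$cy <- dt["cy"]; tracks[[ti]]$cx <- dt["cx"]
        tracks[[ti]]$span <- tracks[[ti]]$span + 1L
        used[best] <- TRUE
      } else {
        tracks[[length(tracks) + 1L]] <-
          list(last_plane = z, cy = dt[["cy"]], cx = dt[["cx"]], span = 1L)
      }
    }
  }
  list(counts = counts,
       track_spans = vapply(tracks, function(t) t$span, integer(1)))
}

#' Perinuclear Arc coverage
#'
#' For each plane of the nucleus, measures what fraction of the perimeter
#' is surrounded by Arc signal: the per-plane nucleus mask is dilated by
#' `annulus_width` pixels, the dilation band (annulus) is divided into
#' `n_sectors` angular sectors around the mask centroid, and a sector
#' counts as covered when it contains at least one annulus pixel at or
#' above `ring_threshold`.
#'
#' @param record a cell record from [segment_nuclei()].
#' @param stack the [image_stack()].
#' @param opts a [classify_options()] list.
#' @return Named numeric vector (one entry per nucleus plane) of coverage
#'   fractions in \[0, 1\].
#' @export
cyto_coverage <- function(record, stack, opts = classify_options()) {
  d <- dim(stack$arc); ny <- d[1]; nx <- d[2]
  w <- opts$annulus_width
  brush <- EBImage::makeBrush(2L * w + 1L, shape = "disc")
  cov <- numeric(length(record$planes))
  names(cov) <- record$planes
  for (j in seq_along(record$planes)) {
    z <- record$planes[j]
    pix <- record$pix[[j]]
    yy <- ((pix - 1L) %% ny) + 1L
    xx <- ((pix - 1L) %/% ny) + 1L
    cy <- mean(yy); cx <- mean(xx)
    y0 <- max(1L, min(yy) - w - 1L); y1 <- min(ny, max(yy) + w + 1L)
    x0 <- max(1L, min(xx) - w - 1L); x1 <- min(nx, max(xx) + w + 1L)
    bw <- matrix(FALSE, y1 - y0 + 1L, x1 - x0 + 1L)
    bw[cbind(yy - y0 + 1L, xx - x0 + 1L)] <- TRUE
    ann <- EBImage::dilate(bw, brush) & !bw
    idx <- which(ann)
    if (!length(idx)) { cov[j] <- 0; next }
    ay <- ((idx - 1L) %% nrow(bw)) + y0
    ax <- ((idx - 1L) %/% nrow(bw)) + x0
    arcvals <- stack$arc[, , z][(ax - 1L) * ny + ay]
    hot <- arcvals >= opts$ring_threshold
    if (!any(hot)) { cov[j] <- 0; next }
    sec <- angle_sector(ay[hot] - cy, ax[hot] - cx, opts$n_sectors)
    cov[j] <- length(unique(sec)) / opts$n_sectors
  }
  cov
}

#' Compartmental classification of one neuron
#'
#' Applies the catFISH criteria to a cell's per-plane evidence:
#' \itemize{
#'   \item nuclear: at least 2 transcription-focus tracks each persisting
#'     `min_foci_planes` or more consecutive planes;
#'   \item cytoplasmic: perimeter coverage strictly greater than
#'     `coverage_min` in `min_ring_planes` or more planes (consecutive only
#'     if `ring_consecutive`);
#'   \item double: both criteria; negative: neither.
#' }
#' The decision is a pure function of the stored evidence, so stored
#' records can be re-classified bit-identically.
#'
#' @param evidence a list with `track_spans` (from [detect_foci()]) and
#'   `coverage` (from [cyto_coverage()]).
#' @param opts a [classify_options()] list.
#' @return One of `"negative"`, `"nuclear"`, `"cytoplasmic"`, `"double"`.
#' @export
classify_cell <- function(evidence, opts = classify_options()) {
  nuclear <- sum(evidence$track_spans >= opts$min_foci_planes) >= 2L
  covered <- evidence$coverage > opts$coverage_min
  if (opts$ring_consecutive) {
    planes <- as.integer(names(evidence$coverage))[covered]
    cyt <- longest_run(planes) >= opts$min_ring_planes
  } else {
    cyt <- sum(covered) >= opts$min_ring_planes
  }
  if (nuclear && cyt) "double"
  else if (nuclear) "nuclear"
  else if (cyt) "cytoplasmic"
  else "negative"
}

longest_run <- function(planes) {
  if (!length(planes)) return(0L)
  planes <- sort(planes)
  best <- run <- 1L
  for (i in seq_along(planes)[-1]) {
    run <- if (planes[i] == planes[i - 1] + 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Classify every neuron in a stack
#'
#' End-to-end per-stack pipeline: median-filter [preprocess()], nucleus
#' [segment_nuclei()], neuron/glia discrimination, [optical_dissector()]
#' sampling, per-cell Arc evidence ([detect_foci()], [cyto_coverage()])
#' and [classify_cell()] labels.
#'
#' @param stack an [image_stack()].
#' @param opts a [classify_options()] list.
#' @return A `data.frame` with one row per segmented nucleus: `cell_id`,
#'   centroid `z`, `y`, `x`, `volume`, `is_neuron`, `in_dissector`,
#'   `n_focus_tracks` (tracks meeting the span criterion), `max_track_span`,
#'   `n_covered_planes`, and `label` (`NA` for cells excluded as glial or
#'   by the dissector). The full records (with evidence) are attached as
#'   attribute `"records"`.
#' @examples
#' cfg <- sim_config(n_cells = 8, stack_shape = c(24L, 160L, 160L),
#'                   noise_sd = 0, glia_fraction = 0, seed = 11)
#' cells <- classify_stack(render_stack(simulate_labels(cfg), cfg))
#' table(cells$label, useNA = "ifany")
#' @export
classify_stack <- function(stack, opts = classify_options()) {
  stack <- preprocess(stack, opts$median_radius)
  recs <- segment_nuclei(stack, opts)
  nz <- dim(stack$counterstain)[3]
  w <- dissector_window(nz, opts$dissector_fraction)
  rows <- lapply(recs, function(rec) {
    neuron <- is_neuron(rec, stack, opts)
    inw <- rec$centroid[["z"]] >= w[1] && rec$centroid[["z"]] <= w[2]
    lab <- NA_character_
    nt <- NA_integer_; ms <- NA_integer_; ncov <- NA_integer_
    if (neuron && inw) {
      foci <- detect_foci(rec, stack, opts)
      cov <- cyto_coverage(rec, stack, opts)
      ev <- list(track_spans = foci$track_spans, coverage = cov)
      lab <- classify_cell(ev, opts)
      nt <- sum(foci$track_spans >= opts$min_foci_planes)
      ms <- if (length(foci$track_spans)) max(foci$track_spans) else 0L
      ncov <- sum(cov > opts$coverage_min)
      rec$evidence <- ev
    }
    rec$is_neuron <- neuron; rec$in_dissector <- inw; rec$label <- lab
    list(rec = rec,
         row = data.frame(
           cell_id = rec$cell_id,
           z = rec$centroid[["z"]], y = rec$centroid[["y"]],
           x = rec$centroid[["x"]], volume = rec$volume,
           is_neuron = neuron, in_dissector = inw,
           n_focus_tracks = nt, max_track_span = ms,
           n_covered_planes = ncov,
           label = lab, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), volume = integer(0),
                      is_neuron = logical(0), in_dissector = logical(0),
                      n_focus_tracks = integer(0), max_track_span = integer(0),
                      n_covered_planes = integer(0), label = character(0))
  attr(out, "records") <- lapply(rows, `[[`, "rec")
  out
}

#' Tally classified cells
#'
#' Pools labeled cells into per-group classification counts
#' (`neg + nuc + cyt + dob = total` exactly). Cells with an `NA` label
#' (glia, out-of-dissector) are ignored; an explicitly unlabeled record
#' among included cells is an integrity error.
#'
#' @param cells a `data.frame` with a `label` column (from
#'   [classify_stack()], possibly row-bound across stacks), or a character
#'   vector of labels.
#' @param ... metadata passed to [cell_counts()] (`animal_id`, `region`,
#'   `condition`, `pretreatment`).
#' @return A one-row [cell_counts()] data frame.
#' @export
tally_cells <- function(cells, ...) {
  labels <- if (is.data.frame(cells)) cells$label else cells
  labels <- labels[!is.na(labels)]
  bad <- setdiff(unique(labels), c("negative", "nuclear", "cytoplasmic", "double"))
  if (length(bad))
    stop("unlabeled or unknown cell label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cell_counts(neg = sum(labels == "negative"),
              nuc = sum(labels == "nuclear"),
              cyt = sum(labels == "cytoplasmic"),
              dob = sum(labels == "double"), ...)
}
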