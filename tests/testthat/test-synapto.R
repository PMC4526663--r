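test_that("threshold calibration lands between modes, is deterministic, rejects flat channels", {
  set.seed(51)
  bimodal <- function(lo, hi) {
    v <- c(rnorm(6000, lo, 0.015), rnorm(2000, hi, 0.015))
    matrix(pmin(pmax(v, 0), 1), 80, 100)
  }
  img <- list(map2 = bimodal(20 / 255, 200 / 255),
              syn = bimodal(0.1, 0.8))
  ts1 <- calibrate_thresholds(img)
  expect_gt(ts1$map2_threshold, 20 / 255)
  expect_lt(ts1$map2_threshold, 200 / 255)
  expect_gt(ts1$syn_threshold, 0.1)
  expect_lt(ts1$syn_threshold, 0.8)
  # independent oracle: exhaustive scan of between-class variance. The
  # maximizer is a plateau between well-separated modes, so the check is
  # that the chosen threshold attains the maximal between-class variance,
  # not that it equals one particular plateau point.
  bcv <- function(v, t) {
    w1 <- mean(v < t)
    if (w1 == 0 || w1 == 1) return(0)
    w1 * (1 - w1) * (mean(v[v >= t]) - mean(v[v < t]))^2
  }
  v <- as.vector(img$map2)
  best <- max(vapply(seq(0.01, 0.99, by = 1 / 256),
                     function(t) bcv(v, t), numeric(1)))
  expect_gte(bcv(v, ts1$map2_threshold), 0.999 * best)
  ts2 <- calibrate_thresholds(img)
  expect_identical(ts1$map2_threshold, ts2$map2_threshold)
  flat <- list(map2 = matrix(0.5, 40, 40), syn = matrix(0.2, 40, 40))
  expect_error(calibrate_thresholds(flat), "constant")
})

test_that("map2 ROI dilates to the first radius reaching the enlarged area target", {
  img <- list(map2 = matrix(0, 160, 160))
  img$map2[31:130, 31:130] <- 0.6  # 10000 px square
  poly <- cbind(x = c(10, 155, 155, 10), y = c(10, 10, 155, 155))
  thr <- structure(list(map2_threshold = 0.3, syn_threshold = 0.3,
                        calibration_image_id = NA), class = "threshold_set")
  mask <- map2_roi(img, poly, thr, enlargement = 0.10)
  expect_gte(sum(mask), 11000)
  expect_equal(attr(mask, "base_area"), 10000)
  expect_gte(attr(mask, "dilation_radius"), 1)
  # one radius less must be below target (first crossing)
  r <- attr(mask, "dilation_radius")
  if (r > 1) {
    smaller <- EBImage::dilate(img$map2 >= 0.3,
                               EBImage::makeBrush(2 * (r - 1) + 1, "disc"))
    expect_lt(sum(smaller), 11000)
  }
  # zero enlargement returns the thresholded region unchanged
  mask0 <- map2_roi(img, poly, thr, enlargement = 0)
  expect_equal(sum(mask0), 10000)
  expect_equal(attr(mask0, "dilation_radius"), 0)
  # polygon outside the tissue: warning and NULL
  far <- cbind(x = c(1, 8, 8, 1), y = c(1, 1, 8, 8))
  expect_warning(out <- map2_roi(img, far, thr), "no Map2 signal")
  expect_null(out)
})

test_that("area fraction is the percentage of supra-threshold synaptophysin in the ROI", {
  img <- list(map2 = matrix(0.6, 100, 100), syn = matrix(0, 100, 100))
  mask <- matrix(TRUE, 100, 100)
  thr <- structure(list(map2_threshold = 0.3, syn_threshold = 0.4,
                        calibration_image_id = NA), class = "threshold_set")
  img$syn[1:25, ] <- 0.8  # 2500 of 10000 pixels
  m <- measure_area_fraction(img, mask, thr)
  expect_equal(m$fraction, 25)
  expect_equal(m$syn_area, 2500)
  img$syn[] <- 0
  expect_equal(measure_area_fraction(img, mask, thr)$fraction, 0)
  expect_error(measure_area_fraction(img, matrix(FALSE, 100, 100), thr),
               "empty ROI")
  # monotonicity: adding supra-threshold pixels never decreases the fraction
  f_prev <- 0
  for (k in seq(10, 90, by = 20)) {
    img$syn[1:k, 1:50] <- 0.9
    f <- measure_area_fraction(img, mask, thr)$fraction
    expect_gte(f, f_prev)
    f_prev <- f
  }
})

test_that("synthetic mosaics are recovered within 0.5 percentage points", {
  rois <- default_roi_spec()
  fr <- setNames(seq(5, 70, length.out = length(rois)), names(rois))
  mz <- render_mosaic(rois, fr, seed = 53)
  out <- measure_mosaic(mz, mz$rois)
  expect_equal(nrow(out), 14)
  got <- out$fraction[match(mz$truth$roi_name, out$roi_name)]
  expect_true(all(abs(got - mz$truth$true_fraction) <= 0.5))
  # edge fractions
  mz2 <- render_mosaic(rois[1:3], c(SOd = 0, SOm = 100, SOp = 50), seed = 54)
  out2 <- measure_mosaic(mz2, mz2$rois)
  expect_equal(out2$fraction[out2$roi_name == "SOd"], 0)
  expect_gt(out2$fraction[out2$roi_name == "SOm"], 99.5)
  expect_error(render_mosaic(rois[1], c(SOd = 120), seed = 1), "\\[0, 100\\]")
})

test_that("fractions are invariant under uniform rescaling with recalibration", {
  rois <- default_roi_spec()[1:4]
  fr <- setNames(c(15, 30, 45, 60), names(rois))
  mz <- render_mosaic(rois, fr, seed = 55)
  base <- measure_mosaic(mz, mz$rois)
  scaled <- mz
  scaled$map2 <- mz$map2 * 0.5
  scaled$syn <- mz$syn * 0.5
  resc <- measure_mosaic(scaled, mz$rois)  # thresholds recalibrated on input
  expect_equal(resc$fraction, base$fraction, tolerance = 0.02)
})

test_that("ROI polygons round-trip through the 0-based JSON format", {
  rois <- default_roi_spec()[c(1, 7, 14)]
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_identical(names(back), names(rois))
  for (nm in names(rois))
    expect_equal(unname(back[[nm]]), unname(rois[[nm]]))
  raw <- jsonlite::read_json(path)
  expect_equal(raw[[1]]$polygon[[1]][[1]], unname(rois[[1]][1, 1]) - 1)
})

test_that("map2 area homogeneity check is calibrated and degenerate-safe", {
  set.seed(56)
  # null: all groups share one distribution; p should not be extreme too often
  ps <- replicate(200, {
    df <- data.frame(roi_name = "SOd",
                     pretreatment = rep(c("IC", "SC", "WM"), each = 5),
                     map2_roi_area = rnorm(15, 10000, 400))
    map2_area_check(df)$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.11)
  # a strongly shifted group is detected
  df <- data.frame(roi_name = "SOd",
                   pretreatment = rep(c("IC", "SC", "WM"), each = 5),
                   map2_roi_area = c(rnorm(5, 10000, 100),
                                     rnorm(5, 10000, 100),
                                     rnorm(5, 10500, 100)))
  expect_lt(map2_area_check(df)$p, 0.05)
  # identical areas: degenerate flag, F = 0
  dfi <- data.frame(roi_name = "SOd",
                    pretreatment = rep(c("IC", "SC"), each = 3),
                    map2_roi_area = rep(10000, 6))
  chk <- map2_area_check(dfi)
  expect_true(chk$degenerate)
  expect_equal(chk$f, 0)
  # fewer than two groups: skipped with a message
  expect_message(
    out <- map2_area_check(data.frame(roi_name = "SOd", pretreatment = "IC",
                                      map2_roi_area = c(1, 2))),
    "skipped")
  expect_null(out)
})
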