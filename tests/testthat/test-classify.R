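test_that("median preprocessing: radius 0 is identity, constants unchanged, impulses removed", {
  cfg <- small_config(n_cells = 3, seed = 31)
  st <- render_stack(simulate_labels(cfg), cfg)
  expect_identical(preprocess(st, 0), st)

  flat <- image_stack(array(0.4, c(20, 20, 4)), array(0.1, c(20, 20, 4)))
  out <- preprocess(flat, 1)
  expect_equal(max(abs(out$counterstain - 0.4)), 0, tolerance = 1 / 65535)
  expect_equal(max(abs(out$arc - 0.1)), 0, tolerance = 1 / 65535)

  imp <- array(0.2, c(21, 21, 3))
  imp[11, 11, 2] <- 1  # single-pixel impulse; 3x3 median of 8x0.2 + 1x1 = 0.2
  st2 <- image_stack(imp, array(0, c(21, 21, 3)))
  out2 <- preprocess(st2, 1)
  expect_equal(out2$counterstain[11, 11, 2], 0.2, tolerance = 1 / 65535)
})

test_that("segmentation recovers rendered nuclei with accurate centroids", {
  cfg <- sim_config(n_cells = 20, stack_shape = c(30L, 220L, 220L),
                    noise_sd = 0, seed = 32)
  tr <- simulate_labels(cfg)
  st <- render_stack(tr, cfg)
  recs <- segment_nuclei(preprocess(st, 1))
  truth <- attr(st, "truth")
  expect_length(recs, 20)
  for (rec in recs) {
    d <- sqrt((truth$y - rec$centroid[["y"]])^2 +
              (truth$x - rec$centroid[["x"]])^2)
    expect_lt(min(d), 1.5)
  }
  # blank stack yields no records, not an error
  blank <- image_stack(array(0, c(10, 40, 40)), array(0, c(10, 40, 40)))
  expect_length(segment_nuclei(blank), 0)
})

test_that("touching nuclei with distinct peaks are split into two records", {
  # two discs overlapping by ~1 px in every plane, mild intensity texture
  a <- array(0, c(48, 64, 9))
  for (z in 1:9) {
    pl <- matrix(0, 48, 64)
    pl <- catfishr:::paint_disc(pl, 24, 22, 8, 0.4)
    pl <- catfishr:::paint_disc(pl, 24, 38, 8, 0.4)
    a[, , z] <- pl
  }
  st <- image_stack(a, array(0, dim(a)))
  recs <- segment_nuclei(st, classify_options(nuc_threshold = 0.2,
                                              split_area = 220L))
  expect_length(recs, 2)
  xs <- sort(vapply(recs, function(r) r$centroid[["x"]], numeric(1)))
  expect_equal(xs, c(22, 38), tolerance = 0.1)
})

test_that("neuron/glia discrimination follows texture and brightness", {
  cfg <- small_config(n_cells = 10, glia_fraction = 0.5, seed = 33)
  st <- preprocess(render_stack(simulate_labels(cfg), cfg), 1)
  recs <- segment_nuclei(st)
  truth <- attr(attr(st, "truth"), "class")  # not attached post-preprocess
  truth <- NULL
  tr <- place_cells(simulate_labels(cfg), cfg)
  for (rec in recs) {
    j <- which.min((tr$y - rec$centroid[["y"]])^2 +
                   (tr$x - rec$centroid[["x"]])^2)
    expect_identical(is_neuron(rec, st), tr$is_neuron[j],
                     label = sprintf("cell %d", j))
  }
  # degenerate one-voxel mask counts as glial, with a warning
  tiny <- list(cell_id = 1L, planes = 1L, pix = list(5L),
               centroid = c(z = 1, y = 5, x = 1), volume = 1L)
  expect_warning(flag <- is_neuron(tiny, st), "degenerate")
  expect_false(flag)
})

test_that("optical dissector keeps the closed central window, inclusive bounds", {
  # 40 planes at 30%: 0-based window 14..26, i.e. 1-based 15..27
  w <- dissector_window(40, 0.30)
  expect_equal(unname(w), c(15, 27))
  mkrec <- function(z) list(centroid = c(z = z, y = 1, x = 1))
  recs <- lapply(c(6, 15, 20, 27, 27.5), mkrec)
  kept <- optical_dissector(recs, 40, 0.30)
  expect_equal(vapply(kept, function(r) r$centroid[["z"]], numeric(1)),
               c(15, 20, 27))
  # fraction 1 keeps everything
  expect_length(optical_dissector(recs, 40, 1), 5)
  # kept count is non-decreasing in the fraction
  zs <- seq(1, 40, by = 0.5)
  recs2 <- lapply(zs, mkrec)
  kept_n <- vapply(seq(0.05, 1, by = 0.05), function(f)
    length(optical_dissector(recs2, 40, f)), integer(1))
  expect_true(all(diff(kept_n) >= 0))
})

test_that("focus tracks span the rendered number of planes", {
  base <- small_config(n_cells = 1, glia_fraction = 0, seed = 34)
  for (fp in c(2L, 3L, 5L)) {
    cfg <- small_config(n_cells = 1, glia_fraction = 0, foci_planes = fp,
                        seed = 34)
    tr <- simulate_labels(cfg)
    tr$e1 <- FALSE; tr$e2 <- TRUE
    st <- preprocess(render_stack(tr, cfg), 1)
    recs <- segment_nuclei(st)
    fo <- detect_foci(recs[[1]], st)
    expect_length(fo$track_spans, 2)
    expect_equal(unname(fo$track_spans), c(fp, fp))
  }
  # no Arc signal: all zero counts, no tracks
  cfg0 <- small_config(n_cells = 1, glia_fraction = 0, seed = 34)
  tr0 <- simulate_labels(cfg0); tr0$e1 <- FALSE; tr0$e2 <- FALSE
  st0 <- preprocess(render_stack(tr0, cfg0), 1)
  recs0 <- segment_nuclei(st0)
  fo0 <- detect_foci(recs0[[1]], st0)
  expect_true(all(fo0$counts == 0))
  expect_length(fo0$track_spans, 0)
})

test_that("perimeter coverage tracks the rendered ring fraction", {
  cfg <- small_config(n_cells = 1, glia_fraction = 0, ring_coverage = 0.7,
                      seed = 35)
  tr <- simulate_labels(cfg)
  tr$e1 <- TRUE; tr$e2 <- FALSE
  st <- preprocess(render_stack(tr, cfg), 1)
  recs <- segment_nuclei(st)
  cov <- cyto_coverage(recs[[1]], st)
  on_ring <- cov > 0
  expect_equal(sum(on_ring), cfg$ring_planes)
  # within one 10-degree sector of the rendered coverage on every plane
  expect_lte(max(abs(cov[on_ring] - round(0.7 * 36) / 36)), 1 / 36 + 1e-9)
  # full ring reaches coverage 1, no signal gives 0 everywhere
  cfg1 <- small_config(n_cells = 1, glia_fraction = 0, ring_coverage = 1,
                       seed = 35)
  tr1 <- simulate_labels(cfg1); tr1$e1 <- TRUE; tr1$e2 <- FALSE
  st1 <- preprocess(render_stack(tr1, cfg1), 1)
  cov1 <- cyto_coverage(segment_nuclei(st1)[[1]], st1)
  expect_equal(max(cov1), 1)
  tr0 <- simulate_labels(cfg1); tr0$e1 <- FALSE; tr0$e2 <- FALSE
  st0 <- preprocess(render_stack(tr0, cfg1), 1)
  expect_true(all(cyto_coverage(segment_nuclei(st0)[[1]], st0) == 0))
})

test_that("classification criteria apply strict thresholds to stored evidence", {
  ev <- function(spans, cov) list(track_spans = as.integer(spans),
                                  coverage = setNames(cov, seq_along(cov)))
  # nuclear: 2 tracks of span >= 3
  expect_equal(classify_cell(ev(c(3, 3), numeric(0))), "nuclear")
  expect_equal(classify_cell(ev(c(3, 2), numeric(0))), "negative")
  expect_equal(classify_cell(ev(c(2, 2), numeric(0))), "negative")
  # cytoplasmic: coverage > 0.60 in >= 4 planes; 0.60 exactly does not count
  expect_equal(classify_cell(ev(integer(0), rep(0.65, 4))), "cytoplasmic")
  expect_equal(classify_cell(ev(integer(0), rep(0.60, 5))), "negative")
  expect_equal(classify_cell(ev(integer(0), rep(0.61, 3))), "negative")
  # double requires both full criteria
  expect_equal(classify_cell(ev(c(4, 3), rep(0.7, 5))), "double")
  # non-consecutive coverage planes count by default, not when restricted
  cov5 <- setNames(c(0.7, 0, 0.7, 0.7, 0, 0.7), c(1, 2, 3, 4, 5, 6))
  e <- list(track_spans = integer(0), coverage = cov5)
  expect_equal(classify_cell(e), "cytoplasmic")
  expect_equal(classify_cell(e, classify_options(ring_consecutive = TRUE)),
               "negative")
  # re-classification of stored evidence is bit-stable
  expect_identical(classify_cell(ev(c(3, 3), rep(0.7, 4))),
                   classify_cell(ev(c(3, 3), rep(0.7, 4))))
})

test_that("tallies partition included cells and add across stacks", {
  labs <- c(rep("negative", 4), rep("nuclear", 3), rep("cytoplasmic", 2),
            "double")
  cc <- tally_cells(labs)
  expect_equal(c(cc$neg, cc$nuc, cc$cyt, cc$dob), c(4, 3, 2, 1))
  expect_equal(cc$total, 10)
  expect_equal(tally_cells(character(0))$total, 0)
  # additivity over two stacks of one animal
  l1 <- c("negative", "double"); l2 <- c("nuclear", "negative", "cytoplasmic")
  both <- tally_cells(c(l1, l2))
  expect_equal(as.data.frame(both)[, c("neg", "nuc", "cyt", "dob")],
               as.data.frame(tally_cells(l1))[, c("neg", "nuc", "cyt", "dob")] +
               as.data.frame(tally_cells(l2))[, c("neg", "nuc", "cyt", "dob")])
  expect_error(tally_cells(c("negative", "weird")), "unlabeled|unknown")
})

test_that("end-to-end labels match generator truth on a noiseless stack", {
  cfg <- sim_config(n_cells = 25, stack_shape = c(36L, 220L, 220L),
                    noise_sd = 0, glia_fraction = 0.2, seed = 36)
  res <- classify_vs_truth(cfg)
  expect_gt(nrow(res), 0)
  expect_equal(res$got, res$expected)
})
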