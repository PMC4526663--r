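# Shared fixtures: small rendered stacks and matching utilities.

# A compact stack config that still exercises every rendering feature.
small_config <- function(n_cells = 10, noise_sd = 0, seed = 1, ...) {
  sim_config(n_cells = n_cells, stack_shape = c(24L, 160L, 160L),
             noise_sd = noise_sd, seed = seed, ...)
}

# Match classified cells to ground-truth cells by in-plane centroid
# proximity; returns the truth row index per classified row (NA if no
# truth cell within max_dist).
match_truth <- function(cells, truth, max_dist = 5) {
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (truth$y - cells$y[i])^2 + (truth$x - cells$x[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist) j else NA_integer_
  }, integer(1))
}

# Per-class F1 of predicted vs expected labels.
class_f1 <- function(expected, got,
                     classes = c("negative", "nuclear", "cytoplasmic", "double")) {
  vapply(classes, function(k) {
    tp <- sum(got == k & expected == k)
    fp <- sum(got == k & expected != k)
    fn <- sum(got != k & expected == k)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

# Independent oracle for the finite-sample expectation of the plug-in
# SiSc at cell count n: multinomial draws over the four staining classes,
# bypassing the package's generator entirely. The population score equals
# kappa exactly; the plug-in estimator carries an O(1/n) ratio bias that
# this oracle quantifies.
sisc_mc_expectation <- function(kappa, n, p1 = 0.3, p2 = 0.3, reps = 2e5) {
  p11 <- p1 * p2 + kappa * (min(p1, p2) - p1 * p2)
  cnt <- stats::rmultinom(reps, n,
                          c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11))
  dob <- cnt[1, ] / n; e1 <- (cnt[1, ] + cnt[2, ]) / n
  e2 <- (cnt[1, ] + cnt[3, ]) / n
  sisc <- (dob - e1 * e2) / (pmin(e1, e2) - e1 * e2)
  ok <- is.finite(sisc)
  c(mean = mean(sisc[ok]), se = stats::sd(sisc[ok]) / sqrt(sum(ok)))
}

# Render one stack and return the classification joined with expected
# labels (included, matched cells only).
classify_vs_truth <- function(cfg, opts = classify_options()) {
  st <- render_stack(simulate_labels(cfg), cfg)
  cl <- classify_stack(st, opts)
  truth <- attr(st, "truth")
  m <- match_truth(cl, truth)
  keep <- !is.na(cl$label) & !is.na(m)
  data.frame(got = cl$label[keep],
             expected = expected_labels(truth, cfg)[m[keep]],
             truth_row = m[keep])
}
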