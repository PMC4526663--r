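test_that("one-way ANOVA matches the hand decomposition and handles edge designs", {
  # hand oracle on toy data {3,5,4}, {8,9,10}, {1,2,3}
  v <- c(3, 5, 4, 8, 9, 10, 1, 2, 3)
  g <- rep(c("a", "b", "c"), each = 3)
  gm <- mean(v)
  ssb <- 3 * sum((tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - ave(v, g))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- one_way_anova(data.frame(v = v, g = g), "v", "g")
  expect_equal(res$statistic, f_hand, tolerance = 1e-9)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, stats::pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical groups: F = 0, p = 1
  df0 <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  r0 <- one_way_anova(df0, "v", "g")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # clean separation
  dfs <- data.frame(v = c(0, 0, 0, 10, 10, 10) + rnorm(6, 0, 1e-4),
                    g = rep(c("a", "b"), each = 3))
  expect_lt(one_way_anova(dfs, "v", "g")$p, 1e-6)
  # underfilled level errors with its name
  expect_error(one_way_anova(data.frame(v = c(1, 2, 3), g = c("a", "a", "b")),
                             "v", "g"), "b")
})

test_that("post hoc tables obey Bonferroni dominance and LSD uses pooled error", {
  set.seed(61)
  df <- data.frame(v = c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3)),
                   g = rep(c("a", "b", "c"), each = 5))
  lsd <- one_way_anova(df, "v", "g", posthoc = "fisher_lsd")
  bon <- one_way_anova(df, "v", "g", posthoc = "bonferroni")
  expect_equal(nrow(lsd$posthoc), 3)
  expect_true(all(bon$posthoc$p_adj >= lsd$posthoc$p_adj - 1e-12))
  expect_true(all(bon$posthoc$p_adj <= 1))
  expect_equal(bon$posthoc$p_adj,
               pmin(1, lsd$posthoc$p_adj * 3), tolerance = 1e-9)
})

test_that("two-way ANOVA separates main effects from a pure crossover interaction", {
  # crossover: cell means +1, -1 / -1, +1; zero marginal means
  df <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:4)
  mu <- ifelse(df$a == "a1", 1, -1) * ifelse(df$b == "b1", 1, -1)
  set.seed(62)
  df$v <- mu + rnorm(nrow(df), 0, 0.1)
  res <- two_way_anova(df, "v", "a", "b")
  expect_lt(res$factor_a$statistic, 5)
  expect_lt(res$factor_b$statistic, 5)
  expect_gt(res$interaction$statistic, 100)
  # all-equal values: every F is 0
  dfe <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:3)
  dfe$v <- 5
  rese <- two_way_anova(dfe, "v", "a", "b")
  fs <- c(rese$factor_a$statistic, rese$factor_b$statistic,
          rese$interaction$statistic)
  expect_true(all(fs == 0))
  expect_true(rese$degenerate)
  # empty cell rejected
  bad <- df[!(df$a == "a2" & df$b == "b2"), ]
  expect_error(two_way_anova(bad, "v", "a", "b"), "empty")
})

test_that("two-way reduces to one-way when the second factor is constant in effect", {
  # factor b has no effect; the F for a should match the one-way F computed
  # within the same residual structure on a balanced design
  set.seed(63)
  df <- expand.grid(a = c("a1", "a2", "a3"), b = c("b1", "b2"), rep = 1:4)
  df$v <- ifelse(df$a == "a1", 0, ifelse(df$a == "a2", 1, 2)) +
    rnorm(nrow(df), 0, 0.5)
  r2 <- two_way_anova(df, "v", "a", "b")
  r1 <- one_way_anova(df, "v", "a")
  # same numerator mean squares; F values agree within the residual reshuffle
  expect_equal(r2$factor_a$df[1], r1$df[1])
  expect_equal(r2$factor_a$statistic, r1$statistic, tolerance = 0.25)
})

test_that("pearson correlation handles exact, noisy and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_cor(x, -x)$statistic, -1)
  r <- pearson_cor(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(r$statistic, stats::cor(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)),
               tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "at least 3")
})

test_that("paired t matches the hand formula and rejects zero-variance differences", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9)
  y <- c(4.9, 4.5, 5.2, 5.6, 5.1)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  res <- paired_t(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-9)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  # |t| grows as the jitter shrinks around a constant difference
  set.seed(64)
  t_big <- abs(paired_t(c(1, 1, 1, 1) + rnorm(4, 0, 1e-6),
                        c(0, 0, 0, 0))$statistic)
  t_small <- abs(paired_t(c(1, 1, 1, 1) + rnorm(4, 0, 1e-1),
                          c(0, 0, 0, 0))$statistic)
  expect_gt(t_big, t_small)
})

test_that("all four tests hold their type-I error near the nominal level", {
  set.seed(65)
  n_rep <- 400
  rej <- c(one_way = 0, two_way = 0, pearson = 0, paired = 0)
  for (i in seq_len(n_rep)) {
    v <- rnorm(15)
    g <- rep(c("a", "b", "c"), each = 5)
    if (one_way_anova(data.frame(v = v, g = g), "v", "g")$p < 0.05)
      rej["one_way"] <- rej["one_way"] + 1
    d2 <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:3)
    d2$v <- rnorm(nrow(d2))
    if (two_way_anova(d2, "v", "a", "b")$interaction$p < 0.05)
      rej["two_way"] <- rej["two_way"] + 1
    if (pearson_cor(rnorm(12), rnorm(12))$p < 0.05)
      rej["pearson"] <- rej["pearson"] + 1
    if (paired_t(rnorm(8), rnorm(8))$p < 0.05)
      rej["paired"] <- rej["paired"] + 1
  }
  rates <- rej / n_rep
  # 3 s.e. band around 0.05 at 400 replicates is about +/- 0.033
  expect_true(all(rates > 0.017), label = paste(rates, collapse = " "))
  expect_true(all(rates < 0.083), label = paste(rates, collapse = " "))
})
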