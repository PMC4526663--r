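#' One-way ANOVA with optional post hoc comparisons
#'
#' Classical between/within variance decomposition of `value` across the
#' levels of `factor`, with F on (k - 1, N - k) degrees of freedom.
#' Post hoc pairwise comparisons use the pooled within-group error:
#' Fisher's LSD (unadjusted pairwise t with pooled SD) or
#' Bonferroni-adjusted pairwise t (`p_adj = min(1, m * p_raw)`).
#'
#' @param table a long-format `data.frame`.
#' @param value,factor column names of the response and the grouping
#'   factor.
#' @param posthoc `"none"`, `"fisher_lsd"`, or `"bonferroni"`.
#' @return A list of class `cat_test`: `method`, `statistic` (F), `df`
#'   (numerator, denominator), `p`, and (when requested) `posthoc`, a
#'   data frame of pairwise comparisons with adjusted p-values.
#' @examples
#' df <- data.frame(v = c(3, 5, 4, 8, 9, 10, 1, 2, 3),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' one_way_anova(df, "v", "g", posthoc = "bonferroni")
#' @export
one_way_anova <- function(table, value, factor,
                          posthoc = c("none", "fisher_lsd", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  v <- table[[value]]
  g <- base::factor(table[[factor]])
  stopifnot(all(is.finite(v)))
  if (nlevels(g) < 2)
    stop("one-way ANOVA needs at least 2 factor levels", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("level(s) with fewer than 2 units: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1]]
  res <- list(method = "one-way ANOVA",
              statistic = tab[["F value"]][1],
              df = c(tab[["Df"]][1], tab[["Df"]][2]),
              p = tab[["Pr(>F)"]][1])
  if (posthoc != "none") {
    adj <- if (posthoc == "bonferroni") "bonferroni" else "none"
    pw <- stats::pairwise.t.test(v, g, p.adjust.method = adj, pool.sd = TRUE)
    m <- pw$p.value
    comp <- data.frame(
      comparison = paste(rep(rownames(m), ncol(m)),
                         rep(colnames(m), each = nrow(m)), sep = " vs "),
      p_adj = as.vector(m))
    comp <- comp[!is.na(comp$p_adj), , drop = FALSE]
    rownames(comp) <- NULL
    res$posthoc <- comp
    res$posthoc_method <- posthoc
  }
  class(res) <- "cat_test"
  res
}

#' Two-way ANOVA (balanced crossed design)
#'
#' Main effects and interaction of two crossed factors by the standard
#' decomposition. Designs with empty cells are rejected.
#'
#' @param table a long-format `data.frame`.
#' @param value,factor_a,factor_b column names.
#' @return A list of class `cat_test2`: one `(statistic, df, p)` triple per
#'   term (`factor_a`, `factor_b`, `interaction`).
#' @export
two_way_anova <- function(table, value, factor_a, factor_b) {
  v <- table[[value]]
  a <- base::factor(table[[factor_a]])
  b <- base::factor(table[[factor_b]])
  stopifnot(all(is.finite(v)))
  cells <- table(a, b)
  if (any(cells == 0))
    stop("empty design cell(s): two-way ANOVA requires a complete crossed design",
         call. = FALSE)
  if (any(cells < 2) && all(cells == 1))
    stop("one observation per cell: the interaction is not estimable",
         call. = FALSE)
  if (stats::var(v) == 0) {
    # all observations identical: every sum of squares is exactly zero and
    # aov would return machine-noise F ratios; report F = 0 explicitly
    dfr <- length(v) - nlevels(a) * nlevels(b)
    zero <- function(d1, name) list(statistic = 0, df = c(d1, dfr), p = 1,
                                    term = name)
    res <- list(method = "two-way ANOVA", degenerate = TRUE,
                factor_a = zero(nlevels(a) - 1L, factor_a),
                factor_b = zero(nlevels(b) - 1L, factor_b),
                interaction = zero((nlevels(a) - 1L) * (nlevels(b) - 1L),
                                   paste0(factor_a, ":", factor_b)))
    class(res) <- "cat_test2"
    return(res)
  }
  fit <- stats::aov(v ~ a * b)
  tab <- summary(fit)[[1]]
  dfr <- tab[["Df"]][4]
  term <- function(i, name) list(statistic = tab[["F value"]][i],
                                 df = c(tab[["Df"]][i], dfr),
                                 p = tab[["Pr(>F)"]][i], term = name)
  res <- list(method = "two-way ANOVA",
              factor_a = term(1, factor_a),
              factor_b = term(2, factor_b),
              interaction = term(3, paste0(factor_a, ":", factor_b)))
  class(res) <- "cat_test2"
  res
}

#' Pearson correlation
#'
#' Sample correlation with the two-sided t-based p-value on n - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return A list of class `cat_test`: `statistic` (r), `df`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("Pearson correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- list(method = "Pearson correlation",
              statistic = unname(ct$estimate),
              df = unname(ct$parameter), p = ct$p.value, n = length(x))
  class(res) <- "cat_test"
  res
}

#' Paired t-test
#'
#' Classical paired t on the within-unit differences (e.g. CA1 vs CA3
#' activation rates of the same animals).
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return A list of class `cat_test`: `statistic` (t), `df`, `p`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: the paired t statistic is undefined",
         call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  res <- list(method = "paired t-test",
              statistic = unname(tt$statistic),
              df = unname(tt$parameter), p = tt$p.value, n = length(x))
  class(res) <- "cat_test"
  res
}

#' @export
print.cat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(x$df, collapse = ", "), x$p))
  if (!is.null(x$posthoc)) {
    cat(sprintf("post hoc (%s):\n", x$posthoc_method))
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.cat_test2 <- function(x, ...) {
  cat(x$method, "\n")
  for (t in x[c("factor_a", "factor_b", "interaction")])
    cat(sprintf("  %s: F(%d, %d) = %.4g, p = %.4g\n",
                t$term, t$df[1], t$df[2], t$statistic, t$p))
  invisible(x)
}
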