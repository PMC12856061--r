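# Small-sample statistical battery ---------------------------------------
#
# Thin, validated wrappers around the classical tests, all returning a
# uniform `test_result`, plus a hand-rolled Dunn post hoc (no base
# implementation exists).  Degenerate inputs (zero variance, all ties)
# are mapped to the documented conventions instead of raw errors.

test_result <- function(statistic, df, p, method, adjusted = FALSE,
                        extra = NULL) {
  structure(c(list(statistic = statistic, df = df, p = p, method = method,
                   adjusted = adjusted), extra), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dftxt <- if (is.null(x$df) || all(is.na(x$df))) ""
           else sprintf(", df = %s", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("<test_result: %s; statistic = %s%s, p = %s%s>\n", x$method,
              signif(x$statistic, 4), dftxt, format.pval(x$p, digits = 4),
              if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, `3 <= n <= 5000`; constant samples are
#'   degenerate and flagged (`p = NA`) rather than erroring.
#' @return A `test_result` with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("Shapiro-Wilk requires n >= 3")
  if (diff(range(x)) == 0)
    return(test_result(NA_real_, NA_real_, NA_real_,
                       "Shapiro-Wilk (degenerate: constant sample)"))
  sw <- stats::shapiro.test(x)
  test_result(unname(sw$statistic), length(x), sw$p.value, "Shapiro-Wilk")
}

split_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  split(values[keep], factor(groups[keep]))
}

#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance, `F = MSB/MSW` on
#' `(k - 1, N - k)` degrees of freedom.  Missing values are dropped
#' (unbalanced groups allowed).  Zero within-group variance with equal
#' group means yields `F = 0, p = 1`; zero within-group variance with
#' unequal means yields `F = Inf, p = 0`.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels, same length.
#' @return A `test_result` with the F statistic.
#' @export
one_way_anova <- function(values, groups) {
  gs <- split_groups(values, groups)
  if (length(gs) < 2L) stop("ANOVA needs >= 2 groups")
  N <- sum(lengths(gs)); k <- length(gs)
  if (N - k < 1L) stop("no within-group degrees of freedom")
  df1 <- k - 1; df2 <- N - k
  ssw <- sum(vapply(gs, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0) {   # degenerate: aov would return NaN
    gm <- mean(unlist(gs))
    ssb <- sum(vapply(gs, function(g) length(g) * (mean(g) - gm)^2, 0))
    if (ssb == 0) return(test_result(0, c(df1, df2), 1, "one-way ANOVA"))
    return(test_result(Inf, c(df1, df2), 0, "one-way ANOVA"))
  }
  d <- data.frame(value = unlist(gs),
                  group = factor(rep(names(gs), lengths(gs))))
  tab <- summary(stats::aov(value ~ group, data = d))[[1]]
  test_result(tab[["F value"]][1], c(df1, df2), tab[["Pr(>F)"]][1],
              "one-way ANOVA")
}

#' Tukey HSD post hoc comparisons
#'
#' Family-wise pairwise comparisons from the studentized range
#' distribution, via [stats::TukeyHSD()] on the one-way fit.
#'
#' @inheritParams one_way_anova
#' @param conf.level Confidence level of the intervals.
#' @return Data frame with one row per pair: `pair, diff, lwr, upr, p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf.level = 0.95) {
  keep <- !is.na(values) & !is.na(groups)
  d <- data.frame(value = values[keep], group = factor(groups[keep]))
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  # zero-variance ties: equal groups compare with p = 1
  out$p_adj[is.nan(out$p_adj) & abs(out$diff) < .Machine$double.eps^0.5] <- 1
  out
}

#' Pooled-variance two-sample t test
#'
#' Unpaired Student's t test with pooled variance, two-sided.  Identical
#' constant samples yield `t = 0, p = 1`.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @return A `test_result`.
#' @export
pooled_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    return(test_result(0, length(a) + length(b) - 2, 1,
                       "pooled t test (degenerate: constant equal samples)"))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "pooled t test")
}

#' Bonferroni adjustment of a test result
#'
#' Multiplies the p value by the number of comparisons in the family,
#' capped at 1, and marks the result as adjusted.
#'
#' @param result A `test_result`.
#' @param k Number of comparisons in the family.
#' @return The adjusted `test_result`.
#' @export
bonferroni <- function(result, k) {
  stopifnot(inherits(result, "test_result"), k >= 1)
  result$p <- min(1, result$p * k)
  result$adjusted <- TRUE
  result$method <- paste0(result$method, " + Bonferroni(", k, ")")
  result
}

#' Mann-Whitney U test
#'
#' Wilcoxon rank-sum test, two-sided, exact when no ties and small n.
#' Samples that are entirely tied across both groups yield `p = 1`.
#'
#' @param a,b Non-empty numeric samples.
#' @return A `test_result` with the U statistic.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("groups must be non-empty")
  if (diff(range(c(a, b))) == 0)
    return(test_result(length(a) * length(b) / 2, NA_real_, 1,
                       "Mann-Whitney U (degenerate: all values tied)"))
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  test_result(unname(wt$statistic), NA_real_, wt$p.value, "Mann-Whitney U")
}

#' Kruskal-Wallis rank-sum test
#'
#' @inheritParams one_way_anova
#' @return A `test_result` with the H (chi-squared) statistic.
#' @export
kruskal_wallis <- function(values, groups) {
  gs <- split_groups(values, groups)
  if (length(gs) < 2L) stop("Kruskal-Wallis needs >= 2 groups")
  if (diff(range(unlist(gs))) == 0)
    return(test_result(0, length(gs) - 1, 1,
                       "Kruskal-Wallis (degenerate: all values tied)"))
  kw <- stats::kruskal.test(unlist(gs),
                            factor(rep(names(gs), lengths(gs))))
  test_result(unname(kw$statistic), unname(kw$parameter), kw$p.value,
              "Kruskal-Wallis")
}

#' Dunn's post hoc test
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis test, with
#' the tie correction
#' `sigma^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/ni + 1/nj)` and a
#' multiplicity adjustment (Bonferroni by default).
#'
#' @inheritParams one_way_anova
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()].
#' @return Data frame `pair, z, p, p_adj`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "bonferroni") {
  gs <- split_groups(values, groups)
  if (length(gs) < 2L) stop("Dunn post hoc needs >= 2 groups")
  all_v <- unlist(gs)
  N <- length(all_v)
  r <- rank(all_v)
  grp <- rep(names(gs), lengths(gs))
  rbar <- tapply(r, grp, mean)
  nn <- lengths(gs)
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(gs), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[[i]] + 1 / nn[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                    z = res["z", ], p = res["p", ])
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}
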