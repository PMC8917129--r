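# ---- result constructors ----------------------------------------------------

new_test_result <- function(statistic, p_value, df = NULL, method,
                            degenerate = FALSE, extra = list()) {
  stopifnot(is.numeric(p_value), p_value >= 0, p_value <= 1 + 1e-12)
  res <- c(list(statistic = unname(statistic),
                p_value = min(1, unname(p_value)),
                df = df, method = method, degenerate = degenerate), extra)
  class(res) <- "beegut_test"
  res
}

#' @export
print.beegut_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 5),
      if (!is.null(x$df)) paste0("  df = ", paste(x$df, collapse = ", ")),
      "\n  p =", format.pval(x$p_value, digits = 4),
      if (isTRUE(x$degenerate)) "  (degenerate input)", "\n")
  invisible(x)
}

new_posthoc_table <- function(group_a, group_b, estimate, raw_p, adjusted_p,
                              adjust_method) {
  out <- data.frame(group_a = group_a, group_b = group_b,
                    estimate = estimate, raw_p = raw_p,
                    adjusted_p = pmin(1, adjusted_p),
                    adjust_method = adjust_method,
                    stringsAsFactors = FALSE)
  class(out) <- c("beegut_posthoc", "data.frame")
  out
}

check_groups <- function(values, groups, min_per_group = 2L) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- table(groups)
  if (length(tab) < 2L)
    stop("need at least two groups with data")
  if (any(tab < min_per_group))
    stop("groups with fewer than ", min_per_group, " observations: ",
         paste(names(tab)[tab < min_per_group], collapse = ", "))
  list(values = values, groups = groups, tab = tab)
}

# ---- one-way ANOVA ----------------------------------------------------------

anova_ss <- function(values, groups) {
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - grand)^2)
  sst <- sum((values - grand)^2)
  list(ssb = ssb, ssw = sst - ssb, sst = sst,
       k = length(gm), n = length(values))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from sums of squares,
#' used as the parametric omnibus test for treatment effects on
#' physiological markers and as the observed statistic of the per-ASV
#' permutation ANOVA.
#'
#' @param values numeric response.
#' @param groups group labels, coerced to character.
#' @return a `beegut_test` with the F statistic, `(k-1, n-k)` degrees of
#'   freedom and the p value from the F distribution. All-identical values
#'   are flagged degenerate with `p = 1`.
#' @examples
#' anova_oneway(c(0, 1, 2, 3), c("a", "a", "b", "b"))
#' @export
anova_oneway <- function(values, groups) {
  g <- check_groups(values, groups)
  ss <- anova_ss(g$values, g$groups)
  df <- c(ss$k - 1L, ss$n - ss$k)
  if (ss$sst <= 0) {
    return(new_test_result(NA_real_, 1, df, "One-way ANOVA", degenerate = TRUE))
  }
  if (ss$ssw <= 0) {
    # groups internally constant but distinct: evidence is infinite
    return(new_test_result(Inf, 0, df, "One-way ANOVA", degenerate = TRUE))
  }
  f <- (ss$ssb / df[1]) / (ss$ssw / df[2])
  new_test_result(f, stats::pf(f, df[1], df[2], lower.tail = FALSE),
                  df, "One-way ANOVA")
}

#' Tukey honest significant difference post hoc test
#'
#' Pairwise comparisons after a one-way ANOVA, with p values from the
#' studentized range distribution with `k` groups and the ANOVA error
#' degrees of freedom. Unbalanced designs use the Tukey-Kramer standard
#' error.
#'
#' @inheritParams anova_oneway
#' @return a posthoc table with one row per unordered pair; `estimate` is
#'   the difference of group means (b - a).
#' @export
tukey_hsd <- function(values, groups) {
  g <- check_groups(values, groups)
  ss <- anova_ss(g$values, g$groups)
  k <- ss$k
  dferr <- ss$n - k
  mse <- ss$ssw / dferr
  gm <- tapply(g$values, g$groups, mean)
  gn <- tapply(g$values, g$groups, length)
  lev <- sort(names(gm))
  pairs <- utils::combn(lev, 2)
  est <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est[j] <- gm[[b]] - gm[[a]]
    if (mse <= 0) {
      p[j] <- if (abs(est[j]) > 0) 0 else 1
      next
    }
    se <- sqrt(mse / 2 * (1 / gn[[a]] + 1 / gn[[b]]))
    q <- abs(est[j]) / se
    p[j] <- stats::ptukey(q, k, dferr, lower.tail = FALSE)
  }
  if (mse <= 0 && ss$ssb <= 0) {
    warning("degenerate variance: all values identical; p values set to 1")
    p[] <- 1
  } else if (mse <= 0) {
    warning("zero within-group variance")
  }
  new_posthoc_table(pairs[1, ], pairs[2, ], est, p, p, "tukey")
}

# ---- rank-based tests -------------------------------------------------------

tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank sum test
#'
#' Nonparametric omnibus test for a location difference among k groups,
#' with midranks for ties and the standard tie correction; p from the
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @inheritParams anova_oneway
#' @export
kruskal_wallis <- function(values, groups) {
  g <- check_groups(values, groups, min_per_group = 1L)
  n <- length(g$values)
  r <- rank(g$values)
  if (length(unique(g$values)) == 1L)
    return(new_test_result(NA_real_, 1, length(g$tab) - 1L,
                           "Kruskal-Wallis", degenerate = TRUE))
  rg <- tapply(r, g$groups, mean)
  ng <- tapply(r, g$groups, length)
  h <- 12 / (n * (n + 1)) * sum(ng * rg^2) - 3 * (n + 1)
  h <- h / (1 - tie_sum(r) / (n^3 - n))
  df <- length(rg) - 1L
  new_test_result(h, stats::pchisq(h, df, lower.tail = FALSE), df,
                  "Kruskal-Wallis")
}

#' Dunn's post hoc test
#'
#' Pairwise z tests on rank means after Kruskal-Wallis, with tie-corrected
#' variance and Benjamini-Hochberg adjustment across pairs.
#'
#' @inheritParams anova_oneway
#' @export
dunn_test <- function(values, groups) {
  g <- check_groups(values, groups, min_per_group = 1L)
  n <- length(g$values)
  r <- rank(g$values)
  rg <- tapply(r, g$groups, mean)
  ng <- tapply(r, g$groups, length)
  lev <- sort(names(rg))
  pairs <- utils::combn(lev, 2)
  v0 <- n * (n + 1) / 12 - tie_sum(r) / (12 * (n - 1))
  est <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est[j] <- rg[[b]] - rg[[a]]
    se <- sqrt(v0 * (1 / ng[[a]] + 1 / ng[[b]]))
    if (se <= 0) { p[j] <- 1; next }
    p[j] <- 2 * stats::pnorm(abs(est[j]) / se, lower.tail = FALSE)
  }
  new_posthoc_table(pairs[1, ], pairs[2, ], est, p,
                    adjust_p(p, "benjamini-hochberg"), "benjamini-hochberg")
}

#' Wilcoxon-Mann-Whitney rank sum test
#'
#' Two-sample rank sum test used to compare CL and MD bacterial loads.
#' For combined sample sizes up to `exact_limit` the two-sided p value is
#' computed by full enumeration of all rank assignments (valid under ties
#' via midranks); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit combined n at or below which exact enumeration is used.
#' @return a `beegut_test`; the statistic is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n <= exact_limit) {
    sums <- utils::combn(n, nx, function(i) sum(r[i]))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= w + eps), mean(sums >= w - eps))
    return(new_test_result(w, min(1, p), NULL, "Wilcoxon rank sum (exact)"))
  }
  mu <- nx * (n + 1) / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_sum(r) / (n * (n - 1)))
  if (sigma2 <= 0)
    return(new_test_result(w, 1, NULL, "Wilcoxon rank sum", degenerate = TRUE))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  new_test_result(w, min(1, p), NULL, "Wilcoxon rank sum (normal approx.)")
}

# ---- p value adjustment -----------------------------------------------------

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjustment.
#' Output order matches input order.
#'
#' @param pvals numeric p values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini-hochberg"`.
#' @export
adjust_p <- function(pvals, method = c("bonferroni", "benjamini-hochberg")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  m <- length(pvals)
  if (method == "bonferroni") return(pmin(1, m * pvals))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  adj
}

# ---- normality routing ------------------------------------------------------

#' Choose a parametric or nonparametric analysis route
#'
#' Applies a Shapiro-Wilk test at level `alpha` to model residuals and
#' returns `"parametric"` when normality is not rejected, otherwise
#' `"nonparametric"`. Constant residuals route nonparametric with a warning.
#'
#' @param residuals numeric residuals (at least 3).
#' @param alpha significance level of the normality test.
#' @export
normality_route <- function(residuals, alpha = 0.05) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  if (stats::sd(residuals) == 0) {
    warning("constant residuals; routing nonparametric")
    return("nonparametric")
  }
  p <- stats::shapiro.test(residuals)$p.value
  if (p >= alpha) "parametric" else "nonparametric"
}

# ---- permutation p ----------------------------------------------------------

#' Empirical permutation p value
#'
#' The study's rule: the proportion of permuted statistics greater than or
#' equal to the observed one (can be exactly 0). The `"plus-one"` variant
#' `(b + 1) / (N + 1)` counts the observed arrangement as one permutation
#' and is strictly positive.
#'
#' @param observed observed statistic.
#' @param permuted numeric vector of permuted statistics.
#' @param rule `"ge-proportion"` (default) or `"plus-one"`.
#' @export
permutation_p <- function(observed, permuted,
                          rule = c("ge-proportion", "plus-one")) {
  rule <- match.arg(rule)
  if (!length(permuted)) stop("permuted must be nonempty")
  b <- sum(permuted >= observed - 1e-12)
  if (rule == "ge-proportion") b / length(permuted)
  else (b + 1) / (length(permuted) + 1)
}
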