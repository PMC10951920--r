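#' Distribution-free group summary
#'
#' Median, interquartile range (linear-interpolation quartiles) and a
#' conservative distribution-free 95 percent confidence interval for the
#' median from binomial order statistics: the interval (x_(r), x_(s)) with
#' r the largest k such that P(Binom(n, 1/2) < k) <= alpha/2 and
#' s = n + 1 - r, guaranteeing >= 95 percent coverage.
#'
#' @param values numeric vector, n >= 1.
#' @param conf confidence level (default 0.95).
#' @return list of class `group_summary`: `n`, `median`, `q1`, `q3`,
#'   `ci95_lo`, `ci95_hi`.
#' @export
group_summary <- function(values, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L)
    stop_gliotrack("group_summary needs >= 1 value",
                   "gliotrack_validation_error")
  qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  s <- sort(values)
  alpha <- 1 - conf
  # largest r with pbinom(r - 1, n, 0.5) <= alpha / 2
  r <- max(which(stats::pbinom(0:(n - 1), n, 0.5) <= alpha / 2), 0L)
  lo <- if (r >= 1) s[r] else s[1]
  hi <- if (r >= 1) s[n + 1 - r] else s[n]
  structure(list(n = n, median = qs[2], q1 = qs[1], q3 = qs[3],
                 ci95_lo = lo, ci95_hi = hi),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, median = %.4g (IQR %.4g-%.4g, 95%% CI %.4g-%.4g)\n",
              x$n, x$median, x$q1, x$q3, x$ci95_lo, x$ci95_hi))
  invisible(x)
}

test_result <- function(statistic, p_value, df = NA_real_, method = "",
                        alpha_used = NA_real_, corrected = FALSE) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), method = method, alpha_used = alpha_used,
                 corrected = corrected),
            class = "gliotrack_test")
}

#' @export
print.gliotrack_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample of the gap between the two
#' empirical CDFs; the p-value uses the asymptotic Kolmogorov distribution
#' with effective n = n_a * n_b / (n_a + n_b). Used to compare particle
#' frequency distributions between pairs of conditions.
#'
#' @param a,b numeric samples.
#' @param alpha nominal alpha before correction (default 0.05).
#' @param n_tests number of tests run on each sample, for the Bonferroni
#'   alpha (default 1 = no correction).
#' @return a test result with `statistic` (D), `p_value`, `alpha_used`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.05, n_tests = 1L) {
  if (!length(a) || !length(b))
    stop_gliotrack("both samples need >= 1 value", "gliotrack_validation_error")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  test_result(kt$statistic, kt$p.value, method = "two-sample KS",
              alpha_used = bonferroni_alpha(alpha, n_tests),
              corrected = n_tests > 1L)
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS test against a Normal with the sample's own mean and SD. Because the
#' parameters are estimated, the p-value is approximate (anti-conservative
#' in the Lilliefors sense); it is used only as a screen to route analyses
#' to nonparametric tests, not as a reported inference.
#'
#' @param values numeric sample, n >= 4.
#' @return a test result; a constant sample degenerately rejects (p = 0).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop_gliotrack("normality screen needs n >= 4", "gliotrack_validation_error")
  s <- stats::sd(values)
  if (s == 0)
    return(test_result(1, 0, method = "KS normality screen (degenerate)"))
  kt <- suppressWarnings(stats::ks.test(values, "pnorm",
                                        mean = mean(values), sd = s,
                                        exact = FALSE))
  test_result(kt$statistic, kt$p.value,
              method = "KS normality screen (approximate)")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k - 1 df (via
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 1).
#' @return a test result with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop_gliotrack("need >= 2 non-empty groups", "gliotrack_validation_error")
  if (length(unique(unlist(groups))) == 1L)
    return(test_result(0, 1, df = length(groups) - 1,
                       method = "Kruskal-Wallis"))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  test_result(kt$statistic, kt$p.value, df = kt$parameter,
              method = "Kruskal-Wallis")
}

#' Dunn's post hoc multiple-comparisons test
#'
#' Pairwise mean-rank comparisons after Kruskal-Wallis:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j)) with
#' the tie term T = sum(t^3 - t) / (12 (N - 1)); two-sided p-values are
#' Bonferroni-adjusted over all k(k-1)/2 pairs (the standard Dunn
#' adjustment).
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunns_posthoc <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop_gliotrack("need >= 2 non-empty groups", "gliotrack_validation_error")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  k <- ncol(pairs)
  z <- p_un <- numeric(k)
  for (m in seq_len(k)) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[m] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p_un[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadjusted = p_un, p_adjusted = pmin(1, p_un * k))
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha nominal alpha.
#' @param n_tests number of tests carried out on the same sample.
#' @return alpha / n_tests.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (n_tests < 1)
    stop_gliotrack("n_tests must be >= 1", "gliotrack_validation_error")
  alpha / n_tests
}
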