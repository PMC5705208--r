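# The study's statistical protocol: normality-gated test selection,
# variance-gated t flavour, sequential multiple-comparison correction, KS
# wrapper and the minimal-sample-size search.

test_result <- function(test_name, statistic, p_raw, n_per_group,
                        trace = list(), p_corrected = NA_real_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_raw = p_raw, p_corrected = p_corrected,
                 n_per_group = n_per_group, trace = trace),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, x$p_raw,
              paste(x$n_per_group, collapse = ", ")))
  if (length(x$trace)) {
    cat("  selection:", paste(names(x$trace), unlist(lapply(x$trace, format)),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-group comparison with normality- and variance-gated test selection
#'
#' Shapiro-Wilk normality is assessed in each group; if both pass
#' (p >= `alpha_gate`) an F test compares variances and a two-tailed
#' Student's t-test (equal variances) or heteroscedastic Welch t-test is
#' used. If either group fails normality a two-tailed Mann-Whitney test is
#' used (mid-rank ties; exact p for small untied samples, normal
#' approximation with continuity correction otherwise). The selection path
#' is recorded in the result's `trace`.
#'
#' @param group_a,group_b numeric vectors (each n >= 3).
#' @param alpha_gate gate for the Shapiro-Wilk and F tests (default 0.05).
#' @return a `test_result` with fields `test_name`, `statistic`, `p_raw`,
#'   `n_per_group` and `trace`.
#' @export
auto_compare <- function(group_a, group_b, alpha_gate = 0.05) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3) {
    stopf("insufficient n for normality gate: need >= 3 per group")
  }
  sw_a <- if (stats::sd(group_a) == 0) 0 else
    stats::shapiro.test(group_a)$p.value
  sw_b <- if (stats::sd(group_b) == 0) 0 else
    stats::shapiro.test(group_b)$p.value
  trace <- list(shapiro_a = sw_a, shapiro_b = sw_b)
  n <- c(length(group_a), length(group_b))
  if (sw_a >= alpha_gate && sw_b >= alpha_gate) {
    fp <- stats::var.test(group_a, group_b)$p.value
    trace$f_test <- fp
    equal_var <- fp >= alpha_gate
    tt <- stats::t.test(group_a, group_b, var.equal = equal_var)
    trace$selected <- if (equal_var) "student_t" else "welch_t"
    return(test_result(trace$selected, tt$statistic, tt$p.value, n, trace))
  }
  trace$selected <- "mann_whitney"
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            correct = TRUE))
  test_result("mann_whitney", wt$statistic, wt$p.value, n, trace)
}

#' One-sample comparison against a reference value
#'
#' Shapiro-Wilk gated choice between a two-tailed one-sample t-test and a
#' Wilcoxon signed-rank test.
#'
#' @param x numeric vector (n >= 3).
#' @param mu reference value.
#' @param alpha_gate normality gate (default 0.05).
#' @return a `test_result`.
#' @export
one_sample_compare <- function(x, mu = 0, alpha_gate = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stopf("insufficient n for normality gate")
  sw <- if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  trace <- list(shapiro = sw)
  if (sw >= alpha_gate) {
    tt <- stats::t.test(x, mu = mu)
    trace$selected <- "one_sample_t"
    return(test_result("one_sample_t", tt$statistic, tt$p.value,
                       length(x), trace))
  }
  trace$selected <- "wilcoxon_signed_rank"
  wt <- suppressWarnings(stats::wilcox.test(x, mu = mu, correct = TRUE))
  test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value,
              length(x), trace)
}

#' Sequential multiple-comparison correction
#'
#' The rank-multiplier rule: for N comparisons, the most significant p is
#' multiplied by N, the second most significant by N - 1, and so on down to
#' a multiplier of 1, with results clamped to at most 1. Corrected p-values
#' are significant if below 0.05. By default no monotonicity is enforced
#' across ranks (the literal rule); `monotone = TRUE` applies the usual
#' step-down running maximum, which makes the rule identical to
#' Holm-Bonferroni.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param monotone enforce non-decreasing corrected values along the
#'   significance ranking (default FALSE).
#' @return corrected p-values, in the input order.
#' @export
holm_correct <- function(p_values, monotone = FALSE) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("invalid p: all p-values must lie in [0, 1]")
  }
  n <- length(p_values)
  o <- order(p_values)
  corrected_sorted <- p_values[o] * (n - seq_len(n) + 1)
  if (monotone) corrected_sorted <- cummax(corrected_sorted)
  corrected_sorted <- pmin(corrected_sorted, 1)
  out <- numeric(n)
  out[o] <- corrected_sorted
  out
}

#' Kolmogorov-Smirnov comparison of cumulative distributions
#'
#' Two-sample KS when `b` is a numeric sample; one-sample KS against the
#' continuous CDF when `b` is a [distance_cdf()]. Two-sided p-values.
#'
#' @param sample_a numeric sample.
#' @param b numeric sample or a [distance_cdf()].
#' @return a `test_result` with `test_name = "ks"`.
#' @export
ks_compare <- function(sample_a, b) {
  if (length(sample_a) == 0) stopf("empty sample")
  if (inherits(b, "distance_cdf")) {
    kt <- suppressWarnings(stats::ks.test(sample_a,
                                          function(q) cdf_prob(b, q)))
    trace <- list(variant = "one_sample")
    n <- length(sample_a)
  } else {
    if (length(b) == 0) stopf("empty sample")
    kt <- suppressWarnings(stats::ks.test(sample_a, b))
    trace <- list(variant = "two_sample")
    n <- c(length(sample_a), length(b))
  }
  test_result("ks", kt$statistic, kt$p.value, n, trace)
}

#' Minimal per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group such that a two-sided two-sample t-test
#' (equal group sizes, common standard deviation) attains the target power,
#' using the noncentral-t power function with noncentrality
#' delta/sd * sqrt(n/2) and 2n - 2 degrees of freedom. The search floors at
#' n = 2 per group (the smallest n giving positive degrees of freedom).
#'
#' @param delta true between-group difference (> 0).
#' @param sd common standard deviation (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power in (0, 1) (default 0.8).
#' @param n_max search ceiling (default 1e5).
#' @return integer n per group.
#' @examples
#' min_sample_size(delta = 50, sd = 25)  # 6
#' @export
min_sample_size <- function(delta, sd, alpha = 0.05, power = 0.8,
                            n_max = 1e5) {
  if (!is.numeric(delta) || delta <= 0 || !is.numeric(sd) || sd <= 0) {
    stopf("delta and sd must be positive")
  }
  if (power <= 0 || power >= 1) stopf("power must lie in (0, 1)")
  for (n in 2:n_max) {
    pw <- stats::power.t.test(n = n, delta = delta, sd = sd,
                              sig.level = alpha,
                              type = "two.sample",
                              alternative = "two.sided")$power
    if (pw >= power) return(as.integer(n))
  }
  stopf("target power unreachable within n_max = %d", n_max)
}

#' Serialize test results to a flat data frame
#'
#' @param results list of `test_result` objects (optionally named).
#' @return data frame with one row per test, including the selection trace
#'   collapsed to a string for auditability.
#' @export
test_results_table <- function(results) {
  if (inherits(results, "test_result")) results <- list(results)
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      label = names(results)[i] %||% as.character(i),
      test_name = r$test_name, statistic = r$statistic, p_raw = r$p_raw,
      p_corrected = r$p_corrected,
      n = paste(r$n_per_group, collapse = "/"),
      trace = paste(names(r$trace), vapply(r$trace, format, ""),
                    sep = "=", collapse = ";"))
  }))
}
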