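#' Two-sample comparison of a continuous variable
#'
#' Welch (unequal-variance) two-sided t-test. The unequal-variance form is the
#' robust default for two clinical groups; with similar group SDs it is
#' practically identical to the pooled test.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return List with `statistic`, `p.value`, `df`, and the underlying
#'   `htest` object in `$test`.
#' @export
two_sample_t <- function(a, b) {
  for (v in list(a, b)) {
    if (!is.numeric(v) || sum(is.finite(v)) < 2L)
      stop("each group needs at least 2 finite values", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), test = ht)
}

#' Test of association in a contingency table
#'
#' Pearson chi-square without continuity correction is the primary test.
#' For a 2x2 table with any expected count below 5 the automatic mode falls
#' back to Fisher's exact test (two-sided), and the method actually used is
#' reported — the small-sample rule is explicit, not silent.
#'
#' @param tab Matrix of non-negative integer counts (2 x k).
#' @param method `"auto"` (default), `"pearson"`, or `"fisher"`.
#' @param expected_min Expected-count threshold for the automatic Fisher
#'   fallback (default 5).
#' @return List with `statistic` (chi-square statistic; `NA` for Fisher),
#'   `p.value`, `df`, `method` (the method run), and `test` (the `htest`).
#' @examples
#' tts <- matrix(c(8, 0, 19, 25), nrow = 2) # sign-positive counts by group
#' categorical_test(tts, method = "pearson")$statistic # 8.754
#' categorical_test(tts)$method                        # "fisher" (expected < 5)
#' @export
categorical_test <- function(tab, method = c("auto", "pearson", "fisher"),
                             expected_min = 5) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must contain non-negative integer counts", call. = FALSE)
  if (sum(tab) == 0) stop("all-zero contingency table", call. = FALSE)
  if (sum(rowSums(tab) > 0) < 2L || sum(colSums(tab) > 0) < 2L)
    stop("need at least 2 non-empty rows and columns", call. = FALSE)

  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (all(dim(tab) == c(2L, 2L)) && any(expected < expected_min))
      "fisher" else "pearson"
  }
  if (method == "fisher") {
    ht <- stats::fisher.test(tab)
    list(statistic = NA_real_, p.value = ht$p.value, df = NA_real_,
         method = "fisher", test = ht)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), method = "pearson", test = ht)
  }
}

#' Correlation between two variables
#'
#' Pearson's or Spearman's correlation with a two-sided p-value, used for the
#' association of CCAR with DO status and with the recovery rate.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p.value`, `method`, and `test`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must be numeric vectors of equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in input", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ht$estimate), p.value = ht$p.value,
       method = method, test = ht)
}

#' Mean with t-based confidence interval
#'
#' Sample mean, SD and the 95% (by default) CI
#' `mean +/- t_{n-1, 1-alpha/2} * sd / sqrt(n)` — the format used for
#' group-level CCAR summaries.
#'
#' @param values Numeric vector, `NA` dropped, at least 2 values.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean`, `sd`, `n`, `ci_lower`, `ci_upper`.
#' @export
mean_ci <- function(values, conf_level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, sd = s, n = n, ci_lower = m - half, ci_upper = m + half)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Exact interval for a proportion by inversion of the binomial tails
#' (delegated to [stats::binom.test()]). At the boundaries the interval has
#' the closed forms: lower bound `(alpha/2)^(1/n)` when all n trials succeed,
#' upper bound `1 - (alpha/2)^(1/n)` when none do.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @return Named numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (length(successes) != 1L || length(n) != 1L || n < 1 ||
      successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("need integer 0 <= successes <= n with n >= 1", call. = FALSE)
  ci <- stats::binom.test(successes, n, conf.level = 1 - alpha)$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

#' Pooled mean of group summaries
#'
#' Size-weighted mean of per-group means, used to recover whole-cohort
#' summaries (mean age, follow-up) from a grouped summary table.
#'
#' @param means Numeric vector of group means.
#' @param ns Integer vector of group sizes, same length.
#' @return The pooled mean.
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) != length(ns) || any(ns <= 0))
    stop("'means' and 'ns' must match with positive sizes", call. = FALSE)
  sum(means * ns) / sum(ns)
}

#' Format a p-value for reporting
#'
#' Three decimals with a display floor of `"<0.001"`.
#'
#' @param p P-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
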