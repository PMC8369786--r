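#' Empirical ROC curve with AUC, DeLong CI and Youden cut-off
#'
#' Sweeps classification thresholds over the observed score values with the
#' decision rule "positive iff score < cutoff" (direction
#' `"lower_is_positive"`, the convention for CCAR where a low score indicates
#' dural ossification / poor outcome), or "positive iff score > cutoff" for
#' `"higher_is_positive"`.
#'
#' The AUC is the Mann-Whitney probability that a positive scores on the
#' diseased side of a negative, counting ties as 1/2; its confidence interval
#' uses DeLong's placement-value variance by default, with the Hanley-McNeil
#' approximation as an option. The optimal cut-off maximizes Youden's
#' J = sensitivity + specificity - 1 over the observed score values; ties on
#' J are broken toward higher sensitivity, then toward the lower threshold.
#'
#' @param scores Numeric scores (e.g. CCAR percents).
#' @param labels Logical (or 0/1) vector, `TRUE` = condition positive.
#' @param direction `"lower_is_positive"` (default) or `"higher_is_positive"`.
#' @param conf_level Confidence level for the AUC CI (default 0.95).
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @return Object of class `ccar_roc`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `auc_se`, `optimal_cutoff`, `youden_j`,
#'   `direction`, `n_pos`, `n_neg`, `ci_method`.
#' @examples
#' set.seed(1)
#' s <- c(rnorm(20, 25, 10), rnorm(20, 50, 10))
#' r <- empirical_roc(s, rep(c(TRUE, FALSE), each = 20))
#' r$auc
#' @export
empirical_roc <- function(scores, labels,
                          direction = c("lower_is_positive", "higher_is_positive"),
                          conf_level = 0.95, ci_method = c("delong", "hanley")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  if (!is.numeric(scores) || anyNA(scores))
    stop("'scores' must be numeric without NA", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(labels) || length(labels) != length(scores))
    stop("'labels' must be logical/0-1 and match 'scores'", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("degenerate labels: both classes must be present", call. = FALSE)

  # orient so that internally "smaller x = more diseased" always holds
  x <- if (direction == "lower_is_positive") scores else -scores
  pos <- x[labels]
  neg <- x[!labels]
  m <- length(pos)
  n <- length(neg)

  # threshold sweep: rule is "positive iff x < c" over observed values (+Inf
  # appended so the curve reaches sensitivity 1 / specificity 0)
  thr <- c(sort(unique(x)), Inf)
  sens <- vapply(thr, function(c) mean(pos < c), numeric(1))
  spec <- vapply(thr, function(c) mean(neg >= c), numeric(1))

  # Mann-Whitney AUC with ties as 1/2, via midranks
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  auc <- 1 - auc # P(pos < neg) + 0.5 P(tie)

  if (ci_method == "delong") {
    # placement values on the oriented scale (positive "wins" when smaller)
    v10 <- vapply(pos, function(p) (sum(p < neg) + 0.5 * sum(p == neg)) / n,
                  numeric(1))
    v01 <- vapply(neg, function(q) (sum(pos < q) + 0.5 * sum(pos == q)) / m,
                  numeric(1))
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  # Youden optimum over observed values only (a reportable score), tie-break:
  # max J, then max sensitivity, then lowest threshold. Comparisons run on
  # integer counts (m*n*(J+1) = n*TP + m*TN) so mathematically tied J values
  # never split on floating-point rounding.
  obs <- seq_len(length(thr) - 1L)
  cpos <- vapply(thr[obs], function(c) sum(pos < c), numeric(1))
  cneg <- vapply(thr[obs], function(c) sum(neg >= c), numeric(1))
  jint <- cpos * n + cneg * m
  best <- obs[jint == max(jint)]
  best <- best[cpos[best] == max(cpos[best])]
  best <- best[which.min(thr[best])]
  cutoff <- thr[best]
  if (direction == "higher_is_positive") cutoff <- -cutoff

  structure(list(
    thresholds = if (direction == "lower_is_positive") thr else rev(-thr),
    sensitivity = if (direction == "lower_is_positive") sens else rev(sens),
    specificity = if (direction == "lower_is_positive") spec else rev(spec),
    auc = auc, auc_ci = ci, auc_se = se,
    optimal_cutoff = cutoff, youden_j = max(jint) / (m * n) - 1,
    direction = direction, n_pos = m, n_neg = n,
    conf_level = conf_level, ci_method = ci_method
  ), class = "ccar_roc")
}

#' @export
print.ccar_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC (%d positive / %d negative, %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC = %.3f (%d%% CI %.3f to %.3f, %s)\n",
              x$auc, round(100 * x$conf_level), x$auc_ci[1], x$auc_ci[2],
              x$ci_method))
  cat(sprintf("  Youden-optimal cutoff = %.4g (J = %.3f)\n",
              x$optimal_cutoff, x$youden_j))
  invisible(x)
}

#' Export an ROC sweep as a data frame
#'
#' One row per threshold with sensitivity and specificity, suitable for
#' `write.csv()` or plotting.
#'
#' @param roc A `ccar_roc` object.
#' @return Data frame with columns `threshold`, `sensitivity`, `specificity`.
#' @export
roc_table <- function(roc) {
  stopifnot(inherits(roc, "ccar_roc"))
  data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
             specificity = roc$specificity)
}

#' Diagnostic performance at a fixed cut-off
#'
#' Confusion-matrix counts under "positive iff score < cutoff" (or `>` for
#' `"higher_is_positive"`), with sensitivity, specificity and accuracy (the
#' diagnostic coincidence rate, (TP+TN)/N) each carrying an exact
#' Clopper-Pearson confidence interval.
#'
#' @inheritParams empirical_roc
#' @param cutoff Finite decision threshold on the score scale.
#' @return Object of class `ccar_diagperf`: list with `counts`
#'   (TP, FP, TN, FN), and `sensitivity`, `specificity`, `accuracy`, each a
#'   list with `estimate`, `ci_lower`, `ci_upper` (proportions).
#' @export
diagnostic_performance <- function(scores, labels, cutoff,
                                   direction = c("lower_is_positive",
                                                 "higher_is_positive"),
                                   conf_level = 0.95) {
  direction <- match.arg(direction)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop("'cutoff' must be a single finite number", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(labels) || length(labels) != length(scores))
    stop("'labels' must be logical/0-1 and match 'scores'", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("degenerate labels: both classes must be present", call. = FALSE)
  pred <- if (direction == "lower_is_positive") scores < cutoff else scores > cutoff

  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  prop <- function(x, n) {
    ci <- clopper_pearson(x, n, alpha = 1 - conf_level)
    list(estimate = x / n, ci_lower = unname(ci["lower"]),
         ci_upper = unname(ci["upper"]), successes = x, n = n)
  }
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    cutoff = cutoff, direction = direction, conf_level = conf_level,
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    accuracy = prop(tp + tn, tp + fp + tn + fn)
  ), class = "ccar_diagperf")
}

#' @export
print.ccar_diagperf <- function(x, ...) {
  fmt <- function(p) sprintf("%.1f%% (%.1f to %.1f%%)", 100 * p$estimate,
                             100 * p$ci_lower, 100 * p$ci_upper)
  cat(sprintf("Cutoff %s %.4g: TP=%d FP=%d TN=%d FN=%d\n",
              if (x$direction == "lower_is_positive") "<" else ">",
              x$cutoff, x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  invisible(x)
}
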