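#' Inter-observer intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation for a subjects x raters matrix of measurements, with the
#' McGraw-Wong F-based confidence interval. Absolute agreement is the right
#' form for interchangeable observers: a constant offset between observers
#' lowers the coefficient, unlike the consistency form.
#'
#' From the two-way ANOVA mean squares (MSR between subjects, MSC between
#' raters, MSE residual) with n subjects and k raters:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements Numeric matrix or data frame, one row per subject, one
#'   column per rater; at least 5 subjects, 2 raters, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `ccar_icc`: list with `icc`, `ci` (lower, upper),
#'   `model`, `n`, `k`, and the mean squares.
#' @export
icc_interobserver <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (!is.numeric(m) || anyNA(m))
    stop("'measurements' must be a numeric matrix with no missing cells",
         call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr <= .Machine$double.eps * abs(grand + 1)) {
    warning("zero between-subject variance: ICC degenerate", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong (1996) CI for ICC(A,1) via Satterthwaite df
  alpha <- 1 - conf_level
  fj <- if (mse > 0) msc / mse else Inf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (is.finite(fj) && is.finite(a) && is.finite(b)) {
    vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    lower <- upper <- icc
  }
  structure(list(icc = icc, ci = c(lower = lower, upper = upper),
                 model = "ICC(2,1) two-way random, absolute agreement, single rater",
                 n = n, k = k, msr = msr, msc = msc, mse = mse,
                 conf_level = conf_level),
            class = "ccar_icc")
}

#' @export
print.ccar_icc <- function(x, ...) {
  cat(sprintf("%s\n  ICC = %.3f (%d%% CI %.3f to %.3f), %d subjects x %d raters\n",
              x$model, x$icc, round(100 * x$conf_level),
              x$ci["lower"], x$ci["upper"], x$n, x$k))
  invisible(x)
}
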