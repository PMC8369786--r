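#' Ossified-mass cross-section area ratio (OCAR)
#'
#' Percent of the normal bony canal occupied by the ossified mass on the
#' axial CT slice at maximum compression.
#'
#' @param mass_area Ossified-mass CSA, mm^2 (CT, level of maximum compression).
#' @param canal_area Normal spinal-canal CSA, mm^2 (CT, pedicle level near the
#'   narrowest segment). Must be positive.
#' @return OCAR in percent. Vectorized.
#' @export
ocar <- function(mass_area, canal_area) {
  check_area(mass_area, "mass_area")
  check_area(canal_area, "canal_area")
  if (any(canal_area == 0))
    stop("'canal_area' must be positive (division by zero)", call. = FALSE)
  100 * mass_area / canal_area
}

#' Spinal-cord cross-section area ratio (SCAR)
#'
#' Percent of the reference dural sac occupied by the cord at the narrowest
#' level on MRI. The reference is the mean adjacent-segment dural-sac area
#' from [reference_dural_sac_area()].
#'
#' @param cord_area Cord CSA at the narrowest level, mm^2 (MRI).
#' @param dural_sac_ref_area Reference dural-sac CSA, mm^2. Must be positive.
#' @return SCAR in percent. Vectorized.
#' @export
scar <- function(cord_area, dural_sac_ref_area) {
  check_area(cord_area, "cord_area")
  check_area(dural_sac_ref_area, "dural_sac_ref_area")
  if (any(dural_sac_ref_area == 0))
    stop("'dural_sac_ref_area' must be positive (division by zero)", call. = FALSE)
  100 * cord_area / dural_sac_ref_area
}

#' Cerebrospinal-fluid cross-section area ratio (CCAR)
#'
#' The CSF share of the canal, defined as `100 - OCAR - SCAR` (percent).
#' Values outside \[0, 100\] can arise under measurement noise; they are
#' returned unchanged with a warning rather than silently clipped, so that
#' downstream QC and ROC analysis see the raw score. Use
#' `ccar_out_of_range()` for the flag itself.
#'
#' @param ocar,scar Component ratios in percent, both non-negative. Vectorized.
#' @return CCAR in percent (possibly outside \[0, 100\], flagged by warning).
#' @seealso [ccar_zone()], [predict_do()], [outcome_zone()]
#' @export
ccar <- function(ocar, scar) {
  if (!is.numeric(ocar) || !is.numeric(scar))
    stop("'ocar' and 'scar' must be numeric", call. = FALSE)
  if (any(ocar < 0, na.rm = TRUE) || any(scar < 0, na.rm = TRUE))
    stop("'ocar' and 'scar' must be non-negative", call. = FALSE)
  out <- 100 - ocar - scar
  n_bad <- sum(ccar_out_of_range(out), na.rm = TRUE)
  if (n_bad > 0L)
    warning(sprintf("%d CCAR value(s) outside [0, 100]; retained unclipped", n_bad),
            call. = FALSE)
  out
}

#' @rdname ccar
#' @param x CCAR values in percent.
#' @return `ccar_out_of_range()`: logical vector, TRUE where outside \[0, 100\].
#' @export
ccar_out_of_range <- function(x) x < 0 | x > 100

#' Convert between percent and fraction scales
#'
#' All ratios in this package are carried as percents (the field's reporting
#' convention); these accessors convert explicitly so that no silent x100
#' factor ever enters a formula.
#'
#' @param pct Values in percent.
#' @param frac Values as fractions.
#' @return The value on the other scale.
#' @export
as_fraction <- function(pct) pct / 100

#' @rdname as_fraction
#' @export
as_percent <- function(frac) frac * 100

#' Neurological recovery rate from mJOA scores
#'
#' `RR = 100 * (followup - pre) / (11 - pre)` on the 11-point thoracic mJOA
#' scale. Undefined (returned as `NA`) when the preoperative score is already
#' the maximum 11, since no recovery headroom exists; such patients are
#' excluded from aggregate RR statistics. Negative RR (deterioration) is a
#' valid value.
#'
#' @param pre,followup Integer mJOA scores in \[0, 11\]. Vectorized.
#' @return Recovery rate in percent, `NA` where `pre == 11`.
#' @export
recovery_rate <- function(pre, followup) {
  check_mjoa(pre, "pre")
  check_mjoa(followup, "followup")
  out <- ifelse(pre == 11, NA_real_, 100 * (followup - pre) / (11 - pre))
  out
}

#' Four-level grading of the recovery rate
#'
#' Excellent 75-100%, good 50-74%, fair 25-49%, poor 0-24%. Grading is applied
#' to the unrounded RR with interval edges `[75, 100]`, `[50, 75)`, `[25, 50)`,
#' `(-Inf, 25)`; negative RR (deterioration) falls in the worst category since
#' the printed scale starts at 0. `NA` (undefined RR) propagates.
#'
#' @param rr Recovery rate in percent. Vectorized.
#' @return Ordered factor with levels poor < fair < good < excellent.
#' @export
grade_rr <- function(rr) {
  if (!is.numeric(rr)) stop("'rr' must be numeric", call. = FALSE)
  cut(rr, breaks = c(-Inf, 25, 50, 75, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent"), ordered_result = TRUE)
}

#' Diagnostic zone for dural ossification from CCAR
#'
#' Three zones: DO zone (CCAR <= 14.3%, every such patient had DO), non-DO
#' zone (CCAR >= 44.5%), gray zone in between. Outer boundaries are closed
#' (the boundary value belongs to the outer zone); the zone cut points are
#' parameters with these reference defaults.
#'
#' @param ccar CCAR in percent. Vectorized.
#' @param do_max Upper edge of the DO zone (default 14.3).
#' @param nondo_min Lower edge of the non-DO zone (default 44.5).
#' @return Factor with levels do_zone, gray_zone, non_do_zone.
#' @export
ccar_zone <- function(ccar, do_max = 14.3, nondo_min = 44.5) {
  if (!is.numeric(ccar)) stop("'ccar' must be numeric", call. = FALSE)
  if (do_max >= nondo_min) stop("'do_max' must be below 'nondo_min'", call. = FALSE)
  out <- ifelse(ccar <= do_max, "do_zone",
                ifelse(ccar >= nondo_min, "non_do_zone", "gray_zone"))
  factor(out, levels = c("do_zone", "gray_zone", "non_do_zone"))
}

#' Predict dural ossification from CCAR at a cut-off
#'
#' Positive (DO predicted) iff `ccar < cutoff` — the ROC convention with the
#' lower score indicating disease. The cut-off value itself therefore
#' classifies as non-DO. Default cut-off 36.4% is the reference Youden
#' optimum.
#'
#' @param ccar CCAR in percent. Vectorized.
#' @param cutoff Decision threshold in percent.
#' @return Logical: TRUE where DO is predicted.
#' @export
predict_do <- function(ccar, cutoff = 36.4) {
  if (!is.numeric(ccar) || !is.numeric(cutoff) || length(cutoff) != 1L)
    stop("'ccar' must be numeric and 'cutoff' a single number", call. = FALSE)
  ccar < cutoff
}

#' Expected-outcome zone from CCAR
#'
#' CCAR <= 14.3% predicts a poor-or-fair recovery rate; CCAR >= 45.2%
#' predicts good-or-excellent recovery; in between the outcome is
#' indeterminate.
#'
#' @param ccar CCAR in percent. Vectorized.
#' @param poor_max Upper edge of the poor-or-fair zone (default 14.3).
#' @param good_min Lower edge of the good-or-excellent zone (default 45.2).
#' @return Factor with levels poor_or_fair, indeterminate, good_or_excellent.
#' @export
outcome_zone <- function(ccar, poor_max = 14.3, good_min = 45.2) {
  if (!is.numeric(ccar)) stop("'ccar' must be numeric", call. = FALSE)
  if (poor_max >= good_min) stop("'poor_max' must be below 'good_min'", call. = FALSE)
  out <- ifelse(ccar <= poor_max, "poor_or_fair",
                ifelse(ccar >= good_min, "good_or_excellent", "indeterminate"))
  factor(out, levels = c("poor_or_fair", "indeterminate", "good_or_excellent"))
}

#' Score every patient in a cohort table
#'
#' Averages the two observers x two repeats per measurement site, forms the
#' reference dural-sac area from the adjacent segments, and appends the score
#' panel columns: `ocar_pct`, `scar_pct`, `ccar_pct`, `ccar_flag` (out of
#' \[0, 100\]), `rr_pct`, `rr_grade`, `ccar_zone`, `outcome_zone`.
#'
#' @param cohort Cohort data frame in the schema of [load_cohort()] /
#'   [generate_cohort()].
#' @return The cohort with score columns appended.
#' @export
score_cohort <- function(cohort) {
  check_cohort(cohort)
  site_mean <- function(site) {
    cols <- paste0(site, "_", c("o1r1", "o1r2", "o2r1", "o2r2"), "_mm2")
    rowMeans(as.matrix(cohort[, cols]))
  }
  canal <- site_mean("canal_ct")
  mass <- site_mean("mass_ct")
  dural_ref <- reference_dural_sac_area(site_mean("dural_upper_mri"),
                                        site_mean("dural_lower_mri"))
  cord <- site_mean("cord_mri")

  cohort$ocar_pct <- ocar(mass, canal)
  cohort$scar_pct <- scar(cord, dural_ref)
  cohort$ccar_pct <- suppressWarnings(ccar(cohort$ocar_pct, cohort$scar_pct))
  cohort$ccar_flag <- ccar_out_of_range(cohort$ccar_pct)
  cohort$rr_pct <- recovery_rate(cohort$mjoa_pre, cohort$mjoa_fu)
  cohort$rr_grade <- grade_rr(cohort$rr_pct)
  cohort$ccar_zone <- ccar_zone(cohort$ccar_pct)
  cohort$outcome_zone <- outcome_zone(cohort$ccar_pct)
  cohort
}

# -- internal validators -----------------------------------------------------

check_area <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop(sprintf("'%s' must be non-negative and non-missing", name), call. = FALSE)
  invisible(x)
}

check_mjoa <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x != round(x)) || any(x < 0) || any(x > 11))
    stop(sprintf("'%s' must be integer mJOA scores in [0, 11] (11-point scale)", name),
         call. = FALSE)
  invisible(x)
}
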