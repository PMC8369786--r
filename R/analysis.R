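#' Configuration of the full cohort analysis
#'
#' @param rr_threshold Recovery-rate dichotomization for the outcome ROC:
#'   `RR >= rr_threshold` counts as good-or-excellent recovery (default 50,
#'   the lower edge of the "good" grade); patients below it are the outcome
#'   positives the ROC tries to flag.
#' @param conf_level Confidence level used throughout (default 0.95).
#' @param ci_method AUC CI method, `"delong"` (default) or `"hanley"`.
#' @param zone_do,zone_outcome Length-2 reference zone edges used for the
#'   zone columns of the scored cohort (defaults `c(14.3, 44.5)` and
#'   `c(14.3, 45.2)`).
#' @return List of class `ccar_config`.
#' @export
analysis_config <- function(rr_threshold = 50, conf_level = 0.95,
                            ci_method = c("delong", "hanley"),
                            zone_do = c(14.3, 44.5),
                            zone_outcome = c(14.3, 45.2)) {
  structure(list(rr_threshold = rr_threshold, conf_level = conf_level,
                 ci_method = match.arg(ci_method), zone_do = zone_do,
                 zone_outcome = zone_outcome),
            class = "ccar_config")
}

# data-driven zone edges from an ROC sweep: the largest cutoff that still has
# perfect specificity (all-positive zone) and the smallest with perfect
# sensitivity (all-negative zone)
zone_cutoffs <- function(roc) {
  obs <- is.finite(roc$thresholds)
  thr <- roc$thresholds[obs]
  sens <- roc$sensitivity[obs]
  spec <- roc$specificity[obs]
  c(lower = if (any(spec == 1)) max(thr[spec == 1]) else NA_real_,
    upper = if (any(sens == 1)) min(thr[sens == 1]) else NA_real_)
}

summarize_test <- function(tt) {
  list(statistic = tt$statistic, p = tt$p.value,
       method = if (!is.null(tt$method)) tt$method else "welch_t")
}

group_continuous <- function(x, do_status, name) {
  a <- x[do_status & !is.na(x)]
  b <- x[!do_status & !is.na(x)]
  tt <- two_sample_t(a, b)
  data.frame(variable = name,
             do_mean = mean(a), do_sd = stats::sd(a),
             nondo_mean = mean(b), nondo_sd = stats::sd(b),
             statistic = tt$statistic, p = tt$p.value)
}

group_categorical <- function(x, do_status, name) {
  tab <- unclass(table(factor(do_status, c(TRUE, FALSE)), x))
  tab <- tab[, colSums(tab) > 0, drop = FALSE] # drop unobserved categories
  if (ncol(tab) < 2L)
    return(data.frame(variable = name, statistic = NA_real_, p = NA_real_,
                      method = "constant"))
  ct <- categorical_test(tab)
  data.frame(variable = name, statistic = ct$statistic, p = ct$p.value,
             method = ct$method)
}

# per-observer CCAR (mean of the two repeats per observer), for the ICC
observer_ccar <- function(cohort) {
  obs_mean <- function(site, o) {
    cols <- paste0(site, "_", o, c("r1", "r2"), "_mm2")
    rowMeans(as.matrix(cohort[, cols]))
  }
  vapply(c("o1", "o2"), function(o) {
    dural <- reference_dural_sac_area(obs_mean("dural_upper_mri", o),
                                      obs_mean("dural_lower_mri", o))
    100 - ocar(obs_mean("mass_ct", o), obs_mean("canal_ct", o)) -
      scar(obs_mean("cord_mri", o), dural)
  }, numeric(nrow(cohort)))
}

#' Run the full CCAR analysis on a cohort
#'
#' Scores every patient (unless score columns are already present), then
#' builds the complete evaluation report: demographic group comparisons,
#' sign/CCAR group table, inter-observer ICC(2,1) on per-observer CCAR,
#' CCAR-DO and CCAR-RR correlations, both ROC analyses (DO diagnosis and
#' dichotomized recovery outcome), and diagnostic-performance tables at the
#' data-driven zone edges and Youden optimum of each ROC. Deterministic for
#' fixed input and configuration.
#'
#' @param cohort Cohort data frame ([load_cohort()] / [generate_cohort()]).
#' @param config An [analysis_config()].
#' @return Object of class `ccar_report` (a nested list of plain scalars,
#'   vectors and data frames; serializable as JSON via [write_report()]).
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  check_cohort(cohort)
  if (!all(score_columns() %in% names(cohort))) cohort <- score_cohort(cohort)
  do <- as.logical(cohort$do_status)
  if (!any(do) || all(do))
    stop("degenerate labels: cohort must contain both DO and non-DO patients",
         call. = FALSE)

  demographics <- do.call(rbind, list(
    group_continuous(cohort$age_yr, do, "age_yr"),
    group_continuous(cohort$followup_yr, do, "followup_yr"),
    group_continuous(cohort$mjoa_pre, do, "mjoa_pre"),
    group_continuous(cohort$mjoa_fu, do, "mjoa_fu"),
    group_continuous(cohort$rr_pct, do, "rr_pct")))
  categorical <- do.call(rbind, list(
    group_categorical(cohort$sex, do, "sex"),
    group_categorical(factor(cohort$segment,
                             c("T1_T4", "T5_T8", "T9_T12")), do, "segment"),
    group_categorical(factor(cohort$sato_type,
                             c("lateral", "extended", "enlarged", "fused",
                               "tuberous")), do, "sato_type"),
    group_categorical(factor(cohort$tts, c(TRUE, FALSE)), do, "tts"),
    group_categorical(factor(cohort$cs, c(TRUE, FALSE)), do, "cs"),
    group_categorical(factor(cohort$bs, c(TRUE, FALSE)), do, "bs")))

  ccar_do <- mean_ci(cohort$ccar_pct[do], config$conf_level)
  ccar_nondo <- mean_ci(cohort$ccar_pct[!do], config$conf_level)
  ccar_t <- two_sample_t(cohort$ccar_pct[do], cohort$ccar_pct[!do])

  icc <- icc_interobserver(observer_ccar(cohort), config$conf_level)

  has_rr <- !is.na(cohort$rr_pct)
  cors <- list(
    ccar_rr_pearson = correlation_test(cohort$ccar_pct[has_rr],
                                       cohort$rr_pct[has_rr], "pearson"),
    ccar_rr_spearman = correlation_test(cohort$ccar_pct[has_rr],
                                        cohort$rr_pct[has_rr], "spearman"),
    ccar_do_pearson = correlation_test(cohort$ccar_pct, as.numeric(do),
                                       "pearson"),
    ccar_do_spearman = correlation_test(cohort$ccar_pct, as.numeric(do),
                                        "spearman"))
  cors <- lapply(cors, function(x) list(estimate = x$estimate, p = x$p.value,
                                        method = x$method))

  roc_do <- empirical_roc(cohort$ccar_pct, do, conf_level = config$conf_level,
                          ci_method = config$ci_method)
  poor_outcome <- cohort$rr_pct[has_rr] < config$rr_threshold
  roc_outcome <- if (any(poor_outcome) && !all(poor_outcome))
    empirical_roc(cohort$ccar_pct[has_rr], poor_outcome,
                  conf_level = config$conf_level,
                  ci_method = config$ci_method) else NULL

  perf_table <- function(scores, labels, cutoffs) {
    cutoffs <- cutoffs[is.finite(cutoffs)]
    do.call(rbind, lapply(cutoffs, function(cut) {
      p <- diagnostic_performance(scores, labels, cut,
                                  conf_level = config$conf_level)
      data.frame(cutoff = cut,
                 sensitivity = p$sensitivity$estimate,
                 sens_lower = p$sensitivity$ci_lower,
                 sens_upper = p$sensitivity$ci_upper,
                 specificity = p$specificity$estimate,
                 spec_lower = p$specificity$ci_lower,
                 spec_upper = p$specificity$ci_upper,
                 accuracy = p$accuracy$estimate,
                 TP = p$counts[["TP"]], FP = p$counts[["FP"]],
                 TN = p$counts[["TN"]], FN = p$counts[["FN"]])
    }))
  }
  zc_do <- zone_cutoffs(roc_do)
  do_performance <- perf_table(cohort$ccar_pct, do,
                               sort(unique(c(zc_do["lower"],
                                             roc_do$optimal_cutoff,
                                             zc_do["upper"]))))
  outcome_performance <- if (!is.null(roc_outcome)) {
    zc_o <- zone_cutoffs(roc_outcome)
    perf_table(cohort$ccar_pct[has_rr], poor_outcome,
               sort(unique(c(zc_o["lower"], roc_outcome$optimal_cutoff,
                             zc_o["upper"]))))
  } else NULL

  roc_summary <- function(r) if (is.null(r)) NULL else
    list(auc = r$auc, auc_ci = unname(r$auc_ci),
         optimal_cutoff = r$optimal_cutoff, youden_j = r$youden_j,
         n_pos = r$n_pos, n_neg = r$n_neg, ci_method = r$ci_method)

  structure(list(
    n = nrow(cohort), n_do = sum(do), n_nondo = sum(!do),
    demographics = demographics,
    categorical = categorical,
    ccar_by_group = list(
      do = ccar_do, nondo = ccar_nondo,
      t_statistic = ccar_t$statistic, p = ccar_t$p.value),
    icc = list(icc = icc$icc, ci = unname(icc$ci), model = icc$model),
    correlations = cors,
    roc_do = roc_summary(roc_do),
    roc_outcome = roc_summary(roc_outcome),
    do_performance = do_performance,
    outcome_performance = outcome_performance,
    config = unclass(config),
    seed = attr(cohort, "seed")
  ), class = "ccar_report")
}

#' @export
print.ccar_report <- function(x, ...) {
  cat(sprintf("CCAR analysis report: %d patients (%d DO / %d non-DO)\n",
              x$n, x$n_do, x$n_nondo))
  cat(sprintf("  CCAR: DO %.1f%% (%.1f-%.1f), non-DO %.1f%% (%.1f-%.1f), p %s\n",
              x$ccar_by_group$do$mean, x$ccar_by_group$do$ci_lower,
              x$ccar_by_group$do$ci_upper, x$ccar_by_group$nondo$mean,
              x$ccar_by_group$nondo$ci_lower, x$ccar_by_group$nondo$ci_upper,
              format_p(x$ccar_by_group$p)))
  cat(sprintf("  ICC(2,1) = %.3f (%.3f to %.3f)\n", x$icc$icc,
              x$icc$ci[1], x$icc$ci[2]))
  cat(sprintf("  DO ROC: AUC %.3f (%.3f to %.3f), cutoff %.1f%%\n",
              x$roc_do$auc, x$roc_do$auc_ci[1], x$roc_do$auc_ci[2],
              x$roc_do$optimal_cutoff))
  if (!is.null(x$roc_outcome))
    cat(sprintf("  Outcome ROC: AUC %.3f (%.3f to %.3f), cutoff %.1f%%\n",
                x$roc_outcome$auc, x$roc_outcome$auc_ci[1],
                x$roc_outcome$auc_ci[2], x$roc_outcome$optimal_cutoff))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' The report is a nested list of plain values, so serialization is
#' deterministic: rewriting the same report yields byte-identical output.
#'
#' @param report A `ccar_report`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ccar_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}
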