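#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the reference study conditions: a 52-patient thoracic OLF
#' cohort, 27 with intraoperative dural ossification (DO) and 25 without,
#' with group-level CCAR means 22.2% / 50.0%, mJOA and recovery-rate moments,
#' and per-group frequencies of the Sato morphologic types and the
#' tram-track / comma / bridge CT signs. Group CCAR SDs are back-computed
#' from the reported 95% CI half-widths via `sd = hw * sqrt(n) / t_{n-1,.975}`
#' (about 12.13 in the DO group from half-width 4.8, and 11.75 in the non-DO
#' group from half-width 4.85); they are derived defaults and can be
#' overridden.
#'
#' @param n_do,n_nondo Group sizes.
#' @param ccar_mean,ccar_sd Named numeric `c(do=, nondo=)`, percent.
#' @param scar_range Uniform range (percent) for the cord-occupancy ratio
#'   SCAR; its distribution is not constrained by group summaries, so a
#'   plausible cord/dural-sac occupancy band is assumed and exposed.
#' @param mjoa_pre_mean,mjoa_pre_sd Named `c(do=, nondo=)` preoperative mJOA.
#' @param rr_mean,rr_sd Named `c(do=, nondo=)` recovery rate, percent.
#' @param age_mean,age_sd Named `c(do=, nondo=)`, years.
#' @param followup_mean,followup_sd Named `c(do=, nondo=)`, years.
#' @param p_male Named `c(do=, nondo=)` probability of male sex.
#' @param segment_probs,sato_probs,sign_probs Per-group categorical
#'   probabilities (lists with `do` and `nondo` entries); sign probabilities
#'   are the maximum-likelihood estimates from the reference counts, and
#'   zero-count cells stay exactly zero.
#' @param canal_area_mean,canal_area_sd Normal bony-canal CSA distribution,
#'   mm^2 (truncated positive); drives the conversion of ratios to raw areas.
#' @param observer_cv Relative (multiplicative) measurement error per single
#'   measurement.
#' @param observer_bias Length-2 relative bias per observer (0 = unbiased).
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return List of class `ccar_cohort_params`.
#' @export
cohort_params <- function(
    n_do = 27L, n_nondo = 25L,
    ccar_mean = c(do = 22.2, nondo = 50.0),
    ccar_sd = c(do = sd_from_ci_halfwidth(4.8, 27),
                nondo = sd_from_ci_halfwidth(4.85, 25)),
    scar_range = c(15, 45),
    mjoa_pre_mean = c(do = 5.1, nondo = 5.7),
    mjoa_pre_sd = c(do = 3.0, nondo = 2.2),
    rr_mean = c(do = 42.3, nondo = 72.5),
    rr_sd = c(do = 32.5, nondo = 23.0),
    age_mean = c(do = 53.9, nondo = 57.4),
    age_sd = c(do = 9.6, nondo = 9.2),
    followup_mean = c(do = 4.6, nondo = 4.5),
    followup_sd = c(do = 2.3, nondo = 2.1),
    p_male = c(do = 10 / 27, nondo = 14 / 25),
    segment_probs = list(do = c(T1_T4 = 4, T5_T8 = 5, T9_T12 = 18) / 27,
                         nondo = c(T1_T4 = 4, T5_T8 = 3, T9_T12 = 18) / 25),
    sato_probs = list(
      do = c(lateral = 0, extended = 4, enlarged = 2, fused = 5,
             tuberous = 16) / 27,
      nondo = c(lateral = 12, extended = 5, enlarged = 4, fused = 4,
                tuberous = 0) / 25),
    sign_probs = list(do = c(tts = 8 / 27, cs = 9 / 27, bs = 6 / 27),
                      nondo = c(tts = 0, cs = 0, bs = 1 / 25)),
    canal_area_mean = 220, canal_area_sd = 30,
    observer_cv = 0.03, observer_bias = c(0, 0),
    seed = 1L) {
  p <- list(n_do = as.integer(n_do), n_nondo = as.integer(n_nondo),
            ccar_mean = ccar_mean, ccar_sd = ccar_sd, scar_range = scar_range,
            mjoa_pre_mean = mjoa_pre_mean, mjoa_pre_sd = mjoa_pre_sd,
            rr_mean = rr_mean, rr_sd = rr_sd,
            age_mean = age_mean, age_sd = age_sd,
            followup_mean = followup_mean, followup_sd = followup_sd,
            p_male = p_male, segment_probs = segment_probs,
            sato_probs = sato_probs, sign_probs = sign_probs,
            canal_area_mean = canal_area_mean, canal_area_sd = canal_area_sd,
            observer_cv = observer_cv, observer_bias = observer_bias,
            seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "ccar_cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n_do < 2L || p$n_nondo < 2L)
    stop("group sizes must be at least 2", call. = FALSE)
  if (any(p$ccar_sd <= 0) || any(p$mjoa_pre_sd <= 0) || any(p$rr_sd <= 0))
    stop("standard deviations must be positive", call. = FALSE)
  probs <- c(unlist(p$segment_probs), unlist(p$sato_probs),
             unlist(p$sign_probs), p$p_male)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  for (g in c("do", "nondo")) {
    for (nm in c("segment_probs", "sato_probs")) {
      if (abs(sum(p[[nm]][[g]]) - 1) > 1e-8)
        stop(sprintf("'%s$%s' must sum to 1", nm, g), call. = FALSE)
    }
  }
  if (p$observer_cv < 0) stop("'observer_cv' must be >= 0", call. = FALSE)
  if (length(p$scar_range) != 2L || p$scar_range[1] >= p$scar_range[2] ||
      p$scar_range[1] < 0)
    stop("'scar_range' must be an increasing non-negative pair", call. = FALSE)
  invisible(p)
}

#' Back-compute a standard deviation from a reported CI half-width
#'
#' Inverts `hw = t_{n-1, 1-alpha/2} * sd / sqrt(n)`, the relation between a
#' group SD and the half-width of the t-based CI of its mean.
#'
#' @param halfwidth CI half-width.
#' @param n Group size.
#' @param conf_level Confidence level of the reported interval.
#' @return The implied SD.
#' @export
sd_from_ci_halfwidth <- function(halfwidth, n, conf_level = 0.95) {
  halfwidth * sqrt(n) / stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
}

# inverse-CDF sampler for a truncated normal (exact, no rejection)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Simulate repeated observer measurements of true areas
#'
#' Two observers each measure every area twice. Each single measurement is
#' `true * (1 + bias_obs) * exp(e)`, with `e ~ N(-sigma^2/2, sigma^2)` and
#' `sigma^2 = log(1 + cv^2)`, i.e. multiplicative log-normal noise with unit
#' mean at the requested coefficient of variation, plus a fixed relative bias
#' per observer. With `cv = 0` and zero bias every measurement equals the
#' truth exactly.
#'
#' @param true_areas Numeric vector or matrix of true areas (mm^2).
#' @param cv Coefficient of variation of a single measurement (>= 0).
#' @param bias_per_observer Length-2 numeric, relative bias of each observer.
#' @param seed Optional seed; `NULL` (default) draws from the current RNG
#'   stream so the caller controls reproducibility.
#' @return Named list `o1r1`, `o1r2`, `o2r1`, `o2r2`, each shaped like
#'   `true_areas`.
#' @export
simulate_observers <- function(true_areas, cv = 0.03,
                               bias_per_observer = c(0, 0), seed = NULL) {
  if (!is.numeric(true_areas) || anyNA(true_areas) || any(true_areas < 0))
    stop("'true_areas' must be non-negative numeric", call. = FALSE)
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  if (length(bias_per_observer) != 2L)
    stop("'bias_per_observer' must have length 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(log(1 + cv^2))
  one <- function(obs) {
    noise <- if (sigma == 0) 1 else
      exp(stats::rnorm(length(true_areas), -sigma^2 / 2, sigma))
    out <- true_areas * (1 + bias_per_observer[obs]) * noise
    if (!is.null(dim(true_areas))) dim(out) <- dim(true_areas)
    out
  }
  list(o1r1 = one(1L), o1r2 = one(1L), o2r1 = one(2L), o2r2 = one(2L))
}

#' Generate a synthetic patient cohort
#'
#' Draws one cohort under the study conditions in `params`, deterministic
#' given the seed. Per group: the true CCAR is normal truncated to
#' \[0, 100\]; SCAR is uniform on `scar_range` and OCAR is set to
#' `100 - SCAR - CCAR` (resampled on a negative implied OCAR, bounded
#' retries), so the three ratios sum to 100 exactly by construction. A
#' sampled canal area converts the ratios into the five raw structure areas
#' (the reference dural sac is taken equal to the normal canal, split into
#' adjacent upper/lower areas with a small random asymmetry), and
#' [simulate_observers()] produces the 2 observers x 2 repeats measurement
#' columns. The recovery rate is drawn truncated to at most 100, the
#' follow-up mJOA back-computed as `pre + RR (11 - pre) / 100` rounded to the
#' nearest integer and clamped to `[max(0, pre - 1), 11]`; negative drawn RR
#' (postoperative deterioration) is allowed. Signs, Sato type, compression
#' segment, sex and age are sampled from the per-group distributions; they
#' feed no downstream formula and exist for schema realism.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return Data frame, one row per patient, in the cohort schema (see
#'   [load_cohort()]), with attributes `params`, `seed`, and `truth` (a data
#'   frame of the latent true ratios, areas and RR).
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  validate_cohort_params(params)
  set.seed(as.integer(seed))
  grp <- function(g, n, do_status) {
    ccar_t <- numeric(n)
    scar_t <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (iter in seq_len(1000L)) {
        ci <- rtrunc_norm(1L, params$ccar_mean[g], params$ccar_sd[g], 0, 100)
        hi <- min(params$scar_range[2], 100 - ci)
        if (hi < params$scar_range[1]) next # CCAR leaves no room for SCAR
        si <- stats::runif(1L, params$scar_range[1], hi)
        ccar_t[i] <- ci; scar_t[i] <- si; ok <- TRUE
        break
      }
      if (!ok) stop("infeasible CCAR/SCAR decomposition after bounded retries",
                    call. = FALSE)
    }
    ocar_t <- 100 - scar_t - ccar_t

    canal_t <- rtrunc_norm(n, params$canal_area_mean, params$canal_area_sd,
                           100, Inf)
    dural_ref_t <- canal_t # reference sac assumed equal to the normal canal
    asym <- stats::runif(n, -0.05, 0.05)
    mass_t <- ocar_t / 100 * canal_t
    cord_t <- scar_t / 100 * dural_ref_t

    mjoa_pre <- as.integer(round(rtrunc_norm(n, params$mjoa_pre_mean[g],
                                             params$mjoa_pre_sd[g], 0, 10)))
    rr_t <- rtrunc_norm(n, params$rr_mean[g], params$rr_sd[g], -Inf, 100)
    mjoa_fu <- as.integer(pmin(11, pmax(pmax(mjoa_pre - 1L, 0L),
                                        round(mjoa_pre + rr_t * (11 - mjoa_pre) / 100))))

    sp <- params$sign_probs[[g]]
    truth <- data.frame(
      ccar_true = ccar_t, scar_true = scar_t, ocar_true = ocar_t,
      canal_true = canal_t, dural_ref_true = dural_ref_t,
      mass_true = mass_t, cord_true = cord_t, rr_true = rr_t)
    rec <- data.frame(
      sex = ifelse(stats::runif(n) < params$p_male[g], "male", "female"),
      age_yr = round(rtrunc_norm(n, params$age_mean[g], params$age_sd[g],
                                 25, 85)),
      do_status = do_status,
      segment = sample(names(params$segment_probs[[g]]), n, replace = TRUE,
                       prob = params$segment_probs[[g]]),
      sato_type = sample(names(params$sato_probs[[g]]), n, replace = TRUE,
                         prob = params$sato_probs[[g]]),
      tts = stats::runif(n) < sp["tts"],
      cs = stats::runif(n) < sp["cs"],
      bs = stats::runif(n) < sp["bs"],
      mjoa_pre = mjoa_pre, mjoa_fu = mjoa_fu,
      followup_yr = round(rtrunc_norm(n, params$followup_mean[g],
                                      params$followup_sd[g], 0.5, Inf), 1))

    true_areas <- cbind(canal_ct = canal_t, mass_ct = mass_t,
                        dural_upper_mri = dural_ref_t * (1 + asym),
                        dural_lower_mri = dural_ref_t * (1 - asym),
                        cord_mri = cord_t)
    meas <- simulate_observers(true_areas, cv = params$observer_cv,
                               bias_per_observer = params$observer_bias)
    for (rep_id in names(meas)) {
      m <- meas[[rep_id]]
      colnames(m) <- paste0(colnames(true_areas), "_", rep_id, "_mm2")
      rec <- cbind(rec, as.data.frame(m))
    }
    list(rec = rec, truth = truth)
  }

  gdo <- grp("do", params$n_do, TRUE)
  gnd <- grp("nondo", params$n_nondo, FALSE)
  cohort <- rbind(gdo$rec, gnd$rec)
  cohort <- cbind(id = sprintf("P%03d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  truth <- rbind(gdo$truth, gnd$truth)
  rownames(truth) <- NULL
  attr(cohort, "params") <- params
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "truth") <- truth
  cohort
}
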