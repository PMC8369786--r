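#' Cohort table schema
#'
#' The cohort CSV is UTF-8, comma-separated, header row, "." decimal, with
#' units embedded in column names. Columns: `id` (unique), `sex`
#' (male/female), `age_yr`, `do_status` (intraoperative ground truth,
#' TRUE/FALSE or 0/1), `segment` (T1_T4 / T5_T8 / T9_T12), `sato_type`
#' (lateral / extended / enlarged / fused / tuberous), `tts`, `cs`, `bs`
#' (sign labels, logical), `mjoa_pre`, `mjoa_fu` (integers 0-11),
#' `followup_yr`, and the twenty raw area columns
#' `<site>_<o1r1|o1r2|o2r1|o2r2>_mm2` for the five sites `canal_ct`,
#' `mass_ct`, `dural_upper_mri`, `dural_lower_mri`, `cord_mri`.
#'
#' @return Character vector of required column names.
#' @export
cohort_columns <- function() {
  c("id", "sex", "age_yr", "do_status", "segment", "sato_type",
    "tts", "cs", "bs", "mjoa_pre", "mjoa_fu", "followup_yr", area_columns())
}

#' @rdname cohort_columns
#' @export
area_columns <- function() {
  sites <- c("canal_ct", "mass_ct", "dural_upper_mri", "dural_lower_mri",
             "cord_mri")
  as.vector(t(outer(sites, c("o1r1", "o1r2", "o2r1", "o2r2"),
                    function(s, r) paste0(s, "_", r, "_mm2"))))
}

check_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(cohort)
}

#' Load a cohort CSV with validation
#'
#' Reads and validates a cohort table (schema in [cohort_columns()]).
#' Structural problems — a missing required column, duplicate ids, an empty
#' file — are errors. Row-level problems (mJOA outside 0-11 or non-integer,
#' negative or missing areas) reject only the offending rows, with one
#' warning per problem naming the row ids, so one bad record does not block
#' a cohort.
#'
#' @param path Path to the CSV file.
#' @return Validated cohort data frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cohort <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                     error = function(e)
                       stop("schema error: unparseable or empty CSV: ",
                            conditionMessage(e), call. = FALSE))
  if (nrow(cohort) == 0L) stop("schema error: no data rows", call. = FALSE)
  check_cohort(cohort)
  if (anyDuplicated(cohort$id))
    stop("integrity error: duplicate patient id(s): ",
         paste(unique(cohort$id[duplicated(cohort$id)]), collapse = ", "),
         call. = FALSE)
  for (col in c("do_status", "tts", "cs", "bs"))
    cohort[[col]] <- as.logical(cohort[[col]])

  bad <- rep(FALSE, nrow(cohort))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond))
      warning(sprintf("rejected row(s) %s: %s",
                      paste(cohort$id[cond], collapse = ", "), why),
              call. = FALSE)
    bad <<- bad | cond
  }
  for (col in c("mjoa_pre", "mjoa_fu")) {
    v <- cohort[[col]]
    flag(!is.numeric(v) | is.na(v) | v != round(v) | v < 0 | v > 11,
         paste0(col, " outside the integer 11-point scale [0, 11]"))
  }
  amat <- as.matrix(cohort[, area_columns()])
  flag(rowSums(is.na(amat) | amat < 0) > 0, "negative or missing area")
  flag(is.na(cohort$do_status), "do_status not interpretable as logical")
  cohort <- cohort[!bad, , drop = FALSE]
  if (nrow(cohort) == 0L)
    stop("schema error: every row was rejected", call. = FALSE)
  rownames(cohort) <- NULL
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort[, union(cohort_columns(),
                                  intersect(names(cohort),
                                            score_columns()))],
                   path, row.names = FALSE)
  invisible(path)
}

score_columns <- function() {
  c("ocar_pct", "scar_pct", "ccar_pct", "ccar_flag", "rr_pct", "rr_grade",
    "ccar_zone", "outcome_zone")
}
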