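#' Construct a longitudinal cohort object
#'
#' A cohort couples a baseline table (one row per subject) with a visit table
#' (one row per subject-visit, holding the longitudinal outcomes). Time is
#' coded as the visit number in units of 6 months: months 0, 6, 12, 18, 24
#' and 36 are visit numbers 0, 1, 2, 3, 4 and 6 (there is no month-30 visit).
#'
#' @param baselines tibble with columns `subject_id`, `age`, `gender`
#'   (`"female"`/`"male"`), `education`, `bmi`, `apoe4` (0/1/2), `hachinski`
#'   (0-12), `faq` (0-50), `mmse` (0-30), `adascog_bl` (0-85), `npbatt_bl`,
#'   and optionally `csf_ratio` (> 0) and `on_medication`.
#' @param visits tibble with columns `subject_id`, `visit_number` and at least
#'   one of `adascog`, `npbatt` non-missing per row.
#' @return an object of class `pgsa_cohort`.
#' @export
cohort <- function(baselines, visits) {
  out <- structure(list(baselines = as_tibble(baselines),
                        visits = as_tibble(visits)),
                   class = "pgsa_cohort")
  validate_cohort(out)
}

#' @export
print.pgsa_cohort <- function(x, ...) {
  cat(sprintf("<pgsa cohort: %d subjects, %d visit records>\n",
              nrow(x$baselines), nrow(x$visits)))
  vn <- sort(unique(x$visits$visit_number))
  cat("  visits (6-month units):", paste(vn, collapse = ", "), "\n")
  cat("  outcomes: ",
      paste(intersect(c("adascog", "npbatt"), names(x$visits)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

check_range <- function(x, lo, hi, field, where, problems) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "%s row %d: %s = %s outside [%s, %s]", where, bad, field,
      format(x[bad]), format(lo), format(hi)))
  }
  problems
}

#' Validate a cohort against the schema invariants
#'
#' Checks score ranges (ADAS-cog 0-85, MMSE 0-30, FAQ 0-50, Hachinski 0-12,
#' ApoE4 allele count in 0/1/2), positivity of age, BMI and the CSF ratio,
#' legality of visit numbers, uniqueness of subject ids and of
#' (subject, visit) pairs, and that every visit resolves to a baseline record.
#' Aborts with a per-row report when any invariant is violated.
#'
#' @param x a `pgsa_cohort`.
#' @return `x`, invisibly usable, after validation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "pgsa_cohort"))
  b <- x$baselines
  v <- x$visits
  problems <- character()

  need_b <- c("subject_id", "age", "gender", "education", "bmi", "apoe4",
              "hachinski", "faq", "mmse", "adascog_bl", "npbatt_bl")
  miss <- setdiff(need_b, names(b))
  if (length(miss)) {
    abort(paste("schema error: baselines lack column(s)",
                paste(miss, collapse = ", ")))
  }
  need_v <- c("subject_id", "visit_number")
  miss <- setdiff(need_v, names(v))
  if (length(miss)) {
    abort(paste("schema error: visits lack column(s)",
                paste(miss, collapse = ", ")))
  }

  if (anyDuplicated(b$subject_id)) {
    problems <- c(problems, paste("integrity: duplicated subject_id in baselines:",
      paste(unique(b$subject_id[duplicated(b$subject_id)]), collapse = ", ")))
  }
  key <- paste(v$subject_id, v$visit_number)
  if (anyDuplicated(key)) {
    problems <- c(problems, paste("integrity: duplicated (subject, visit):",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  orphan <- setdiff(v$subject_id, b$subject_id)
  if (length(orphan)) {
    problems <- c(problems, paste("integrity: visits for unknown subject(s):",
                                  paste(orphan, collapse = ", ")))
  }

  problems <- check_range(b$apoe4, 0, 2, "apoe4", "baseline", problems)
  nonint <- which(!is.na(b$apoe4) & b$apoe4 != round(b$apoe4))
  if (length(nonint)) {
    problems <- c(problems,
                  sprintf("baseline row %d: apoe4 must be an integer count", nonint))
  }
  problems <- check_range(b$adascog_bl, 0, ADAS_MAX, "adascog_bl", "baseline", problems)
  problems <- check_range(b$mmse, 0, 30, "mmse", "baseline", problems)
  problems <- check_range(b$faq, 0, 50, "faq", "baseline", problems)
  problems <- check_range(b$hachinski, 0, 12, "hachinski", "baseline", problems)
  problems <- check_range(b$age, 1e-9, Inf, "age", "baseline", problems)
  problems <- check_range(b$bmi, 1e-9, Inf, "bmi", "baseline", problems)
  if ("csf_ratio" %in% names(b)) {
    problems <- check_range(b$csf_ratio, 1e-12, Inf, "csf_ratio", "baseline", problems)
  }

  badv <- which(!v$visit_number %in% LEGAL_VISITS)
  if (length(badv)) {
    problems <- c(problems, sprintf(
      "visit row %d: visit_number = %s not in {%s}", badv,
      v$visit_number[badv], paste(LEGAL_VISITS, collapse = ", ")))
  }
  if ("adascog" %in% names(v)) {
    problems <- check_range(v$adascog, 0, ADAS_MAX, "adascog", "visit", problems)
  }
  has_outcome <- rep(FALSE, nrow(v))
  for (oc in intersect(c("adascog", "npbatt"), names(v))) {
    has_outcome <- has_outcome | !is.na(v[[oc]])
  }
  if (nrow(v) && !all(has_outcome)) {
    problems <- c(problems, sprintf(
      "visit row %d: no outcome (adascog or npbatt) present", which(!has_outcome)))
  }

  if (length(problems)) {
    abort(paste0("cohort validation failed:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  x
}

COHORT_COLS <- c("subject_id", "visit_month", "age", "gender", "education_years",
                 "bmi", "apoe4", "hachinski", "faq", "mmse", "adascog", "npbatt",
                 "csf_ab42_ttau", "medication")

#' Read a cohort file
#'
#' Reads a delimited subject-visit table into a validated [cohort()]. The file
#' has one row per subject-visit with columns `subject_id, visit_month, age,
#' gender, education_years, bmi, apoe4, hachinski, faq, mmse, adascog, npbatt`
#' and optionally `csf_ab42_ttau` and `medication`. Baseline covariates may be
#' repeated on every row or given only on the `visit_month = 0` row; both
#' dialects are accepted. Visit months are mapped to visit numbers in 6-month
#' units (month 36 is visit 6; month 30 is not a legal visit).
#'
#' @param file path to a delimited text file.
#' @param coding a [coding_config()] (kept for downstream encoding; the raw
#'   covariates are stored unencoded).
#' @param delim field delimiter, comma by default.
#' @return a `pgsa_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(file, coding = coding_config(), delim = ",") {
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  mandatory <- setdiff(COHORT_COLS, c("csf_ab42_ttau", "medication"))
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    abort(paste("schema error: missing mandatory column(s):",
                paste(miss, collapse = ", ")))
  }
  badm <- which(!raw$visit_month %in% LEGAL_MONTHS)
  if (length(badm)) {
    abort(paste0("validation error:\n  ", paste(sprintf(
      "row %d: visit_month = %s not in {%s}", badm, raw$visit_month[badm],
      paste(LEGAL_MONTHS, collapse = ", ")), collapse = "\n  ")))
  }
  raw$visit_number <- as.integer(raw$visit_month) %/% 6L

  bl <- raw[raw$visit_number == 0L, ]
  if (anyDuplicated(bl$subject_id)) {
    abort("integrity error: duplicated baseline (visit_month 0) rows")
  }
  missing_bl <- setdiff(unique(raw$subject_id), bl$subject_id)
  if (length(missing_bl)) {
    abort(paste("integrity error: subject(s) without a visit_month 0 row:",
                paste(missing_bl, collapse = ", ")))
  }
  baselines <- tibble(
    subject_id = as.character(bl$subject_id),
    age = bl$age, gender = as.character(bl$gender),
    education = bl$education_years, bmi = bl$bmi, apoe4 = bl$apoe4,
    hachinski = bl$hachinski, faq = bl$faq, mmse = bl$mmse,
    adascog_bl = bl$adascog, npbatt_bl = bl$npbatt
  )
  if ("csf_ab42_ttau" %in% names(raw)) {
    baselines$csf_ratio <- bl$csf_ab42_ttau
  }
  if ("medication" %in% names(raw)) {
    baselines$on_medication <- as.logical(bl$medication)
  }

  visits <- tibble(
    subject_id = as.character(raw$subject_id),
    visit_number = raw$visit_number,
    adascog = raw$adascog, npbatt = raw$npbatt
  )
  visits <- visits[!is.na(visits$adascog) | !is.na(visits$npbatt), ]
  cohort(baselines, visits)
}

#' Write a cohort file
#'
#' Writes the canonical dialect: one row per subject-visit with baseline
#' covariates repeated on every row. `read_cohort(write_cohort(x, f))` is
#' lossless for valid cohorts.
#'
#' @param x a `pgsa_cohort`.
#' @param file output path.
#' @param delim field delimiter.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(x, file, delim = ",") {
  stopifnot(inherits(x, "pgsa_cohort"))
  b <- x$baselines
  v <- x$visits
  if (!"adascog" %in% names(v)) v$adascog <- NA_real_
  if (!"npbatt" %in% names(v)) v$npbatt <- NA_real_
  # every subject gets a visit-0 row carrying the baseline scores, so the
  # file round-trips regardless of which outcomes were simulated
  no_v0 <- setdiff(b$subject_id, v$subject_id[v$visit_number == 0L])
  if (length(no_v0)) {
    v <- dplyr::bind_rows(v, tibble(subject_id = no_v0, visit_number = 0L,
                                    adascog = NA_real_, npbatt = NA_real_))
  }
  at0 <- v$visit_number == 0L
  idx <- match(v$subject_id[at0], b$subject_id)
  v$adascog[at0] <- dplyr::coalesce(v$adascog[at0], b$adascog_bl[idx])
  v$npbatt[at0] <- dplyr::coalesce(v$npbatt[at0], b$npbatt_bl[idx])
  out <- dplyr::left_join(v, b, by = "subject_id")
  out <- tibble(
    subject_id = out$subject_id,
    visit_month = out$visit_number * 6L,
    age = out$age, gender = out$gender, education_years = out$education,
    bmi = out$bmi, apoe4 = out$apoe4, hachinski = out$hachinski,
    faq = out$faq, mmse = out$mmse, adascog = out$adascog, npbatt = out$npbatt,
    csf_ab42_ttau = if ("csf_ratio" %in% names(b)) out$csf_ratio else NA_real_,
    medication = if ("on_medication" %in% names(b)) {
      as.integer(out$on_medication)
    } else {
      NA_integer_
    }
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$visit_month)
  readr::write_delim(out, file, delim = delim, na = "")
  invisible(file)
}
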