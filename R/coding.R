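#' Covariate coding configuration
#'
#' Controls how raw baseline covariates are turned into model design values:
#' which gender is the reference (indicator 0), the body-mass-index class
#' cutoffs, and which BMI class defines the binary obesity flag.
#'
#' The BMI classes are `<25`, `25 to <30` and `>=30` kg/m2 by default; the
#' obesity flag marks the third class. The gender indicator is 1 for female
#' with a male reference by default; published coefficient tables rarely state
#' the reference level, so it is configurable here.
#'
#' @param gender_reference gender mapped to indicator 0 (`"male"` or
#'   `"female"`).
#' @param bmi_cutoffs two strictly increasing thresholds (kg/m2) splitting BMI
#'   into three classes.
#' @param obesity_definition which BMI class the binary obesity flag marks:
#'   `"bmi3"` (the top class, default) or `"bmi2_or_3"` (at or above the first
#'   cutoff).
#' @return an object of class `pgsa_coding`.
#' @examples
#' coding_config()
#' @export
coding_config <- function(gender_reference = c("male", "female"),
                          bmi_cutoffs = c(25, 30),
                          obesity_definition = c("bmi3", "bmi2_or_3")) {
  gender_reference <- match.arg(gender_reference)
  obesity_definition <- match.arg(obesity_definition)
  if (length(bmi_cutoffs) != 2L || diff(bmi_cutoffs) <= 0) {
    abort("bmi_cutoffs must be two strictly increasing thresholds")
  }
  structure(
    list(gender_reference = gender_reference,
         bmi_cutoffs = as.numeric(bmi_cutoffs),
         obesity_definition = obesity_definition),
    class = "pgsa_coding"
  )
}

#' @export
print.pgsa_coding <- function(x, ...) {
  cat("<pgsa covariate coding>\n")
  cat("  gender indicator: 1 =", setdiff(c("female", "male"), x$gender_reference),
      "(reference:", paste0(x$gender_reference, ")\n"))
  cat(sprintf("  BMI classes: <%g, %g to <%g, >=%g kg/m2\n",
              x$bmi_cutoffs[1], x$bmi_cutoffs[1], x$bmi_cutoffs[2], x$bmi_cutoffs[2]))
  cat("  obesity flag:", if (x$obesity_definition == "bmi3") {
    sprintf("BMI >= %g", x$bmi_cutoffs[2])
  } else {
    sprintf("BMI >= %g", x$bmi_cutoffs[1])
  }, "\n")
  invisible(x)
}

#' Encode baseline covariates as model design values
#'
#' Expands a baseline table into the numeric design values the PGSA models
#' use: a 0/1 gender indicator, the ApoE4 allele count as a numeric 0/1/2
#' predictor (two alleles approximately double the effect of one, so the
#' count enters linearly), BMI class dummies `bmi2`/`bmi3` with the lowest
#' class as reference, a binary `obesity` flag, and pass-through continuous
#' covariates. Baseline scores are renamed with a `_bl` suffix
#' (`faq_bl`, `mmse_bl`, `adascog_bl`, `npbatt_bl`).
#'
#' @param baselines a data frame with one row per subject; see
#'   [generate_baseline()] or [read_cohort()] for the schema.
#' @param coding a [coding_config()].
#' @return a tibble with one row per subject and only numeric design columns
#'   (plus `subject_id`).
#' @examples
#' bl <- generate_baseline(5, seed = 1)
#' encode_covariates(bl)
#' @export
encode_covariates <- function(baselines, coding = coding_config()) {
  stopifnot(inherits(coding, "pgsa_coding"))
  b <- as_tibble(baselines)
  need <- c("subject_id", "age", "gender", "education", "bmi", "apoe4",
            "hachinski", "faq", "mmse", "adascog_bl", "npbatt_bl")
  missing_cols <- setdiff(need, names(b))
  if (length(missing_cols)) {
    abort(paste("baselines lack required columns:",
                paste(missing_cols, collapse = ", ")))
  }
  g <- as.character(b$gender)
  if (!all(g %in% c("female", "male"))) {
    abort("gender must be 'female' or 'male'")
  }
  cut1 <- coding$bmi_cutoffs[1]
  cut2 <- coding$bmi_cutoffs[2]
  bmi2 <- as.numeric(b$bmi >= cut1 & b$bmi < cut2)
  bmi3 <- as.numeric(b$bmi >= cut2)
  obesity <- if (coding$obesity_definition == "bmi3") bmi3 else pmax(bmi2, bmi3)
  tibble(
    subject_id = b$subject_id,
    gender = as.numeric(g != coding$gender_reference),
    age = as.numeric(b$age),
    education = as.numeric(b$education),
    bmi2 = bmi2,
    bmi3 = bmi3,
    obesity = obesity,
    apoe4 = as.numeric(b$apoe4),
    hachinski = as.numeric(b$hachinski),
    faq_bl = as.numeric(b$faq),
    mmse_bl = as.numeric(b$mmse),
    adascog_bl = as.numeric(b$adascog_bl),
    npbatt_bl = as.numeric(b$npbatt_bl),
    csf_ratio = if ("csf_ratio" %in% names(b)) as.numeric(b$csf_ratio) else NA_real_
  )
}

# ---- design-matrix helpers (internal) ---------------------------------------

canon_term <- function(term) {
  vapply(term, function(tm) {
    if (tm == "(Intercept)") return(tm)
    paste(sort(strsplit(tm, ":", fixed = TRUE)[[1]]), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

safe_name <- function(term) {
  ifelse(term == "(Intercept)", ".intercept", gsub(":", "_x_", term, fixed = TRUE))
}

term_parents <- function(term) {
  strsplit(term, ":", fixed = TRUE)[[1]]
}

is_interaction <- function(term) grepl(":", term, fixed = TRUE)

# Build the design matrix for canonical terms from an encoded covariate table
# (plus, for longitudinal models, a `visit` time column).
build_design <- function(encoded, terms) {
  cols <- lapply(terms, function(tm) {
    if (tm == "(Intercept)") return(rep(1, nrow(encoded)))
    parts <- term_parents(tm)
    missing_parts <- setdiff(parts, names(encoded))
    if (length(missing_parts)) {
      abort(paste0("cannot build term '", tm, "': missing covariate(s) ",
                   paste(missing_parts, collapse = ", ")))
    }
    Reduce(`*`, lapply(parts, function(p) as.numeric(encoded[[p]])))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  if (anyNA(X)) {
    abort("design matrix contains missing values; check required covariates")
  }
  X
}
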