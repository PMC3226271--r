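# Small deterministic fixtures built in code.

# A hand-written two-subject cohort table covering both outcome types.
tiny_cohort_file <- function(path = tempfile(fileext = ".csv")) {
  lines <- c(
    "subject_id,visit_month,age,gender,education_years,bmi,apoe4,hachinski,faq,mmse,adascog,npbatt,csf_ab42_ttau,medication",
    "A,0,74.2,female,16,26.1,1,1,2,27,18.6,-1.02,1.564,1",
    "A,6,74.2,female,16,26.1,1,1,2,27,20.0,-1.10,1.564,1",
    "A,24,74.2,female,16,26.1,1,1,2,27,24.5,-1.40,1.564,1",
    "B,0,68.0,male,12,31.0,0,0,0,29,10.0,-0.20,,0",
    "B,6,68.0,male,12,31.0,0,0,0,29,11.0,-0.35,,0",
    "B,36,68.0,male,12,31.0,0,0,0,29,15.0,-0.80,,0"
  )
  writeLines(lines, path)
  path
}

# Baseline tibble with fully controlled covariates (one row per subject).
make_baselines <- function(n = 1, age = 74.2, gender = "female",
                           education = 16, bmi = 26.1, apoe4 = 1,
                           hachinski = 1, faq = 2, mmse = 27,
                           adascog_bl = 18.6, npbatt_bl = -1.02,
                           csf_ratio = NA_real_) {
  tibble::tibble(
    subject_id = sprintf("T%04d", seq_len(n)),
    age = age, gender = gender, education = education, bmi = bmi,
    apoe4 = apoe4, hachinski = hachinski, faq = faq, mmse = mmse,
    adascog_bl = adascog_bl, npbatt_bl = npbatt_bl, csf_ratio = csf_ratio
  )
}

# A trajectory fit with modified variance components (for noise-free limits).
modified_trajectory_fit <- function(fit = pgsa_example_fit("trajectory"),
                                    sd_intercept = NULL, sd_slope = NULL,
                                    cor = NULL, sigma_w = NULL,
                                    zero_vcov = FALSE) {
  if (!is.null(sd_intercept)) fit$ranef$sd_intercept <- sd_intercept
  if (!is.null(sd_slope)) fit$ranef$sd_slope <- sd_slope
  if (!is.null(cor)) fit$ranef$cor <- cor
  if (!is.null(sigma_w)) fit$sigma_w <- sigma_w
  if (zero_vcov) fit$vcov[] <- 0
  fit
}

zero_vcov_endpoint <- function(fit = pgsa_example_fit("endpoint"),
                               sigma = NULL) {
  fit$vcov[] <- 0
  if (!is.null(sigma)) fit$sigma <- sigma
  fit
}
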