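#' Write a fitted-model artifact
#'
#' Serializes an endpoint or trajectory fit as a structured JSON document:
#' term names and coefficients, the parameter covariance matrix, the residual
#' (or within-subject) SD, the transform or time coding, the covariate
#' coding, and a provenance block.
#'
#' @param fit a `pgsa_endpoint_fit` or `pgsa_trajectory_fit`.
#' @param path output path.
#' @param seed optional seed to record in the provenance block.
#' @return `path`, invisibly.
#' @seealso [read_model_artifact()]
#' @export
write_model_artifact <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "pgsa_fit"))
  type <- if (inherits(fit, "pgsa_endpoint_fit")) "endpoint" else "trajectory"
  doc <- list(
    type = type,
    terms = fit$terms,
    coefficients = as.list(setNames(unname(fit$coefficients), fit$terms)),
    vcov = unname(apply(fit$vcov, 1, as.list)),
    coding = unclass(fit$coding),
    provenance = list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package = paste0("pgsa ", as.character(packageVersion("pgsa"))),
      seed = seed
    )
  )
  if (type == "endpoint") {
    doc$residual_sd <- fit$sigma
    doc$transform <- fit$transform
    doc$n <- fit$n
    doc$provenance$n <- fit$n
  } else {
    doc$ranef <- fit$ranef
    doc$within_sd <- fit$sigma_w
    doc$time_unit <- fit$time_unit
    doc$n_subjects <- fit$n_subjects
    doc$provenance$n <- fit$n_subjects
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a fitted-model artifact
#'
#' @param path path to a JSON artifact written by [write_model_artifact()]
#'   (or a packaged fixture; see [pgsa_example_fit()]).
#' @return a `pgsa_endpoint_fit` or `pgsa_trajectory_fit`.
#' @export
read_model_artifact <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- doc$terms
  beta <- setNames(as.numeric(unlist(doc$coefficients[terms])), terms)
  V <- matrix(unlist(doc$vcov), nrow = length(terms), byrow = TRUE,
              dimnames = list(terms, terms))
  if (max(abs(V - t(V))) > 1e-10 * max(abs(V), 1)) {
    abort("artifact covariance matrix is not symmetric")
  }
  coding <- coding_config(
    gender_reference = doc$coding$gender_reference,
    bmi_cutoffs = as.numeric(doc$coding$bmi_cutoffs),
    obesity_definition = doc$coding$obesity_definition
  )
  if (identical(doc$type, "endpoint")) {
    structure(
      list(terms = terms, coefficients = beta, vcov = V,
           sigma = as.numeric(doc$residual_sd), n = doc$n,
           transform = doc$transform, coding = coding,
           r_squared = NA_real_, aic = NA_real_,
           selection_trace = "read from artifact"),
      class = c("pgsa_endpoint_fit", "pgsa_fit")
    )
  } else if (identical(doc$type, "trajectory")) {
    r <- doc$ranef
    if (r$sd_intercept <= 0 || r$sd_slope < 0 || abs(r$cor) > 1) {
      abort("artifact random effects are out of range")
    }
    structure(
      list(terms = terms, coefficients = beta, vcov = V,
           ranef = list(sd_intercept = r$sd_intercept,
                        sd_slope = r$sd_slope, cor = r$cor),
           sigma_w = as.numeric(doc$within_sd), time_unit = doc$time_unit,
           n_subjects = doc$n_subjects, n_obs = NA_integer_,
           slope_lrt = NULL, singular = FALSE, coding = coding,
           selection_trace = "read from artifact"),
      class = c("pgsa_trajectory_fit", "pgsa_fit")
    )
  } else {
    abort(paste("unknown artifact type:", doc$type))
  }
}

#' Packaged reference model fits
#'
#' Ready-made model artifacts with the published coefficient tables from the
#' ADNI MCI analyses, for use as data-generating truths and virtual-placebo
#' engines without access to the source data:
#' * `"endpoint"` — the month-24 sqrt-ADAS-cog regression (n = 286; residual
#'   SD 0.669).
#' * `"trajectory"` — the NP-Batt random-intercept/slope model (375 subjects).
#' * `"trajectory-csf"` — the variant adding the CSF Ab42/T-tau ratio
#'   (189 subjects).
#'
#' The published tables print standard errors but not the full parameter
#' covariance, so each fixture's covariance matrix is the diagonal of squared
#' standard errors — a synthetic approximation that overstates
#' replicate-level dispersion of simulated group means (the true covariance
#' has substantial negative off-diagonals). Set the matrix yourself, or pass
#' `parameter_uncertainty = FALSE` to the simulators, where this matters.
#'
#' @param which one of `"endpoint"`, `"trajectory"`, `"trajectory-csf"`.
#' @return the corresponding fit object.
#' @examples
#' pgsa_example_fit("endpoint")
#' @export
pgsa_example_fit <- function(which = c("endpoint", "trajectory",
                                       "trajectory-csf")) {
  which <- match.arg(which)
  file <- c("endpoint" = "endpoint-adas24-mci.json",
            "trajectory" = "trajectory-npbatt-mci.json",
            "trajectory-csf" = "trajectory-npbatt-mci-csf.json")[[which]]
  read_model_artifact(system.file("extdata", file, package = "pgsa",
                                  mustWork = TRUE))
}
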