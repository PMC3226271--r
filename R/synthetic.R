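#' Marginal distributions for the synthetic MCI cohort
#'
#' Defaults emulate the published baseline table of the ADNI MCI cohort
#' (n = 397): age N(74.2, 7.4); 36% women; education N(15.7, 3.0) truncated
#' to 0-20; BMI N(26.1, 4.0) truncated above 15; ApoE4 allele counts with
#' probabilities 185/397, 165/397, 47/397; modified Hachinski and FAQ as
#' right-skewed truncated negative-binomial counts matched to the printed
#' medians (1 and 2) and ranges (0-4, 0-21); MMSE N(27.0, 1.8) truncated to
#' the MCI inclusion window 24-30 and rounded to integers; modified ADAS-cog
#' N(18.6, 6.3) truncated to 0-85; NP-Batt N(-1.02, 0.66); CSF Ab42/T-tau
#' log-normal with median 1.564 (sdlog 0.6, matching the printed range) in a
#' configurable subsample (about half the cohort underwent lumbar puncture);
#' medication use 60%.
#'
#' @param ... named overrides; each entry replaces the same-named element of
#'   the default spec (see the structure of the returned list).
#' @return an object of class `pgsa_marginals`.
#' @examples
#' marginal_spec(age = list(mean = 70, sd = 5))
#' @export
marginal_spec <- function(...) {
  spec <- list(
    age = list(mean = 74.2, sd = 7.4, min = 40, max = 110),
    gender = list(p_female = 141 / 397),
    education = list(mean = 15.7, sd = 3.0, min = 0, max = 20),
    bmi = list(mean = 26.1, sd = 4.0, min = 15, max = 60),
    apoe4 = list(p = c(185, 165, 47) / 397),
    hachinski = list(size = 2, mu = 1.3, max = 4),
    faq = list(size = 0.8, mu = 3.2, max = 21),
    mmse = list(mean = 27.0, sd = 1.8, min = 24, max = 30),
    adascog = list(mean = 18.6, sd = 6.3, min = 0, max = 85),
    npbatt = list(mean = -1.02, sd = 0.66),
    csf_ratio = list(meanlog = log(1.564), sdlog = 0.6, fraction = 199 / 397),
    medication = list(p = 240 / 397)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(spec))
    if (length(bad)) abort(paste("unknown marginal(s):", paste(bad, collapse = ", ")))
    for (nm in names(over)) spec[[nm]] <- modifyList(spec[[nm]], over[[nm]])
  }
  stopifnot(abs(sum(spec$apoe4$p) - 1) < 1e-8, all(spec$apoe4$p >= 0))
  structure(spec, class = "pgsa_marginals")
}

# covariates driven by the latent Gaussian copula, in fixed order
COPULA_VARS <- c("age", "gender", "education", "bmi", "apoe4",
                 "hachinski", "faq", "mmse", "adascog", "npbatt")

#' Dependence structure for the synthetic cohort
#'
#' Correlation matrix of the latent Gaussian copula that couples the baseline
#' covariates. The default couples the cognitive measures only (latent
#' correlations: ADAS-cog with NP-Batt -0.6, ADAS-cog with MMSE -0.4, FAQ with
#' NP-Batt -0.3; all others 0) — assumed values, since covariate correlations
#' of the source cohort are not published.
#'
#' @param pairs a named list of latent correlations, names of the form
#'   `"var1,var2"` with variables among age, gender, education, bmi, apoe4,
#'   hachinski, faq, mmse, adascog, npbatt.
#' @return a `pgsa_dependence` object wrapping the correlation matrix.
#' @examples
#' dependence_spec() # default
#' dependence_spec(pairs = list("age,npbatt" = -0.2))
#' @export
dependence_spec <- function(pairs = list("adascog,npbatt" = -0.6,
                                         "adascog,mmse" = -0.4,
                                         "faq,npbatt" = -0.3)) {
  p <- length(COPULA_VARS)
  R <- diag(p)
  dimnames(R) <- list(COPULA_VARS, COPULA_VARS)
  for (nm in names(pairs)) {
    vars <- trimws(strsplit(nm, ",", fixed = TRUE)[[1]])
    if (length(vars) != 2L || !all(vars %in% COPULA_VARS)) {
      abort(paste0("dependence error: bad pair '", nm, "'"))
    }
    R[vars[1], vars[2]] <- R[vars[2], vars[1]] <- pairs[[nm]]
  }
  if (any(abs(R) > 1)) abort("dependence error: correlations must lie in [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort("dependence error: correlation matrix is not positive semidefinite")
  }
  structure(list(R = R), class = "pgsa_dependence")
}

# quantile of a negative binomial truncated to 0..max
q_trunc_nbinom <- function(p, size, mu, max) {
  cdf <- stats::pnbinom(0:max, size = size, mu = mu)
  cdf <- cdf / cdf[max + 1L]
  findInterval(p, cdf, left.open = TRUE)
}

# quantile of a normal truncated to [min, max]
q_trunc_norm <- function(p, mean, sd, min = -Inf, max = Inf) {
  plo <- pnorm(min, mean, sd)
  phi <- pnorm(max, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

#' Generate a synthetic baseline cohort
#'
#' Draws `n` baseline records from a Gaussian copula: a latent multivariate
#' normal vector per subject (correlation matrix from `dependence`) is mapped
#' through each covariate's marginal quantile function (`marginals`). All
#' schema invariants hold by construction (truncation is enforced). Output is
#' bit-reproducible for a given seed.
#'
#' @param n number of subjects.
#' @param marginals a [marginal_spec()].
#' @param dependence a [dependence_spec()].
#' @param seed integer seed, or `NULL` to use the ambient RNG state.
#' @return a baseline tibble (see [cohort()]).
#' @examples
#' generate_baseline(5, seed = 42)
#' @export
generate_baseline <- function(n, marginals = marginal_spec(),
                              dependence = dependence_spec(), seed = NULL) {
  stopifnot(n >= 1, inherits(marginals, "pgsa_marginals"),
            inherits(dependence, "pgsa_dependence"))
  with_seed(seed, {
    z <- rmvn(n, rep(0, length(COPULA_VARS)), dependence$R)
    colnames(z) <- COPULA_VARS
    u <- pnorm(z)
    m <- marginals

    apoe_cdf <- cumsum(m$apoe4$p)
    b <- tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = round(q_trunc_norm(u[, "age"], m$age$mean, m$age$sd,
                               m$age$min, m$age$max), 1),
      gender = ifelse(u[, "gender"] < m$gender$p_female, "female", "male"),
      education = round(q_trunc_norm(u[, "education"], m$education$mean,
                                     m$education$sd, m$education$min,
                                     m$education$max)),
      bmi = round(q_trunc_norm(u[, "bmi"], m$bmi$mean, m$bmi$sd,
                               m$bmi$min, m$bmi$max), 1),
      apoe4 = findInterval(u[, "apoe4"], apoe_cdf, left.open = TRUE),
      hachinski = q_trunc_nbinom(u[, "hachinski"], m$hachinski$size,
                                 m$hachinski$mu, m$hachinski$max),
      faq = q_trunc_nbinom(u[, "faq"], m$faq$size, m$faq$mu, m$faq$max),
      mmse = round(q_trunc_norm(u[, "mmse"], m$mmse$mean, m$mmse$sd,
                                m$mmse$min, m$mmse$max)),
      adascog_bl = round(q_trunc_norm(u[, "adascog"], m$adascog$mean,
                                      m$adascog$sd, m$adascog$min,
                                      m$adascog$max), 1),
      npbatt_bl = round(q_trunc_norm(u[, "npbatt"], m$npbatt$mean,
                                     m$npbatt$sd), 3)
    )
    has_csf <- runif(n) < m$csf_ratio$fraction
    csf <- stats::qlnorm(runif(n), m$csf_ratio$meanlog, m$csf_ratio$sdlog)
    b$csf_ratio <- ifelse(has_csf, round(csf, 3), NA_real_)
    b$on_medication <- runif(n) < m$medication$p
    b
  })
}

#' Generate longitudinal outcomes from fitted-model artifacts
#'
#' Simulates outcome records for a baseline cohort from a fitted endpoint
#' and/or trajectory model, using the point estimates as truth (no parameter
#' uncertainty; see [simulate_control_endpoints()] and
#' [simulate_control_trajectories()] for virtual-placebo simulation with a
#' parameter draw). For the trajectory model each subject receives a random
#' intercept/slope pair drawn from the fit's G matrix, the fixed-effect mean
#' at each scheduled visit, independent within-subject noise, and — for
#' treated subjects — `treatment_slope_delta` times the visit number (a
#' positive delta flattens the decline, since higher NP-Batt = better). For
#' the endpoint model a month-24 ADAS-cog value is generated on the
#' square-root scale and back-transformed with clipping to \[0, 85\].
#'
#' @param baselines baseline tibble.
#' @param endpoint_fit a `pgsa_endpoint_fit`, or `NULL`.
#' @param trajectory_fit a `pgsa_trajectory_fit`, or `NULL`.
#' @param schedule visit numbers for the trajectory outcomes; must be a subset
#'   of `{0, 1, 2, 3, 4, 6}`.
#' @param treatment_slope_delta slope improvement in z-units per visit applied
#'   to treated subjects (default 0 = untreated/control).
#' @param treated logical vector marking treated subjects (default: all
#'   treated when `treatment_slope_delta != 0`, none otherwise).
#' @param seed RNG seed or `NULL`.
#' @return a [cohort()] whose visits carry `npbatt` (trajectory) and/or
#'   `adascog` at visit 4 (endpoint).
#' @export
generate_outcomes <- function(baselines, endpoint_fit = NULL,
                              trajectory_fit = NULL,
                              schedule = LEGAL_VISITS,
                              treatment_slope_delta = 0,
                              treated = NULL, seed = NULL) {
  if (is.null(endpoint_fit) && is.null(trajectory_fit)) {
    abort("provide at least one of endpoint_fit, trajectory_fit")
  }
  if (!all(schedule %in% LEGAL_VISITS)) {
    abort(paste("schedule error: visit numbers must be a subset of",
                paste(LEGAL_VISITS, collapse = ", ")))
  }
  b <- as_tibble(baselines)
  n <- nrow(b)
  if (is.null(treated)) treated <- rep(treatment_slope_delta != 0, n)
  stopifnot(length(treated) == n)

  with_seed(seed, {
    visits <- tibble(subject_id = character(), visit_number = integer(),
                     adascog = numeric(), npbatt = numeric())
    if (!is.null(trajectory_fit)) {
      stopifnot(inherits(trajectory_fit, "pgsa_trajectory_fit"))
      sim <- simulate_trajectory_once(trajectory_fit, b, sort(schedule),
                                      theta = trajectory_fit$coefficients,
                                      slope_delta = treatment_slope_delta,
                                      treated = treated)
      visits <- dplyr::bind_rows(visits, sim)
    }
    if (!is.null(endpoint_fit)) {
      stopifnot(inherits(endpoint_fit, "pgsa_endpoint_fit"))
      enc <- encode_covariates(b, endpoint_fit$coding)
      X <- build_design(enc, endpoint_fit$terms)
      s <- drop(X %*% endpoint_fit$coefficients) +
        rnorm(n, 0, endpoint_fit$sigma) -
        treatment_slope_delta_endpoint(treatment_slope_delta, treated)
      ep <- tibble(subject_id = b$subject_id, visit_number = 4L,
                   adascog = adas_unsqrt(s), npbatt = NA_real_)
      if (nrow(visits)) {
        visits <- dplyr::rows_patch(visits, ep[, c("subject_id", "visit_number",
                                                   "adascog")],
                                    by = c("subject_id", "visit_number"),
                                    unmatched = "ignore")
        extra <- !ep$subject_id %in%
          visits$subject_id[visits$visit_number == 4L]
        visits <- dplyr::bind_rows(visits, ep[extra, ])
      } else {
        visits <- ep
      }
    }
    cohort(b, visits)
  })
}

# endpoint interpretation of a treatment effect: lower sqrt-scale score
treatment_slope_delta_endpoint <- function(delta, treated) {
  ifelse(treated, delta, 0)
}

# one trajectory realization at fixed fixed-effect vector theta
simulate_trajectory_once <- function(fit, baselines, schedule, theta,
                                     slope_delta = 0, treated = NULL) {
  enc <- encode_covariates(baselines, fit$coding)
  n <- nrow(enc)
  if (is.null(treated)) treated <- rep(FALSE, n)
  G <- ranef_cov(fit)
  bmat <- if (all(G == 0)) matrix(0, n, 2) else rmvn(n, c(0, 0), G)
  long <- tidyr::expand_grid(idx = seq_len(n), visit = as.numeric(schedule))
  encl <- enc[long$idx, ]
  encl$visit <- long$visit
  X <- build_design(encl, fit$terms)
  mu <- drop(X %*% theta)
  eps <- rnorm(nrow(long), 0, fit$sigma_w)
  y <- mu + bmat[long$idx, 1] + bmat[long$idx, 2] * long$visit + eps +
    ifelse(treated[long$idx], slope_delta * long$visit, 0)
  tibble(subject_id = enc$subject_id[long$idx],
         visit_number = as.integer(long$visit),
         adascog = NA_real_, npbatt = y)
}

#' Thin a cohort by random dropout
#'
#' Removes visit records independently with per-visit retention
#' probabilities (missing completely at random); baselines are kept. In the
#' source cohort 286 of 397 subjects (72%) had a month-24 evaluation.
#'
#' @param x a `pgsa_cohort`.
#' @param retention named numeric vector of retention probabilities in (0, 1],
#'   names = visit numbers; visits not named are fully retained. Probabilities
#'   must be non-increasing over visits.
#' @param seed RNG seed or `NULL`.
#' @return a thinned `pgsa_cohort`.
#' @examples
#' bl <- generate_baseline(50, seed = 1)
#' co <- generate_outcomes(bl, trajectory_fit = pgsa_example_fit("trajectory"),
#'                         seed = 2)
#' apply_dropout(co, retention = c("4" = 0.72, "6" = 0.6), seed = 3)
#' @export
apply_dropout <- function(x, retention, seed = NULL) {
  stopifnot(inherits(x, "pgsa_cohort"))
  ret <- as.numeric(retention)
  if (any(ret <= 0 | ret > 1)) abort("retention probabilities must be in (0, 1]")
  vn <- as.integer(names(retention))
  if (is.unsorted(vn)) {
    ord <- order(vn)
    vn <- vn[ord]; ret <- ret[ord]
  }
  if (is.unsorted(rev(ret))) {
    abort("retention must be non-increasing over visits")
  }
  with_seed(seed, {
    p <- rep(1, nrow(x$visits))
    idx <- match(x$visits$visit_number, vn)
    p[!is.na(idx)] <- ret[idx[!is.na(idx)]]
    keep <- runif(nrow(x$visits)) < p
    cohort(x$baselines, x$visits[keep, ])
  })
}
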