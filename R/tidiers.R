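#' Tidy an endpoint model fit
#'
#' @param x a `pgsa_endpoint_fit`.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.pgsa_endpoint_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$coefficients / se
  tibble(term = x$terms, estimate = unname(x$coefficients),
         std.error = unname(se), statistic = unname(stat),
         p.value = unname(2 * pnorm(-abs(stat))))
}

#' @rdname tidy.pgsa_endpoint_fit
#' @export
glance.pgsa_endpoint_fit <- function(x, ...) {
  tibble(n = x$n, sigma = x$sigma, r.squared = x$r_squared, AIC = x$aic,
         n_terms = length(x$terms), transform = x$transform)
}

#' Tidy a trajectory model fit
#'
#' Follows the broom.mixed convention: fixed effects carry
#' `effect = "fixed"`; the random-effect SDs, their correlation and the
#' within-subject SD carry `effect = "ran_pars"`.
#'
#' @param x a `pgsa_trajectory_fit`.
#' @param ... unused.
#' @return a tibble with columns `effect`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (the latter three `NA` for variance components).
#' @export
tidy.pgsa_trajectory_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$coefficients / se
  fixed <- tibble(effect = "fixed", term = x$terms,
                  estimate = unname(x$coefficients),
                  std.error = unname(se), statistic = unname(stat),
                  p.value = unname(2 * pnorm(-abs(stat))))
  ran <- tibble(effect = "ran_pars",
                term = c("sd__(Intercept)", "sd__visit",
                         "cor__(Intercept).visit", "sd__Observation"),
                estimate = c(x$ranef$sd_intercept, x$ranef$sd_slope,
                             x$ranef$cor, x$sigma_w),
                std.error = NA_real_, statistic = NA_real_,
                p.value = NA_real_)
  dplyr::bind_rows(fixed, ran)
}

#' @rdname tidy.pgsa_trajectory_fit
#' @export
glance.pgsa_trajectory_fit <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_obs = x$n_obs, sigma_w = x$sigma_w,
         sd_intercept = x$ranef$sd_intercept, sd_slope = x$ranef$sd_slope,
         cor_intercept_slope = x$ranef$cor,
         slope_lrt_p = if (is.null(x$slope_lrt)) NA_real_ else x$slope_lrt$p,
         singular = x$singular, time_unit = x$time_unit)
}

#' Tidy a power result
#'
#' @param x a `pgsa_power`.
#' @param ... unused.
#' @return a one-row tibble with the power, its method, the Monte-Carlo SE
#'   when applicable, and the design that produced it.
#' @export
tidy.pgsa_power <- function(x, ...) {
  as_tibble(Filter(function(el) is.atomic(el) && length(el) == 1,
                   unclass(x)))
}
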