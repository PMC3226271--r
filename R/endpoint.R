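#' Default candidate terms for the endpoint model
#'
#' Demographics, ApoE4 allele count, the obesity flag, modified Hachinski,
#' and baseline FAQ, MMSE, ADAS-cog and NP-Batt scores.
#' @keywords internal
ENDPOINT_CANDIDATES <- c("age", "gender", "education", "obesity", "apoe4",
                         "hachinski", "faq_bl", "mmse_bl", "adascog_bl",
                         "npbatt_bl")

fit_lm_terms <- function(y, enc, terms) {
  X <- build_design(enc, terms)
  df <- as.data.frame(X)
  names(df) <- safe_name(terms)
  df$.y <- y
  rhs <- setdiff(names(df), c(".y", ".intercept"))
  f <- stats::reformulate(if (length(rhs)) rhs else "1", response = ".y")
  lm(f, data = df)
}

# Backward AIC elimination with marginality: a main effect is never dropped
# while a retained interaction contains it. Deterministic: at each step the
# single deletion with the largest AIC drop is taken; ties break by term name.
aic_backward <- function(y, enc, terms, trace = NULL) {
  repeat {
    cur <- fit_lm_terms(y, enc, terms)
    cur_aic <- AIC(cur)
    droppable <- setdiff(terms, "(Intercept)")
    inter <- droppable[is_interaction(droppable)]
    protected <- unique(unlist(lapply(inter, term_parents)))
    droppable <- setdiff(droppable, protected)
    if (!length(droppable)) break
    cand <- vapply(sort(droppable), function(tm) {
      AIC(fit_lm_terms(y, enc, setdiff(terms, tm)))
    }, numeric(1))
    best <- names(cand)[which.min(cand)]
    if (cand[best] < cur_aic) {
      trace <- c(trace, sprintf("drop %-24s AIC %.2f -> %.2f",
                                best, cur_aic, cand[best]))
      terms <- setdiff(terms, best)
    } else {
      break
    }
  }
  list(terms = terms, trace = trace)
}

#' Fit the endpoint (24-month ADAS-cog) model
#'
#' Regresses the square root of the modified ADAS-cog at visit 4 (month 24)
#' on baseline covariates. Selection proceeds in three stages: (1) backward
#' elimination of main effects by AIC to a local minimum; (2) each pairwise
#' interaction of the retained main effects is tested singly for inclusion
#' (kept when it lowers the AIC); (3) accepted interactions are pooled and
#' backward AIC elimination is re-run, honoring marginality.
#'
#' @param data a `pgsa_cohort` with ADAS-cog outcomes at visit 4.
#' @param candidates candidate main-effect term names (design columns from
#'   [encode_covariates()]); the default covers demographics, ApoE4, obesity,
#'   Hachinski and the four baseline scores.
#' @param coding a [coding_config()].
#' @param terms optional fixed term set (including `"(Intercept)"`); when
#'   given, selection is skipped and the model is fit as-is.
#' @param select run the selection stages (default `TRUE`).
#' @return a `pgsa_endpoint_fit`: term names, coefficients, parameter
#'   covariance, residual SD on the square-root scale, n, and the selection
#'   trace. Supports [tidy()], [glance()], [predict_endpoint()],
#'   [simulate_control_endpoints()].
#' @export
fit_endpoint <- function(data, candidates = ENDPOINT_CANDIDATES,
                         coding = coding_config(), terms = NULL,
                         select = TRUE) {
  stopifnot(inherits(data, "pgsa_cohort"))
  v4 <- data$visits[data$visits$visit_number == 4L, ]
  v4 <- v4[!is.na(v4$adascog), ]
  if (!nrow(v4)) abort("sample-size error: no month-24 ADAS-cog outcomes")
  enc <- encode_covariates(data$baselines, coding)
  enc <- enc[match(v4$subject_id, enc$subject_id), ]
  keep_cols <- unique(c("subject_id",
                        unlist(lapply(c(candidates, terms), term_parents))))
  keep_cols <- setdiff(keep_cols, "(Intercept)")
  cc <- complete.cases(enc[, intersect(keep_cols, names(enc))])
  enc <- enc[cc, ]
  v4 <- v4[cc, ]
  y <- adas_sqrt(v4$adascog)

  if (!is.null(terms)) {
    terms <- canon_term(terms)
    if (!"(Intercept)" %in% terms) terms <- c("(Intercept)", terms)
    sel_trace <- "fixed term set supplied; selection skipped"
  } else {
    start <- c("(Intercept)", canon_term(candidates))
    if (nrow(enc) < length(start) + 2L) {
      abort("sample-size error: need at least 2 more complete cases than terms")
    }
    X <- build_design(enc, start)
    if (qr(X)$rank < ncol(X)) {
      abort("collinearity error: candidate design matrix is rank-deficient")
    }
    if (!select) {
      terms <- start
      sel_trace <- "select = FALSE; full main-effects model"
    } else {
      sel_trace <- character()
      bw <- aic_backward(y, enc, start, trace = sel_trace)
      mains <- setdiff(bw$terms, "(Intercept)")
      sel_trace <- bw$trace
      accepted <- character()
      if (length(mains) >= 2L) {
        base_aic <- AIC(fit_lm_terms(y, enc, bw$terms))
        pairs <- utils::combn(sort(mains), 2L,
                              function(p) paste(p, collapse = ":"))
        for (tm in pairs) {
          a <- AIC(fit_lm_terms(y, enc, c(bw$terms, tm)))
          if (a < base_aic) {
            accepted <- c(accepted, tm)
            sel_trace <- c(sel_trace, sprintf(
              "accept %-22s AIC %.2f -> %.2f (singly)", tm, base_aic, a))
          }
        }
      }
      final <- aic_backward(y, enc, c(bw$terms, accepted), trace = sel_trace)
      terms <- final$terms
      sel_trace <- final$trace
    }
  }

  m <- fit_lm_terms(y, enc, terms)
  beta <- coef(m)
  names(beta) <- c("(Intercept)", setdiff(terms, "(Intercept)"))
  Sigma <- vcov(m)
  dimnames(Sigma) <- list(names(beta), names(beta))
  structure(
    list(terms = names(beta), coefficients = beta, vcov = Sigma,
         sigma = sigma(m), n = length(y), transform = "sqrt",
         coding = coding, r_squared = summary(m)$r.squared,
         aic = AIC(m), selection_trace = sel_trace),
    class = c("pgsa_endpoint_fit", "pgsa_fit")
  )
}

#' @export
print.pgsa_endpoint_fit <- function(x, ...) {
  cat("<pgsa endpoint model: sqrt(ADAS-cog at month 24)>\n")
  cat(sprintf("  n = %d, residual SD (sqrt scale) = %.4f", x$n, x$sigma))
  if (!is.null(x$r_squared) && !is.na(x$r_squared)) {
    cat(sprintf(", R^2 = %.3f", x$r_squared))
  }
  cat("\n  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the virtual-placebo endpoint for new subjects
#'
#' Forms the linear predictor of a fitted endpoint model for each baseline
#' record. The expectation is computed on the square-root scale (`pred_sqrt`);
#' `pred` back-transforms it by squaring (a plug-in value — the
#' back-transform of a mean is biased low relative to the mean of the
#' back-transform, which is why power and precision arithmetic stay on the
#' square-root scale).
#'
#' @param fit a `pgsa_endpoint_fit`.
#' @param baselines baseline tibble.
#' @return tibble with `subject_id`, `pred_sqrt`, `pred`.
#' @export
predict_endpoint <- function(fit, baselines) {
  stopifnot(inherits(fit, "pgsa_endpoint_fit"))
  enc <- encode_covariates(as_tibble(baselines), fit$coding)
  X <- build_design(enc, fit$terms)
  s <- drop(X %*% fit$coefficients)
  tibble(subject_id = enc$subject_id, pred_sqrt = s, pred = adas_unsqrt(s))
}

#' Simulate virtual-placebo endpoint distributions
#'
#' Generates `n_replicates` virtual control datasets from a fitted endpoint
#' model: per replicate one parameter vector is drawn from the multivariate
#' normal distribution of the estimated parameters (shared by all subjects,
#' preserving parameter-uncertainty correlation within a virtual trial), the
#' linear combination is formed for each subject's covariates, residual noise
#' with the fitted variance is added, and the square-root-scale value is
#' back-transformed with clipping to \[0, 85\].
#'
#' @param fit a `pgsa_endpoint_fit`.
#' @param baselines baseline tibble.
#' @param n_replicates number of virtual datasets.
#' @param seed RNG seed or `NULL`.
#' @param parameter_uncertainty draw the parameter vector per replicate
#'   (default `TRUE`); `FALSE` fixes it at the point estimates.
#' @return numeric matrix, `n_replicates` rows by `nrow(baselines)` columns,
#'   of original-scale ADAS-cog scores; column names are subject ids.
#' @export
simulate_control_endpoints <- function(fit, baselines, n_replicates,
                                       seed = NULL,
                                       parameter_uncertainty = TRUE) {
  stopifnot(inherits(fit, "pgsa_endpoint_fit"), n_replicates >= 1)
  enc <- encode_covariates(as_tibble(baselines), fit$coding)
  X <- build_design(enc, fit$terms)
  n <- nrow(X)
  with_seed(seed, {
    theta <- if (parameter_uncertainty) {
      rmvn(n_replicates, fit$coefficients, fit$vcov)
    } else {
      matrix(fit$coefficients, nrow = n_replicates,
             ncol = length(fit$coefficients), byrow = TRUE)
    }
    out <- theta %*% t(X) +
      matrix(rnorm(n_replicates * n, 0, fit$sigma), n_replicates, n)
    out <- adas_unsqrt(out)
    colnames(out) <- enc$subject_id
    out
  })
}

#' Analytic power for a two-group endpoint comparison
#'
#' Standard normal-approximation power for comparing two means: with effect
#' `d` on the square-root scale, residual SD `s` in each group and `n`
#' subjects per group, power = Phi(d / (s * sqrt(2/n)) - z) (plus the
#' opposite tail for a two-sided test). A randomized treatment indicator is
#' uncorrelated with the model covariates, so the two-sample formula applies
#' directly to the adjusted comparison.
#'
#' @param effect group difference on the square-root ADAS-cog scale (>= 0).
#' @param sd residual SD on the square-root scale.
#' @param n_per_group subjects per group (>= 2).
#' @param alpha significance level.
#' @param sided 2 (default) or 1.
#' @return a `pgsa_power` object; the power value is `$power`.
#' @examples
#' analytic_power(0.16, 0.669, 286)
#' @export
analytic_power <- function(effect, sd, n_per_group, alpha = 0.05, sided = 2) {
  stopifnot(effect >= 0, sd > 0, n_per_group >= 2, alpha > 0, alpha < 1,
            sided %in% c(1, 2))
  z <- qnorm(1 - alpha / sided)
  ncp <- effect / (sd * sqrt(2 / n_per_group))
  pow <- pnorm(ncp - z) + if (sided == 2) pnorm(-ncp - z) else 0
  new_power(power = pow, method = "analytic", effect = effect, sd = sd,
            n_per_group = n_per_group, alpha = alpha, sided = sided)
}

new_power <- function(power, method, ...) {
  structure(c(list(power = power, method = method), list(...)),
            class = "pgsa_power")
}

#' @export
print.pgsa_power <- function(x, ...) {
  cat(sprintf("<pgsa power (%s)>\n", x$method))
  cat(sprintf("  power = %.3f", x$power))
  if (!is.null(x$mc_se)) cat(sprintf(" (MC SE %.3f, %d simulations", x$mc_se,
                                     x$n_sims),
                             if (isTRUE(x$n_nonconverged > 0)) {
                               sprintf(", %d non-converged excluded)", x$n_nonconverged)
                             } else ")", sep = "")
  cat("\n")
  des <- setdiff(names(x), c("power", "method", "mc_se", "reliability_warning"))
  for (nm in des) {
    val <- x[[nm]]
    if (is.numeric(val) && length(val) == 1) cat(sprintf("  %s = %g\n", nm, val))
  }
  if (isTRUE(x$reliability_warning)) {
    cat("  warning: > 5% of inner fits failed to converge\n")
  }
  invisible(x)
}
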