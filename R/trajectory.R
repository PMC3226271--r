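#' Default candidate terms for the trajectory model
#' @keywords internal
TRAJECTORY_CANDIDATES <- c("bmi2", "bmi3", "apoe4", "age", "gender",
                           "education", "hachinski", "faq_bl", "mmse_bl",
                           "adascog_bl", "npbatt_bl")

ranef_cov <- function(fit) {
  sdi <- fit$ranef$sd_intercept
  sds <- fit$ranef$sd_slope
  r <- fit$ranef$cor
  G <- matrix(c(sdi^2, r * sdi * sds, r * sdi * sds, sds^2), 2L, 2L)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) abort("random-effects covariance G is not PSD")
  G
}

traj_long_data <- function(data, coding, time_unit, include_csf) {
  enc <- encode_covariates(data$baselines, coding)
  v <- data$visits[!is.na(data$visits$npbatt), ]
  if (!nrow(v)) abort("no NP-Batt outcomes in the cohort")
  if (include_csf) {
    has <- enc$subject_id[!is.na(enc$csf_ratio)]
    v <- v[v$subject_id %in% has, ]
    if (!nrow(v)) abort("no subjects with both CSF ratio and NP-Batt outcomes")
  }
  d <- dplyr::left_join(v, enc, by = "subject_id")
  d$visit <- if (time_unit == "visit") as.numeric(d$visit_number) else
    as.numeric(d$visit_number) * 6
  d
}

fit_lmer_terms <- function(d, terms, reml = TRUE) {
  X <- build_design(d, setdiff(terms, "(Intercept)"))
  df <- as.data.frame(X)
  names(df) <- safe_name(colnames(X))
  df$.y <- d$npbatt
  df$.id <- factor(d$subject_id)
  df$visit <- d$visit
  rhs <- setdiff(names(df), c(".y", ".id", "visit"))
  rhs <- union(rhs, if ("visit" %in% terms) "visit" else character())
  f <- stats::as.formula(paste(
    ".y ~", paste(c(rhs, "(visit | .id)"), collapse = " + ")))
  suppressMessages(suppressWarnings(
    lme4::lmer(f, data = df, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
}

# Wald p-values with a normal reference (large-sample; the cohorts here have
# hundreds of subjects, where this coincides with Satterthwaite-type dfs)
wald_p <- function(m) {
  cf <- summary(m)$coefficients
  p <- 2 * pnorm(-abs(cf[, "t value"]))
  names(p) <- rownames(cf)
  p
}

unsafe_name <- function(nm) {
  canon_term(ifelse(nm == ".intercept" | nm == "(Intercept)", "(Intercept)",
                    gsub("_x_", ":", nm, fixed = TRUE)))
}

#' Fit the trajectory (NP-Batt over 36 months) mixed model
#'
#' Random-intercept/random-slope linear mixed model for the NP-Batt composite
#' at all follow-up visits, with time coded as the visit number in 6-month
#' units. Selection: (1) the saturated model carries every candidate main
#' effect, every candidate-by-time interaction, and random intercepts and
#' slopes; (2) a likelihood-ratio test compares the random-slope structure
#' against random intercepts only, and slopes are retained when p < 0.05;
#' (3) fixed time interactions, then fixed main effects, are eliminated
#' backward by Wald tests (largest p first, removal when p > 0.05), honoring
#' marginality — a main effect (including the time slope itself) is never
#' removed while a retained interaction contains it; (4) pairwise
#' interactions of the surviving main effects are tested singly for
#' inclusion, pooled, and pruned the same way. Variance components are
#' REML-estimated; the random-structure LRT uses ML refits.
#'
#' @param data a `pgsa_cohort` with NP-Batt outcomes.
#' @param candidates candidate main-effect design columns.
#' @param include_csf add the CSF Ab42/T-tau ratio (and its time interaction)
#'   to the candidates; subjects without a CSF value are dropped.
#' @param coding a [coding_config()].
#' @param terms optional fixed term set (skips selection).
#' @param select run selection (default `TRUE`); `FALSE` fits the saturated
#'   model.
#' @param time_unit `"visit"` (6-month units, default) or `"month"`.
#' @param alpha_wald removal threshold for the Wald elimination.
#' @return a `pgsa_trajectory_fit` with fixed effects and their covariance,
#'   the random-effects covariance as (sd_intercept, sd_slope, cor), the
#'   within-subject SD, the slope LRT, and the selection trace.
#' @export
fit_trajectory <- function(data, candidates = TRAJECTORY_CANDIDATES,
                           include_csf = FALSE, coding = coding_config(),
                           terms = NULL, select = TRUE, time_unit = c("visit", "month"),
                           alpha_wald = 0.05) {
  stopifnot(inherits(data, "pgsa_cohort"))
  time_unit <- match.arg(time_unit)
  if (include_csf) candidates <- union(candidates, "csf_ratio")
  d <- traj_long_data(data, coding, time_unit, include_csf)

  slope_lrt <- NULL
  sel_trace <- character()
  if (!is.null(terms)) {
    terms <- canon_term(terms)
    if (!"(Intercept)" %in% terms) terms <- c("(Intercept)", terms)
    sel_trace <- "fixed term set supplied; selection skipped"
  } else {
    mains <- canon_term(candidates)
    saturated <- c("(Intercept)", mains, "visit",
                   canon_term(paste0(mains, ":visit")))
    m_full <- fit_lmer_terms(d, saturated, reml = TRUE)
    # LRT: random slopes vs random intercepts only (ML refits via anova)
    f_ri <- stats::update(stats::formula(m_full),
                          . ~ . - (visit | .id) + (1 | .id))
    m_ri <- suppressMessages(suppressWarnings(
      lme4::lmer(f_ri, data = m_full@frame, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    ll_full <- logLik(lme4::refitML(m_full))
    ll_ri <- logLik(lme4::refitML(m_ri))
    chisq <- max(0, 2 * as.numeric(ll_full - ll_ri))
    df_lrt <- attr(ll_full, "df") - attr(ll_ri, "df")
    # naive chi-square reference (conservative at the variance boundary)
    slope_lrt <- list(chisq = chisq, df = df_lrt,
                      p = stats::pchisq(chisq, df_lrt, lower.tail = FALSE))
    if (slope_lrt$p >= 0.05) {
      warn(paste("random slopes not supported by the LRT (p =",
                 format.pval(slope_lrt$p), "); they are retained in the",
                 "returned fit — refit with a simpler structure if desired"))
    }
    sel_trace <- c(sel_trace, sprintf(
      "random-slope LRT: chisq = %.2f, df = %d, p = %.2g (slopes %s)",
      slope_lrt$chisq, slope_lrt$df, slope_lrt$p,
      if (slope_lrt$p < 0.05) "retained" else "not supported"))

    terms <- saturated
    if (select) {
      # stage 1: backward over time interactions, then main effects
      for (stage in c("interaction", "main")) {
        repeat {
          m <- fit_lmer_terms(d, terms, reml = TRUE)
          p <- wald_p(m)
          names(p) <- unsafe_name(names(p))
          inter <- terms[is_interaction(terms)]
          droppable <- if (stage == "interaction") inter else {
            protected <- unique(unlist(lapply(inter, term_parents)))
            setdiff(terms, c("(Intercept)", inter, protected))
          }
          p <- p[names(p) %in% droppable]
          if (!length(p) || max(p) <= alpha_wald) break
          worst <- names(p)[order(-p, names(p))][1]
          sel_trace <- c(sel_trace, sprintf("drop %-24s Wald p = %.3g",
                                            worst, max(p)))
          terms <- setdiff(terms, worst)
        }
      }
      # stage 2: screen pairwise interactions of surviving main effects
      surv <- setdiff(terms[!is_interaction(terms)], c("(Intercept)", "visit"))
      if (length(surv) >= 2L) {
        cand_pairs <- utils::combn(sort(surv), 2L,
                                   function(pp) paste(pp, collapse = ":"))
        cand_pairs <- setdiff(canon_term(cand_pairs), terms)
        accepted <- character()
        for (tm in cand_pairs) {
          m_try <- fit_lmer_terms(d, c(terms, tm), reml = TRUE)
          p_try <- wald_p(m_try)
          names(p_try) <- unsafe_name(names(p_try))
          if (!is.na(p_try[tm]) && p_try[tm] < alpha_wald) {
            accepted <- c(accepted, tm)
            sel_trace <- c(sel_trace, sprintf(
              "accept %-22s Wald p = %.3g (singly)", tm, p_try[tm]))
          }
        }
        if (length(accepted)) {
          terms <- c(terms, accepted)
          repeat {
            m <- fit_lmer_terms(d, terms, reml = TRUE)
            p <- wald_p(m)
            names(p) <- unsafe_name(names(p))
            p <- p[names(p) %in% accepted]
            if (!length(p) || max(p) <= alpha_wald) break
            worst <- names(p)[order(-p, names(p))][1]
            sel_trace <- c(sel_trace, sprintf("drop %-24s Wald p = %.3g",
                                              worst, max(p)))
            terms <- setdiff(terms, worst)
            accepted <- setdiff(accepted, worst)
          }
        }
      }
    }
  }

  m <- fit_lmer_terms(d, terms, reml = TRUE)
  beta <- lme4::fixef(m)
  names(beta) <- unsafe_name(names(beta))
  Sigma <- as.matrix(vcov(m))
  dimnames(Sigma) <- list(names(beta), names(beta))
  vc <- lme4::VarCorr(m)[[".id"]]
  sds <- attr(vc, "stddev")
  corr <- attr(vc, "correlation")[1, 2]
  singular <- lme4::isSingular(m)
  if (singular) {
    warn("random-effects covariance is singular (boundary fit)")
  }
  structure(
    list(terms = names(beta), coefficients = beta, vcov = Sigma,
         ranef = list(sd_intercept = unname(sds["(Intercept)"]),
                      sd_slope = unname(sds["visit"]),
                      cor = unname(corr)),
         sigma_w = sigma(m), time_unit = time_unit,
         n_subjects = length(unique(d$subject_id)), n_obs = nrow(d),
         slope_lrt = slope_lrt, singular = singular,
         coding = coding, selection_trace = sel_trace),
    class = c("pgsa_trajectory_fit", "pgsa_fit")
  )
}

#' @export
print.pgsa_trajectory_fit <- function(x, ...) {
  cat("<pgsa trajectory model: NP-Batt, random intercept + slope>\n")
  cat(sprintf("  %d subjects, %d observations; time in %s units\n",
              x$n_subjects, x$n_obs,
              if (x$time_unit == "visit") "6-month visit" else "month"))
  cat(sprintf("  SD(intercept) %.4f, SD(slope) %.4f, cor %.3f, within-SD %.4f\n",
              x$ranef$sd_intercept, x$ranef$sd_slope, x$ranef$cor, x$sigma_w))
  cat("  fixed effects:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the expected NP-Batt trajectory
#'
#' Fixed-effects mean at each requested visit for each baseline record
#' (population-level trajectory; random effects average to zero).
#'
#' @param fit a `pgsa_trajectory_fit`.
#' @param baselines baseline tibble.
#' @param visits visit numbers (6-month units), a subset of
#'   `{0, 1, 2, 3, 4, 6}`.
#' @return tibble with `subject_id`, `visit_number`, `pred`.
#' @export
predict_trajectory <- function(fit, baselines, visits = LEGAL_VISITS) {
  stopifnot(inherits(fit, "pgsa_trajectory_fit"))
  if (!all(visits %in% LEGAL_VISITS)) {
    abort(paste("schedule error: visit numbers must be a subset of",
                paste(LEGAL_VISITS, collapse = ", ")))
  }
  enc <- encode_covariates(as_tibble(baselines), fit$coding)
  long <- tidyr::expand_grid(idx = seq_len(nrow(enc)),
                             visit = as.numeric(sort(visits)))
  encl <- enc[long$idx, ]
  encl$visit <- if (fit$time_unit == "visit") long$visit else long$visit * 6
  X <- build_design(encl, fit$terms)
  tibble(subject_id = enc$subject_id[long$idx],
         visit_number = as.integer(long$visit),
         pred = drop(X %*% fit$coefficients))
}

#' Simulate virtual-placebo NP-Batt trajectories
#'
#' Per replicate: one fixed-effect vector is drawn from the multivariate
#' normal of the estimates (shared across subjects); per subject an
#' (intercept, slope) deviation is drawn from the fit's G matrix; per visit
#' the value is fixed mean + intercept deviation + slope deviation times the
#' visit number + independent within-subject noise.
#'
#' @inheritParams predict_trajectory
#' @param n_replicates number of virtual datasets.
#' @param seed RNG seed or `NULL`.
#' @param parameter_uncertainty draw the fixed-effect vector per replicate
#'   (default `TRUE`).
#' @return a tibble with columns `replicate`, `subject_id`, `visit_number`,
#'   `npbatt`.
#' @export
simulate_control_trajectories <- function(fit, baselines,
                                          visits = LEGAL_VISITS,
                                          n_replicates = 1, seed = NULL,
                                          parameter_uncertainty = TRUE) {
  stopifnot(inherits(fit, "pgsa_trajectory_fit"), n_replicates >= 1)
  if (!all(visits %in% LEGAL_VISITS)) {
    abort(paste("schedule error: visit numbers must be a subset of",
                paste(LEGAL_VISITS, collapse = ", ")))
  }
  b <- as_tibble(baselines)
  with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      theta <- if (parameter_uncertainty) {
        drop(rmvn(1, fit$coefficients, fit$vcov))
      } else {
        fit$coefficients
      }
      sim <- simulate_trajectory_once(fit, b, sort(visits), theta = theta)
      sim$replicate <- r
      sim
    })
    out <- dplyr::bind_rows(reps)
    out[, c("replicate", "subject_id", "visit_number", "npbatt")]
  })
}

#' Marginal SD of a single NP-Batt observation
#'
#' Combines between-subject (random intercept and slope) and within-subject
#' variability at a given visit:
#' sqrt(sd_int^2 + t^2 sd_slope^2 + 2 t cor sd_int sd_slope + sigma_w^2).
#' Monotone increasing in t when the intercept-slope correlation is
#' non-negative.
#'
#' @param fit a `pgsa_trajectory_fit`.
#' @param visit visit number(s) (>= 0, in the fit's time unit).
#' @return numeric vector of SDs.
#' @examples
#' marginal_sd(pgsa_example_fit("trajectory"), c(0, 4, 6))
#' @export
marginal_sd <- function(fit, visit) {
  stopifnot(inherits(fit, "pgsa_trajectory_fit"), all(visit >= 0))
  r <- fit$ranef
  sqrt(r$sd_intercept^2 + visit^2 * r$sd_slope^2 +
         2 * visit * r$cor * r$sd_intercept * r$sd_slope + fit$sigma_w^2)
}

#' Simulation-based power for a slope-altering treatment effect
#'
#' Monte-Carlo power of the arm-by-time Wald test: each simulation generates
#' a control arm and a treated arm (treated slope improved by `slope_delta`
#' z-units per visit) from the trajectory model over freshly drawn synthetic
#' cohorts, fits a random-intercept/random-slope mixed model with arm and
#' arm-by-time fixed effects, and records whether the arm-by-time Wald test
#' rejects at `alpha`. Non-converged inner fits are excluded; if more than 5%
#' fail, the result carries a reliability warning.
#'
#' @param fit a `pgsa_trajectory_fit` acting as the data-generating truth.
#' @param cohort_generator function of one argument `n` returning a baseline
#'   tibble, drawing from the ambient RNG (default: [generate_baseline()]
#'   with default marginals).
#' @param n_per_arm subjects per arm.
#' @param slope_delta treatment improvement of the time slope, z-units per
#'   visit (>= 0); 0.02 per visit equals 0.04 per year.
#' @param n_sims number of simulations (>= 100).
#' @param alpha two-sided significance level.
#' @param visits visit schedule (6-month units).
#' @param seed RNG seed or `NULL`.
#' @param parameter_uncertainty draw the fixed-effect truth per simulation
#'   (shared by both arms, so it cancels from the arm contrast); default
#'   `TRUE`.
#' @return a `pgsa_power` with `$power`, `$mc_se` (binomial Monte-Carlo SE),
#'   `$n_sims`, `$n_nonconverged`.
#' @export
simulate_power_trajectory <- function(fit, cohort_generator = NULL,
                                      n_per_arm = 400, slope_delta = 0.02,
                                      n_sims = 500, alpha = 0.05,
                                      visits = LEGAL_VISITS, seed = NULL,
                                      parameter_uncertainty = TRUE) {
  stopifnot(inherits(fit, "pgsa_trajectory_fit"), n_sims >= 100,
            slope_delta >= 0, n_per_arm >= 2)
  if (is.null(cohort_generator)) {
    cohort_generator <- function(n) generate_baseline(n)
  }
  zcrit <- qnorm(1 - alpha / 2)
  visits <- sort(visits)
  with_seed(seed, {
    reject <- logical(0)
    n_fail <- 0L
    for (s in seq_len(n_sims)) {
      theta <- if (parameter_uncertainty) {
        drop(rmvn(1, fit$coefficients, fit$vcov))
      } else {
        fit$coefficients
      }
      bl_c <- cohort_generator(n_per_arm)
      bl_t <- cohort_generator(n_per_arm)
      sim_c <- simulate_trajectory_once(fit, bl_c, visits, theta = theta)
      sim_t <- simulate_trajectory_once(fit, bl_t, visits, theta = theta,
                                        slope_delta = slope_delta,
                                        treated = rep(TRUE, n_per_arm))
      d <- data.frame(
        y = c(sim_c$npbatt, sim_t$npbatt),
        t = c(sim_c$visit_number, sim_t$visit_number),
        arm = rep(c(0, 1), c(nrow(sim_c), nrow(sim_t))),
        id = factor(c(paste0("c", sim_c$subject_id),
                      paste0("t", sim_t$subject_id)))
      )
      m <- tryCatch(
        withCallingHandlers(
          lme4::lmer(y ~ arm * t + (t | id), data = d, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")),
          warning = function(w) {
            if (grepl("converge", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          }),
        error = function(e) NULL)
      conv <- !is.null(m) &&
        length(m@optinfo$conv$lme4) == 0 && m@optinfo$conv$opt == 0
      if (!conv) {
        n_fail <- n_fail + 1L
        next
      }
      tval <- summary(m)$coefficients["arm:t", "t value"]
      reject <- c(reject, abs(tval) > zcrit)
    }
    n_eff <- length(reject)
    if (!n_eff) abort("all inner fits failed to converge")
    pow <- mean(reject)
    new_power(
      power = pow, method = "monte-carlo",
      mc_se = sqrt(pow * (1 - pow) / n_eff),
      n_sims = n_eff, n_nonconverged = n_fail,
      reliability_warning = n_fail > 0.05 * n_sims,
      slope_delta_per_visit = slope_delta, n_per_arm = n_per_arm,
      alpha = alpha
    )
  })
}
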