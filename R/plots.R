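#' QQ plot of an observed-versus-simulated comparison
#'
#' @param object a `pgsa_dist_comparison` from [compare_distributions()].
#' @param ... unused.
#' @return a ggplot: simulated against observed quantiles with the identity
#'   line.
#' @export
autoplot.pgsa_dist_comparison <- function(object, ...) {
  ggplot2::ggplot(object$qq,
                  ggplot2::aes(x = .data$observed, y = .data$simulated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Observed quantiles", y = "Simulated quantiles",
                  title = "Quantile-quantile plot, simulated vs observed",
                  subtitle = sprintf("Kolmogorov-Smirnov distance %.3f",
                                     object$ks)) +
    ggplot2::theme_minimal()
}

#' Profile plot of an interaction in a fitted model
#'
#' Displays the predicted outcome against a focal covariate with the
#' moderator fixed at chosen quantiles of its distribution in `baselines` —
#' the standard way to read an interaction such as baseline FAQ modifying the
#' effect of the baseline NP-Batt on the 24-month ADAS-cog.
#'
#' @param fit a `pgsa_endpoint_fit` or `pgsa_trajectory_fit`.
#' @param baselines baseline tibble supplying the covariate distribution;
#'   non-focal covariates are fixed at their median (dummies at 0, gender at
#'   its reference).
#' @param focal name of the design column varied along the x axis.
#' @param moderator name of the design column fixed at `quantiles`.
#' @param quantiles probabilities at which the moderator is fixed.
#' @param visit for trajectory fits, the visit number at which to evaluate.
#' @param n_grid number of grid points along the focal covariate.
#' @return a ggplot with one line per moderator level.
#' @export
plot_profile <- function(fit, baselines, focal, moderator,
                         quantiles = c(0.25, 0.5, 0.75), visit = 4,
                         n_grid = 50) {
  stopifnot(inherits(fit, "pgsa_fit"))
  enc <- encode_covariates(as_tibble(baselines), fit$coding)
  vars <- setdiff(unique(unlist(lapply(fit$terms, term_parents))),
                  c("(Intercept)", "visit"))
  if (!focal %in% vars || !moderator %in% vars) {
    abort("focal and moderator must be design columns used by the fit")
  }
  base_row <- lapply(setdiff(vars, c(focal, moderator)), function(vn) {
    median(enc[[vn]], na.rm = TRUE)
  })
  names(base_row) <- setdiff(vars, c(focal, moderator))
  fr <- range(enc[[focal]], na.rm = TRUE)
  mq <- quantile(enc[[moderator]], quantiles, na.rm = TRUE, names = FALSE)
  grid <- tidyr::expand_grid(
    !!focal := seq(fr[1], fr[2], length.out = n_grid),
    !!moderator := mq
  )
  for (nm in names(base_row)) grid[[nm]] <- base_row[[nm]]
  grid$visit <- visit
  X <- build_design(grid, fit$terms)
  grid$pred <- drop(X %*% fit$coefficients)
  ylab <- if (inherits(fit, "pgsa_endpoint_fit")) {
    grid$pred <- adas_unsqrt(grid$pred)
    "Predicted ADAS-cog at month 24"
  } else {
    sprintf("Predicted NP-Batt at visit %g", visit)
  }
  grid$.moderator <- factor(signif(grid[[moderator]], 3))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[focal]], y = .data$pred,
                                     colour = .data$.moderator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = focal, y = ylab,
                  colour = sprintf("%s (quantiles)", moderator)) +
    ggplot2::theme_minimal()
}

#' Spaghetti/profile plot of simulated virtual-placebo trajectories
#'
#' @param simulated output of [simulate_control_trajectories()].
#' @param max_subjects thin to at most this many subjects per replicate.
#' @return a ggplot of NP-Batt against visit number, one line per subject,
#'   with the per-visit mean overlaid.
#' @export
plot_trajectories <- function(simulated, max_subjects = 50) {
  stopifnot(all(c("replicate", "subject_id", "visit_number", "npbatt") %in%
                  names(simulated)))
  ids <- unique(simulated$subject_id)
  keep <- head(ids, max_subjects)
  d <- simulated[simulated$subject_id %in% keep & simulated$replicate == 1, ]
  m <- dplyr::summarise(dplyr::group_by(simulated, .data$visit_number),
                        npbatt = mean(.data$npbatt), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$visit_number, y = .data$npbatt)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(data = m, linewidth = 1.2, colour = "firebrick") +
    ggplot2::labs(x = "Visit number (6-month units)", y = "NP-Batt (z)",
                  title = "Simulated virtual-placebo trajectories") +
    ggplot2::theme_minimal()
}
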