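tr <- pgsa_example_fit("trajectory")

test_that("the trajectory linear predictor reproduces published contrasts", {
  # one extra E4 allele steepens the slope by -0.03558 per visit
  bl <- make_baselines(2, apoe4 = c(0, 1))
  p <- predict_trajectory(tr, bl, visits = c(0, 4))
  slope <- function(id) diff(p$pred[p$subject_id == id]) / 4
  expect_equal(slope("T0002") - slope("T0001"), -0.03558, tolerance = 1e-10)

  # +1 baseline NP-Batt raises every visit's prediction by 0.97529
  bl <- make_baselines(2, npbatt_bl = c(-1, 0))
  p <- predict_trajectory(tr, bl, visits = c(0, 2, 6))
  d <- p$pred[p$subject_id == "T0002"] - p$pred[p$subject_id == "T0001"]
  expect_equal(d, rep(0.97529, 3), tolerance = 1e-10)

  # visit-0 predictions are untouched by any time interaction
  bl <- make_baselines(2, apoe4 = c(0, 2), adascog_bl = 18.6)
  p0 <- predict_trajectory(tr, bl, visits = 0)
  expect_equal(diff(p0$pred), 2 * 0.03383, tolerance = 1e-10) # main effect only
})

test_that("the CSF-variant fixture carries the Ab42/T-tau slope interaction", {
  trc <- pgsa_example_fit("trajectory-csf")
  bl <- make_baselines(2, csf_ratio = c(1, 3))
  p <- predict_trajectory(trc, bl, visits = c(0, 4))
  slope <- function(id) diff(p$pred[p$subject_id == id]) / 4
  # higher Ab42/T-tau flattens the decline: 2 units x 0.02229 per visit
  expect_equal(slope("T0002") - slope("T0001"), 2 * 0.02229, tolerance = 1e-10)
})

test_that("marginal SD follows the closed form and its limiting behavior", {
  # t = 0: sqrt(0.1856^2 + 0.2500^2)
  expect_equal(marginal_sd(tr, 0), sqrt(0.1856^2 + 0.25^2), tolerance = 1e-12)
  expect_equal(marginal_sd(tr, 0), 0.3114, tolerance = 1e-3)
  # no slope variance, no correlation: constant in t
  flat <- modified_trajectory_fit(sd_slope = 1e-15, cor = 0)
  expect_equal(marginal_sd(flat, c(0, 3, 6)), rep(marginal_sd(flat, 0), 3))
  # non-negative correlation: monotone increasing in t
  expect_true(all(diff(marginal_sd(tr, 0:6)) > 0))
})

test_that("simulated trajectories match the closed-form marginal covariance", {
  bl <- make_baselines(1)[rep(1, 8000), ]
  bl$subject_id <- sprintf("R%05d", seq_len(8000))
  sims <- simulate_control_trajectories(tr, bl, visits = c(0, 2, 4, 6),
                                        n_replicates = 1, seed = 71,
                                        parameter_uncertainty = FALSE)
  wide <- tidyr::pivot_wider(sims, id_cols = "subject_id",
                             names_from = "visit_number",
                             values_from = "npbatt")
  Y <- as.matrix(wide[, c("0", "2", "4", "6")])
  emp <- stats::cov(Y)
  g <- tr$ranef
  closed <- outer(c(0, 2, 4, 6), c(0, 2, 4, 6), function(s, t) {
    g$sd_intercept^2 + s * t * g$sd_slope^2 +
      (s + t) * g$cor * g$sd_intercept * g$sd_slope
  }) + diag(tr$sigma_w^2, 4)
  expect_equal(emp, closed, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("per-subject OLS random effects recover G as within-noise vanishes", {
  fit <- modified_trajectory_fit(sigma_w = 1e-3, zero_vcov = TRUE)
  bl <- make_baselines(1)[rep(1, 4000), ]
  bl$subject_id <- sprintf("Q%05d", seq_len(4000))
  sims <- simulate_control_trajectories(fit, bl, visits = c(0, 1, 2, 3, 4, 6),
                                        n_replicates = 1, seed = 72,
                                        parameter_uncertainty = FALSE)
  est <- sims |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(b0 = coef(lm(npbatt ~ visit_number))[1],
                     b1 = coef(lm(npbatt ~ visit_number))[2],
                     .groups = "drop")
  G_emp <- stats::cov(cbind(est$b0, est$b1))
  g <- fit$ranef
  G <- matrix(c(g$sd_intercept^2, g$cor * g$sd_intercept * g$sd_slope,
                g$cor * g$sd_intercept * g$sd_slope, g$sd_slope^2), 2)
  expect_equal(G_emp, G, tolerance = 0.08, ignore_attr = TRUE)
})

test_that("selection keeps random slopes when present and honors marginality", {
  set.seed(81)
  bl <- generate_baseline(350)
  co <- generate_outcomes(bl, trajectory_fit = tr, seed = 82)
  fit <- fit_trajectory(co)
  expect_lt(fit$slope_lrt$p, 0.05)
  # marginality: every interaction's parents are present
  for (tm in fit$terms[grepl(":", fit$terms)]) {
    expect_true(all(strsplit(tm, ":")[[1]] %in% fit$terms))
  }
  # refit with the selected term set reproduces the estimates
  refit <- fit_trajectory(co, terms = fit$terms)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(refit$ranef, fit$ranef, tolerance = 1e-6)
})

test_that("the random-slope LRT stays near its nominal rate under the null", {
  # truth has no slope variance and no time interactions: the chi-square(2)
  # reference is conservative at the boundary, so rejections at 0.05 should
  # be rare
  null_fit <- modified_trajectory_fit(sd_slope = 1e-12, cor = 0,
                                      zero_vcov = TRUE)
  null_fit$coefficients[grepl(":visit|^visit", names(null_fit$coefficients))] <- 0
  set.seed(83)
  rejections <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    bl <- generate_baseline(80)
    co <- generate_outcomes(bl, trajectory_fit = null_fit,
                            schedule = c(0, 1, 2, 3, 4))
    f <- suppressWarnings(fit_trajectory(co, candidates = "npbatt_bl",
                                         select = FALSE))
    if (f$slope_lrt$p < 0.05) rejections <- rejections + 1L
  }
  # binomial(20, 0.05) exceeds 3 with probability < 2%; conservatism pushes
  # the true rate below 0.05
  expect_lte(rejections, 3L)
})

test_that("refitting on the month scale rescales slope terms by exactly 1/6", {
  set.seed(84)
  bl <- generate_baseline(150)
  co <- generate_outcomes(bl, trajectory_fit = tr, seed = 85)
  terms <- c("(Intercept)", "npbatt_bl", "apoe4", "visit", "apoe4:visit")
  f_visit <- fit_trajectory(co, terms = terms)
  f_month <- fit_trajectory(co, terms = terms, time_unit = "month")
  expect_equal(f_month$coefficients["visit"],
               f_visit$coefficients["visit"] / 6, tolerance = 1e-4)
  expect_equal(f_month$coefficients["apoe4:visit"],
               f_visit$coefficients["apoe4:visit"] / 6, tolerance = 1e-4)
  expect_equal(f_month$coefficients["npbatt_bl"],
               f_visit$coefficients["npbatt_bl"], tolerance = 1e-5)
  expect_equal(f_month$ranef$sd_slope, f_visit$ranef$sd_slope / 6,
               tolerance = 1e-3)
})

test_that("the CSF variant drops subjects without a CSF value", {
  set.seed(86)
  bl <- generate_baseline(300)
  co <- generate_outcomes(bl, trajectory_fit = tr, seed = 87)
  n_csf <- sum(!is.na(bl$csf_ratio))
  f <- fit_trajectory(co, terms = c("(Intercept)", "npbatt_bl", "csf_ratio",
                                    "visit", "csf_ratio:visit"),
                      include_csf = TRUE)
  expect_equal(f$n_subjects, n_csf)
})

test_that("trajectory tidiers follow the broom.mixed layout", {
  td <- tidy(tr)
  expect_setequal(unique(td$effect), c("fixed", "ran_pars"))
  expect_equal(td$estimate[td$term == "npbatt_bl"], 0.97529)
  expect_equal(td$estimate[td$term == "sd__visit"], 0.0677)
  gl <- glance(tr)
  expect_equal(gl$sigma_w, 0.25)
  expect_equal(gl$n_subjects, 375)
})
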