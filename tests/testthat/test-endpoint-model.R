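ep <- pgsa_example_fit("endpoint")

test_that("the endpoint linear predictor reproduces published contrasts", {
  # obesity flag alone changes the sqrt-scale prediction by its coefficient
  bl <- make_baselines(2, bmi = c(26, 31))
  p <- predict_endpoint(ep, bl)
  expect_equal(diff(p$pred_sqrt), -0.27526, tolerance = 1e-10)

  # FAQ 6 vs 0 at npbatt_bl = 0: the interaction vanishes, difference 6 x 0.07902
  bl <- make_baselines(2, faq = c(6, 0), npbatt_bl = 0)
  p <- predict_endpoint(ep, bl)
  expect_equal(p$pred_sqrt[1] - p$pred_sqrt[2], 6 * 0.07902, tolerance = 1e-10)

  # intercept-only fit predicts the intercept for any subject
  int_only <- ep
  int_only$terms <- "(Intercept)"
  int_only$coefficients <- c("(Intercept)" = 3.84232)
  int_only$vcov <- matrix(0.76473^2, 1, 1,
                          dimnames = list("(Intercept)", "(Intercept)"))
  p <- predict_endpoint(int_only, make_baselines(1))
  expect_equal(p$pred_sqrt, 3.84232)
})

test_that("degenerate noise collapses simulation to the deterministic prediction", {
  fit0 <- zero_vcov_endpoint(sigma = 1e-12)
  bl <- make_baselines(3, adascog_bl = c(10, 18.6, 40))
  sims <- simulate_control_endpoints(fit0, bl, n_replicates = 5, seed = 1)
  pred <- predict_endpoint(fit0, bl)
  for (r in 1:5) expect_equal(unname(sims[r, ]), pred$pred, tolerance = 1e-6)
})

test_that("simulated sqrt-scale dispersion matches the residual SD and x'Sx + s2", {
  bl <- make_baselines(1) # one covariate profile: between-subject spread is 0
  sims <- simulate_control_endpoints(zero_vcov_endpoint(), bl[rep(1, 4000), ],
                                     n_replicates = 1, seed = 2)
  expect_equal(sd(sqrt(sims[1, ])), 0.669, tolerance = 0.03)

  # with parameter uncertainty the sqrt-scale variance is x'Sigma x + sigma^2
  sims <- simulate_control_endpoints(ep, bl, n_replicates = 20000, seed = 3)
  enc <- encode_covariates(bl, ep$coding)
  x <- drop(pgsa:::build_design(enc, ep$terms))
  expect_equal(var(sqrt(sims[, 1])),
               drop(x %*% ep$vcov %*% x) + ep$sigma^2, tolerance = 0.05)
})

test_that("analytic power is calibrated at the null and monotone in n", {
  expect_equal(analytic_power(0, 0.669, 286)$power, 0.05, tolerance = 1e-10)
  pows <- vapply(c(50, 100, 200, 400, 800),
                 function(n) analytic_power(0.16, 0.669, n)$power, numeric(1))
  expect_true(all(diff(pows) > 0))
  # one-sided test is more powerful at the same alpha
  expect_gt(analytic_power(0.16, 0.669, 286, sided = 1)$power,
            analytic_power(0.16, 0.669, 286, sided = 2)$power)
  expect_error(analytic_power(-0.1, 0.669, 286), "effect")
})

test_that("stepwise AIC selection recovers structure and is idempotent", {
  set.seed(51)
  bl <- generate_baseline(1500)
  co <- generate_outcomes(bl, endpoint_fit = zero_vcov_endpoint(), seed = 52)
  fit <- fit_endpoint(co)
  # true support is recovered (extra AIC-kept terms are allowed)
  expect_true(all(ep$terms %in% fit$terms))
  # refitting the selected term set on the same data reproduces the fit
  refit <- fit_endpoint(co, terms = fit$terms)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(refit$sigma, fit$sigma, tolerance = 1e-12)
  # final model cannot have higher AIC than the full main-effects start
  full <- fit_endpoint(co, select = FALSE)
  expect_lte(fit$aic, full$aic)
})

test_that("a pure-noise outcome yields a near-empty model", {
  set.seed(61)
  bl <- generate_baseline(2000)
  v <- tibble::tibble(subject_id = bl$subject_id, visit_number = 4L,
                      adascog = pmin(pmax(rnorm(2000, 20, 5), 0), 85),
                      npbatt = NA_real_)
  fit <- fit_endpoint(cohort(bl, v))
  # AIC retains a noise term with probability ~0.16 each; allow a few
  expect_lte(length(setdiff(fit$terms, "(Intercept)")), 3)
})

test_that("endpoint fitting reports informative errors", {
  bl <- make_baselines(5)
  v <- tibble::tibble(subject_id = bl$subject_id, visit_number = 1L,
                      adascog = 20, npbatt = NA_real_)
  expect_error(fit_endpoint(cohort(bl, v)), "sample-size")
  v4 <- tibble::tibble(subject_id = bl$subject_id, visit_number = 4L,
                       adascog = 20 + seq_len(5), npbatt = NA_real_)
  expect_error(fit_endpoint(cohort(bl, v4)), "sample-size|collinearity")
})

test_that("tidy and glance expose the fit in broom form", {
  td <- tidy(ep)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[td$term == "adascog_bl"], 0.0925)
  expect_equal(td$std.error[td$term == "gender"], 0.08387, tolerance = 1e-6)
  gl <- glance(ep)
  expect_equal(gl$sigma, 0.669)
  expect_equal(gl$n, 286)
})
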