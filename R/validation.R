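#' Subject-level k-fold cross-validation of a fitted model
#'
#' Splits subjects into `k` folds (a subject's visits never straddle folds),
#' refits the model with its already-selected term set on each training set,
#' predicts the held-out responses, and pools the prediction error on the
#' model's working scale: the square-root ADAS-cog scale for the endpoint
#' model, the z scale (fixed-effects predictions) for the trajectory model.
#'
#' @param data a `pgsa_cohort`.
#' @param fit a `pgsa_endpoint_fit` or `pgsa_trajectory_fit` whose term set
#'   defines the model to refit per fold.
#' @param k number of folds (>= 2); `k` equal to the subject count gives
#'   leave-one-out.
#' @param seed RNG seed for the random split, or `NULL`.
#' @param error `"rmse"` (root-mean-square, default — directly comparable to
#'   a residual SD) or `"mae"` (mean absolute error).
#' @return a `pgsa_cv` object; the pooled error is `$error`, per-fold errors
#'   in `$per_fold`.
#' @export
kfold_cv <- function(data, fit, k = 5, seed = NULL,
                     error = c("rmse", "mae")) {
  stopifnot(inherits(data, "pgsa_cohort"), inherits(fit, "pgsa_fit"), k >= 2)
  error <- match.arg(error)
  is_ep <- inherits(fit, "pgsa_endpoint_fit")

  subj <- if (is_ep) {
    unique(data$visits$subject_id[data$visits$visit_number == 4L &
                                    !is.na(data$visits$adascog)])
  } else {
    unique(data$visits$subject_id[!is.na(data$visits$npbatt)])
  }
  if (k > length(subj)) abort("fold-size error: more folds than subjects")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), length(subj)))
  })
  names(fold) <- subj

  res <- lapply(seq_len(k), function(f) {
    test_ids <- subj[fold == f]
    train_ids <- setdiff(subj, test_ids)
    min_needed <- length(fit$terms) + 2L
    if (length(train_ids) < min_needed) {
      abort("fold-size error: a training fold is too small to fit the model")
    }
    train <- cohort(data$baselines[data$baselines$subject_id %in% train_ids, ],
                    data$visits[data$visits$subject_id %in% train_ids, ])
    test_bl <- data$baselines[data$baselines$subject_id %in% test_ids, ]
    if (is_ep) {
      refit <- fit_endpoint(train, coding = fit$coding, terms = fit$terms)
      pred <- predict_endpoint(refit, test_bl)
      obs <- data$visits[data$visits$subject_id %in% test_ids &
                           data$visits$visit_number == 4L &
                           !is.na(data$visits$adascog), ]
      err <- adas_sqrt(obs$adascog) -
        pred$pred_sqrt[match(obs$subject_id, pred$subject_id)]
    } else {
      refit <- fit_trajectory(train, coding = fit$coding, terms = fit$terms,
                              time_unit = fit$time_unit)
      obs <- data$visits[data$visits$subject_id %in% test_ids &
                           !is.na(data$visits$npbatt), ]
      pred <- predict_trajectory(refit, test_bl,
                                 visits = sort(unique(obs$visit_number)))
      key_o <- paste(obs$subject_id, obs$visit_number)
      key_p <- paste(pred$subject_id, pred$visit_number)
      err <- obs$npbatt - pred$pred[match(key_o, key_p)]
    }
    tibble(fold = f, n = length(err),
           error = if (error == "rmse") sqrt(mean(err^2)) else mean(abs(err)),
           sq_sum = sum(err^2), abs_sum = sum(abs(err)))
  })
  per_fold <- dplyr::bind_rows(res)
  pooled <- if (error == "rmse") {
    sqrt(sum(per_fold$sq_sum) / sum(per_fold$n))
  } else {
    sum(per_fold$abs_sum) / sum(per_fold$n)
  }
  structure(
    list(error = pooled, metric = error, k = k,
         scale = if (is_ep) "sqrt(ADAS-cog)" else "z (NP-Batt)",
         n_predictions = sum(per_fold$n),
         per_fold = per_fold[, c("fold", "n", "error")]),
    class = "pgsa_cv"
  )
}

#' @export
print.pgsa_cv <- function(x, ...) {
  cat(sprintf("<pgsa %d-fold cross-validation>\n", x$k))
  cat(sprintf("  pooled %s prediction error: %.4f on the %s scale (%d predictions)\n",
              toupper(x$metric), x$error, x$scale, x$n_predictions))
  invisible(x)
}

#' Variance inflation factors
#'
#' Multicollinearity screen for the quantitative predictors: each predictor
#' is regressed on the others and VIF = 1 / (1 - R^2). Two predictors with
#' correlation 0.8 yield VIF = 1 / (1 - 0.64) = 2.78; VIF is always >= 1. A
#' perfectly collinear predictor is reported as `Inf` with a warning.
#'
#' @param data a baseline tibble or `pgsa_cohort` (its baselines are used).
#' @param predictors quantitative design columns to screen; the default is
#'   the continuous covariates plus the ApoE4 allele count (binary dummies
#'   excluded).
#' @param coding a [coding_config()].
#' @return a tibble with columns `predictor`, `vif`, in input order.
#' @export
vif <- function(data,
                predictors = c("age", "education", "bmi", "apoe4", "hachinski",
                               "faq_bl", "mmse_bl", "adascog_bl", "npbatt_bl"),
                coding = coding_config()) {
  if (inherits(data, "pgsa_cohort")) data <- data$baselines
  enc <- encode_covariates(as_tibble(data), coding)
  if ("bmi" %in% predictors && !"bmi" %in% names(enc)) {
    enc$bmi <- as_tibble(data)$bmi
  }
  if (length(predictors) < 2L) abort("need at least 2 predictors")
  miss <- setdiff(predictors, names(enc))
  if (length(miss)) abort(paste("unknown predictor(s):", paste(miss, collapse = ", ")))
  M <- as.data.frame(enc[, predictors])
  M <- M[complete.cases(M), , drop = FALSE]
  zero_var <- vapply(M, function(col) var(col) == 0, logical(1))
  if (any(zero_var)) {
    abort(paste("predictor(s) with zero variance:",
                paste(predictors[zero_var], collapse = ", ")))
  }
  v <- vapply(predictors, function(p) {
    m <- lm(stats::reformulate(setdiff(predictors, p), response = p), data = M)
    r2 <- 1 - sum(stats::residuals(m)^2) / sum((M[[p]] - mean(M[[p]]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(v))) {
    warn(paste("perfectly collinear predictor(s):",
               paste(predictors[is.infinite(v)], collapse = ", ")))
  }
  tibble(predictor = predictors, vif = unname(v))
}

#' Compare an observed and a simulated score distribution
#'
#' Emits the seven standard descriptives (minimum, first quartile, median,
#' mean, third quartile, maximum, SD) for each sample and their differences,
#' paired quantiles for a quantile-quantile plot (plotting positions
#' (i - 0.5)/n of the smaller sample; the larger sample linearly
#' interpolated), and the Kolmogorov-Smirnov distance as a single-number
#' summary. Samples of unequal size are accepted.
#'
#' @param observed,simulated non-empty numeric vectors.
#' @return a `pgsa_dist_comparison`: `$summary` (tibble statistic/observed/
#'   simulated/difference), `$qq` (tibble of paired quantiles), `$ks`
#'   (KS distance). Supports [autoplot()].
#' @export
compare_distributions <- function(observed, simulated) {
  observed <- observed[!is.na(observed)]
  simulated <- simulated[!is.na(simulated)]
  if (!length(observed) || !length(simulated)) {
    abort("both samples must be non-empty")
  }
  desc <- function(x) {
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    c(minimum = q[1], first_quartile = q[2], median = q[3], mean = mean(x),
      third_quartile = q[4], maximum = q[5], sd = sd(x))
  }
  d_obs <- desc(observed)
  d_sim <- desc(simulated)
  summary_tbl <- tibble(
    statistic = names(d_obs),
    observed = unname(d_obs),
    simulated = unname(d_sim),
    difference = unname(d_sim - d_obs)
  )
  n_small <- min(length(observed), length(simulated))
  probs <- (seq_len(n_small) - 0.5) / n_small
  qq <- tibble(
    prob = probs,
    observed = quantile(observed, probs, names = FALSE),
    simulated = quantile(simulated, probs, names = FALSE)
  )
  ks <- suppressWarnings(
    unname(ks.test(observed, simulated)$statistic))
  structure(list(summary = summary_tbl, qq = qq, ks = ks),
            class = "pgsa_dist_comparison")
}

#' @export
print.pgsa_dist_comparison <- function(x, ...) {
  cat("<pgsa distribution comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  cat(sprintf("Kolmogorov-Smirnov distance: %.4f\n", x$ks))
  invisible(x)
}
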