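test_that("cohort files round-trip losslessly and months map to visit numbers", {
  f <- tiny_cohort_file()
  co <- read_cohort(f)
  expect_s3_class(co, "pgsa_cohort")
  expect_equal(nrow(co$baselines), 2L)
  expect_equal(nrow(co$visits), 6L)
  # month 36 is visit 6, month 24 is visit 4; there is no visit 5
  expect_setequal(co$visits$visit_number[co$visits$subject_id == "A"],
                  c(0L, 1L, 4L))
  expect_setequal(co$visits$visit_number[co$visits$subject_id == "B"],
                  c(0L, 1L, 6L))

  f2 <- tempfile(fileext = ".csv")
  write_cohort(co, f2)
  co2 <- read_cohort(f2)
  expect_equal(co2$baselines, co$baselines)
  expect_equal(dplyr::arrange(co2$visits, subject_id, visit_number),
               dplyr::arrange(co$visits, subject_id, visit_number))
})

test_that("full legal month schedule maps to visit numbers 0,1,2,3,4,6", {
  rows <- sprintf("C,%d,70,male,12,24,0,0,0,28,%g,%g,,0",
                  c(0, 6, 12, 18, 24, 36), 10 + 0:5, -0.1 * (0:5))
  f <- tempfile(fileext = ".csv")
  writeLines(c(readLines(tiny_cohort_file())[1], rows), f)
  co <- read_cohort(f)
  expect_equal(sort(co$visits$visit_number), c(0L, 1L, 2L, 3L, 4L, 6L))
})

test_that("invalid rows are rejected with named per-row reports", {
  f <- tiny_cohort_file()
  lines <- readLines(f)

  bad <- sub("29,10.0", "31,10.0", lines[5], fixed = TRUE) # mmse = 31
  writeLines(c(lines[-5], bad), f)
  expect_error(read_cohort(f), "mmse")

  writeLines(c(lines, lines[3]), f) # duplicate (A, 6)
  expect_error(read_cohort(f), "duplicated")

  writeLines(sub("visit_month", "month", lines), f) # missing mandatory column
  expect_error(read_cohort(f), "schema error")

  writeLines(c(lines[1], sub(",6,", ",30,", lines[3])), f) # month 30 illegal
  expect_error(read_cohort(f), "visit_month")
})

test_that("cohort invariants catch range and integrity violations", {
  bl <- make_baselines(2)
  v <- tibble::tibble(subject_id = c("T0001", "T0002"), visit_number = 4L,
                      adascog = c(20, 30), npbatt = NA_real_)
  expect_s3_class(cohort(bl, v), "pgsa_cohort")

  bl_bad <- bl; bl_bad$apoe4 <- c(1, 3)
  expect_error(cohort(bl_bad, v), "apoe4")
  v_bad <- v; v_bad$visit_number <- c(4L, 5L)
  expect_error(cohort(bl, v_bad), "visit_number")
  v_bad <- v; v_bad$subject_id[2] <- "ghost"
  expect_error(cohort(bl, v_bad), "unknown subject")
  v_bad <- v; v_bad$adascog[2] <- NA
  expect_error(cohort(bl, v_bad), "no outcome")
})

test_that("NP-Batt composite matches hand-computed z-score arithmetic", {
  norms <- npbatt_norms(mean = c(10, 8, 6, 20, 14, 90, 27, 40, 45),
                        sd = c(4, 2, 2, 5, 4, 30, 3, 9, 10))
  at_norm <- setNames(as.list(norms$mean), norms$subtest)
  expect_equal(compute_np_batt(as.data.frame(at_norm), norms), 0)

  # every subtest 1 SD better than the norm (Trail Making B: 1 SD *faster*)
  better <- norms$mean + ifelse(norms$higher_better, 1, -1) * norms$sd
  one_up <- setNames(as.list(better), norms$subtest)
  expect_equal(compute_np_batt(as.data.frame(one_up), norms), 1)

  # frozen hand-computed case: z = (0.5, -0.5, 0.5, 0.6, -0.5, -1.0,
  # -1/3, 1.0, 0.5), mean = 0.0851852
  x <- setNames(as.list(c(12, 7, 7, 23, 12, 120, 26, 49, 50)), norms$subtest)
  expect_equal(compute_np_batt(as.data.frame(x), norms), 0.76666667 / 9,
               tolerance = 1e-7)

  # invariant to subtest column order; linear in one oriented z
  shuffled <- as.data.frame(x)[, sample(9)]
  expect_equal(compute_np_batt(shuffled, norms),
               compute_np_batt(as.data.frame(x), norms))
  x2 <- x; x2$avlt <- x2$avlt + 9 # one more SD on one subtest
  expect_equal(compute_np_batt(as.data.frame(x2), norms),
               compute_np_batt(as.data.frame(x), norms) + 1 / 9)

  expect_error(compute_np_batt(as.data.frame(x)[-1], norms), "missing subtest")
  norms_bad <- norms; norms_bad$sd[3] <- 0
  expect_error(compute_np_batt(as.data.frame(x), norms_bad), "degenerate")
})

test_that("covariate encoding produces the documented dummies and codings", {
  bl <- make_baselines(4, bmi = c(22, 26.1, 31, 30), apoe4 = c(0, 1, 2, 2),
                       gender = c("female", "male", "female", "male"))
  enc <- encode_covariates(bl)
  expect_equal(enc$bmi2, c(0, 1, 0, 0))
  expect_equal(enc$bmi3, c(0, 0, 1, 1))
  expect_equal(enc$obesity, c(0, 0, 1, 1))
  expect_equal(enc$apoe4, c(0, 1, 2, 2)) # numeric allele count
  expect_equal(enc$gender, c(1, 0, 1, 0)) # female = 1 by default

  flipped <- encode_covariates(bl, coding_config(gender_reference = "female"))
  expect_equal(flipped$gender, 1 - enc$gender)

  wide <- encode_covariates(bl, coding_config(obesity_definition = "bmi2_or_3"))
  expect_equal(wide$obesity, c(0, 1, 1, 1))

  dummies <- as.matrix(enc[, c("gender", "bmi2", "bmi3", "obesity")])
  expect_true(all(dummies %in% c(0, 1)))
})

test_that("square-root transform and inverse behave at bounds", {
  expect_equal(adas_sqrt(0), 0)
  expect_equal(adas_unsqrt(adas_sqrt(18.6)), 18.6)
  expect_equal(adas_unsqrt(9.5), 85) # 9.5^2 > 85, clipped
  expect_equal(adas_unsqrt(-1), 0) # floored before squaring
  expect_error(adas_sqrt(-0.5), "0")
  expect_error(adas_sqrt(86), "85")
})

test_that("model artifacts serialize and restore losslessly", {
  ep <- pgsa_example_fit("endpoint")
  f <- tempfile(fileext = ".json")
  write_model_artifact(ep, f, seed = 7)
  ep2 <- read_model_artifact(f)
  expect_equal(ep2$coefficients, ep$coefficients)
  expect_equal(ep2$vcov, ep$vcov)
  expect_equal(ep2$sigma, ep$sigma)
  expect_equal(ep2$transform, "sqrt")

  tr <- pgsa_example_fit("trajectory")
  write_model_artifact(tr, f)
  tr2 <- read_model_artifact(f)
  expect_equal(tr2$coefficients, tr$coefficients)
  expect_equal(tr2$ranef, tr$ranef)
  expect_equal(tr2$sigma_w, tr$sigma_w)
  doc <- jsonlite::read_json(f)
  expect_true(!is.null(doc$provenance$package))
})
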