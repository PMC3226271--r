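#' The nine NP-Batt subtests
#'
#' Names of the subtests entering the neuropsychological composite, in
#' canonical order. Trail Making B is timed (lower raw score = better) and is
#' sign-flipped in the composite; all other subtests score higher = better.
#'
#' @format character vector of length 9.
#' @export
npbatt_subtests <- c(
  "logical_memory_ii",
  "digit_span_forward",
  "digit_span_backward",
  "category_fluency_animals",
  "category_fluency_vegetables",
  "trail_making_b",
  "boston_naming",
  "avlt",
  "digit_symbol"
)

#' Normative table skeleton for the NP-Batt composite
#'
#' Builds the norms table [compute_np_batt()] expects: one row per subtest
#' with the normative mean and SD (from cognitively normal controls) and the
#' score orientation.
#'
#' @param mean,sd numeric vectors of length 9, in [npbatt_subtests] order.
#' @param higher_better logical vector of length 9; defaults to `TRUE` for all
#'   subtests except Trail Making B (a timed test, where lower = better).
#' @return a tibble with columns `subtest`, `mean`, `sd`, `higher_better`.
#' @export
npbatt_norms <- function(mean, sd,
                         higher_better = npbatt_subtests != "trail_making_b") {
  stopifnot(length(mean) == 9L, length(sd) == 9L, length(higher_better) == 9L)
  tibble(subtest = npbatt_subtests, mean = as.numeric(mean),
         sd = as.numeric(sd), higher_better = as.logical(higher_better))
}

#' Neuropsychological composite (NP-Batt) z-score
#'
#' The NP-Batt is the arithmetic mean of nine per-subtest z-scores, each
#' standardized against the normative mean and SD of cognitively normal
#' controls. Subtests where a lower raw score is better (Trail Making B) are
#' sign-flipped so that a higher composite always means better performance.
#'
#' @param scores a data frame with one row per subject and one column per
#'   subtest (all nine of [npbatt_subtests] must be present), or a named
#'   numeric vector for a single subject.
#' @param norms a norms table as built by [npbatt_norms()].
#' @return a numeric vector of composite z-scores, one per subject.
#' @examples
#' norms <- npbatt_norms(mean = c(12, 8, 7, 20, 14, 80, 27, 43, 45),
#'                       sd   = c(4, 2, 2, 5, 4, 40, 3, 9, 10))
#' scores <- setNames(as.list(norms$mean), norms$subtest)
#' compute_np_batt(as.data.frame(scores), norms) # all at norm -> 0
#' @export
compute_np_batt <- function(scores, norms) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- as_tibble(as.list(scores))
  }
  scores <- as_tibble(scores)
  missing_sub <- setdiff(npbatt_subtests, names(scores))
  if (length(missing_sub)) {
    abort(paste("incomplete input: missing subtest(s)",
                paste(missing_sub, collapse = ", ")))
  }
  norms <- as_tibble(norms)
  stopifnot(all(c("subtest", "mean", "sd", "higher_better") %in% names(norms)))
  norms <- norms[match(npbatt_subtests, norms$subtest), ]
  if (anyNA(norms$subtest)) abort("norms must cover all nine subtests")
  if (any(norms$sd <= 0)) abort("degenerate norms: each norm SD must be > 0")
  z <- mapply(function(sub, m, s, hb) {
    zz <- (as.numeric(scores[[sub]]) - m) / s
    if (hb) zz else -zz
  }, norms$subtest, norms$mean, norms$sd, norms$higher_better,
  SIMPLIFY = FALSE)
  rowMeans(do.call(cbind, z))
}
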