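# Relaxed completion thresholds for series incentives. ANC, PNC and
# immunization incentives pay a single lump sum for completing a series of K
# component activities; observed payments exceed the strict-rule expectation
# because full payment is made for partial completion. The mechanism is
# formalised as a threshold k on the completion count: payment occurs when
# count >= k, with k = full_threshold being the designed (strict) rule.

#' Distribution of series completion counts
#'
#' Probabilities `p_0 .. p_K` over the number of components of a series
#' incentive actually completed per beneficiary (conditional on CHW contact
#' where the series is a household behavior).
#'
#' @param incentive_id id of the series incentive the distribution belongs to.
#' @param probabilities numeric vector of length `K + 1` (counts `0..K`),
#'   nonnegative, summing to 1.
#' @return object of class `series_distribution`.
#' @export
series_distribution <- function(incentive_id, probabilities) {
  if (!is.character(incentive_id) || length(incentive_id) != 1L) {
    chw_abort("`incentive_id` must be a string")
  }
  p <- as.numeric(probabilities)
  if (length(p) < 2L) chw_abort("need probabilities for counts 0..K with K >= 1")
  if (any(!is.finite(p)) || any(p < 0)) {
    chw_abort("completion-count probabilities must be finite and >= 0")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    chw_abort(sprintf("completion-count probabilities must sum to 1 (got %.10f)", sum(p)))
  }
  structure(list(incentive_id = incentive_id, probabilities = p,
                 K = length(p) - 1L),
            class = "series_distribution")
}

#' Read series distributions from CSV
#'
#' Expected columns: `incentive_id`, `count`, `probability`; counts `0..K`
#' per incentive.
#'
#' @param path CSV path.
#' @return named list of [series_distribution()] objects keyed by id.
#' @export
load_series_distributions <- function(path) {
  if (!file.exists(path)) chw_abort(sprintf("series distribution file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("incentive_id", "count", "probability"), names(df))
  if (length(missing_cols)) {
    chw_abort(sprintf("series CSV missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  out <- lapply(split(df, df$incentive_id), function(d) {
    d <- d[order(d$count), ]
    if (!identical(as.integer(d$count), seq(0L, nrow(d) - 1L))) {
      chw_abort(sprintf("counts for '%s' must be 0..K with no gaps", d$incentive_id[1]))
    }
    series_distribution(d$incentive_id[1], d$probability)
  })
  out[order(names(out))]
}

check_series_pair <- function(inc, dist) {
  stopifnot(inherits(inc, "incentive_definition"),
            inherits(dist, "series_distribution"))
  if (is.null(inc$series)) {
    chw_contract_error(sprintf("incentive '%s' has no series specification", inc$id))
  }
  if (dist$K != inc$series$n_components) {
    chw_contract_error(sprintf(
      "distribution covers counts 0..%d but incentive '%s' has %d components",
      dist$K, inc$id, inc$series$n_components))
  }
}

#' Expected monthly payment of a series incentive under threshold k
#'
#' Pays the full lump sum when the completion count reaches `threshold`:
#' expected payment = incidence x P(count >= threshold) x amount. At
#' `threshold = full_threshold` this is the designed strict-rule expectation;
#' smaller thresholds model relaxed payment (e.g. paying for 1+ antenatal
#' check-ups instead of 4+). Non-increasing in `threshold` and never above
#' `incidence x amount`.
#'
#' @param inc a series [incentive()].
#' @param dist a [series_distribution()] with `K == n_components`.
#' @param threshold integer `1 <= k <= n_components`.
#' @param incidence claimable beneficiary events per month (after any CHW
#'   contact rate has been applied).
#' @return expected INR per month.
#' @export
expected_series_payment <- function(inc, dist, threshold, incidence) {
  check_series_pair(inc, dist)
  assert_scalar_number(incidence, "incidence")
  if (incidence < 0) chw_contract_error("incidence must be >= 0")
  if (!is_scalar_number(threshold) || threshold != round(threshold) ||
      threshold < 1 || threshold > inc$series$n_components) {
    chw_contract_error(sprintf(
      "threshold must be an integer in 1..%d", inc$series$n_components))
  }
  p_ge <- sum(dist$probabilities[(threshold + 1):(dist$K + 1)])
  incidence * p_ge * inc$amount
}

#' Fit the completion threshold that best explains observed payments
#'
#' Evaluates [expected_series_payment()] for every threshold
#' `k = 1 .. full_threshold` and returns the k whose expectation is closest
#' to the observed mean monthly payment in absolute rupees. Ties break toward
#' the largest k (the explanation closest to the designed rule).
#'
#' @param inc a series [incentive()].
#' @param dist a [series_distribution()].
#' @param incidence claimable beneficiary events per month.
#' @param observed observed mean monthly payment (INR); must be >= 0.
#' @return object of class `relaxation_result`: `incentive_id`,
#'   `fitted_threshold`, `expected_payment`, `observed_payment`,
#'   `discrepancy`, and the full `candidates` table of (threshold, expected,
#'   discrepancy).
#' @export
fit_relaxation <- function(inc, dist, incidence, observed) {
  check_series_pair(inc, dist)
  assert_scalar_number(observed, "observed")
  if (observed < 0) chw_contract_error("observed payment must be >= 0")
  ks <- seq_len(inc$series$full_threshold)
  expected <- vapply(ks, function(k)
    expected_series_payment(inc, dist, k, incidence), numeric(1))
  disc <- abs(expected - observed)
  best <- max(ks[disc == min(disc)])  # tie-break: least-relaxed rule
  structure(
    list(incentive_id = inc$id,
         fitted_threshold = best,
         expected_payment = expected[best],
         observed_payment = observed,
         discrepancy = disc[best],
         candidates = data.frame(threshold = ks, expected = expected,
                                 discrepancy = disc)),
    class = "relaxation_result"
  )
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf(
    "<relaxation_result> '%s': fitted threshold %d+ (expected INR %.0f vs observed INR %.0f)\n",
    x$incentive_id, x$fitted_threshold, x$expected_payment, x$observed_payment))
  print(x$candidates)
  invisible(x)
}
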