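# Estimation of rate inputs and descriptive results (awareness, payment
# delays, claim experience) from linked survey microdata.

#' Binomial proportion with confidence interval
#'
#' Wilson score interval by default; for small denominators (n < 30) or
#' boundary counts (0 or n successes) the exact Clopper-Pearson interval from
#' [stats::binom.test()] is used instead. The source analysis reports no
#' intervals, so the interval is presentation-only.
#'
#' @param item label.
#' @param x success count.
#' @param n denominator (> 0).
#' @param level confidence level.
#' @return one-row data frame: `item`, `numerator`, `denominator`,
#'   `proportion`, `ci_lower`, `ci_upper`.
#' @export
prop_summary <- function(item, x, n, level = 0.95) {
  if (!is_scalar_number(n) || n <= 0 || n != round(n)) {
    chw_contract_error("`n` must be a positive integer")
  }
  if (!is_scalar_number(x) || x < 0 || x > n) {
    chw_contract_error("`x` must lie in 0..n")
  }
  p <- x / n
  if (n < 30 || x == 0 || x == n) {
    ci <- stats::binom.test(x, n, conf.level = level)$conf.int
    lo <- ci[1]; hi <- ci[2]
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  }
  data.frame(item = item, numerator = as.integer(x), denominator = as.integer(n),
             proportion = p, ci_lower = lo, ci_upper = hi,
             stringsAsFactors = FALSE)
}

#' Estimate CHW action and household behavior rates from microdata
#'
#' Action rates are the share of eligible beneficiaries with CHW contact
#' (routine action rates come from per-CHW-month completion flags in
#' `chw_months`); behavior rates are the share with the outcome *among
#' beneficiaries with the required contact* (conditional estimation -- the
#' engine never uses unconditional population rates). Series completion keys
#' are estimated as the share of completion counts reaching the full
#' threshold, conditional on contact where applicable. Strata with an empty
#' denominator are omitted with a warning rather than returned as 0/0.
#'
#' @param households microdata from [generate_microdata()] (or read back via
#'   [read_microdata()]).
#' @param catalog the `incentive_catalog` defining key ownership; defaults to
#'   [fixture_catalog()].
#' @param chw_months optional per-CHW-month routine flags.
#' @return a [rate_set()] with provenance `"ESTIMATED"`.
#' @export
estimate_rates <- function(households, catalog = fixture_catalog(),
                           chw_months = NULL) {
  stopifnot(is.data.frame(households), inherits(catalog, "incentive_catalog"))
  num <- list(); den <- list()
  tally <- function(key, successes, trials) {
    num[[key]] <<- (num[[key]] %||% 0) + successes
    den[[key]] <<- (den[[key]] %||% 0) + trials
  }
  col <- function(nm) if (nm %in% names(households)) households[[nm]] else NULL

  for (inc in catalog) {
    if (inc$scaling == "FIXED") next
    rows <- households$incentive_id == inc$id
    if (!any(rows)) next
    own_action_series <- !is.null(inc$series) && length(inc$behavior_keys) == 0L

    contact_all <- rep(TRUE, sum(rows))
    if (!own_action_series) {
      for (key in inc$action_keys) {
        flag <- col(paste0("contact_", key))[rows]
        if (is.null(flag)) next
        keep <- !is.na(flag)
        tally(key, sum(flag[keep] == 1L), sum(keep))
        contact_all <- contact_all & !is.na(flag) & flag == 1L
      }
    }
    if (!is.null(inc$series)) {
      count <- col("series_count")[rows]
      kf <- inc$series$full_threshold
      if (own_action_series) {
        keep <- !is.na(count)
        tally(inc$action_keys[1], sum(count[keep] >= kf), sum(keep))
      } else if (length(inc$behavior_keys) == 1L) {
        keep <- contact_all & !is.na(count)
        tally(inc$behavior_keys[1], sum(count[keep] >= kf), sum(keep))
      }
    } else {
      for (key in inc$behavior_keys) {
        out <- col(paste0("outcome_", key))[rows]
        if (is.null(out)) next
        keep <- contact_all & !is.na(out)
        tally(key, sum(out[keep] == 1L), sum(keep))
      }
    }
  }

  if (!is.null(chw_months)) {
    routine_keys <- unique(unlist(lapply(
      Filter(function(i) i$scaling == "FIXED", catalog), `[[`, "action_keys")))
    for (key in routine_keys) {
      nm <- paste0("flag_", key)
      if (nm %in% names(chw_months)) {
        flag <- chw_months[[nm]]
        tally(key, sum(flag == 1L, na.rm = TRUE), sum(!is.na(flag)))
      }
    }
  }

  keys <- names(num)
  empty <- keys[unlist(den[keys]) == 0]
  if (length(empty)) {
    warning(sprintf("rate(s) omitted, empty conditioning stratum: %s",
                    paste(empty, collapse = ", ")))
    keys <- setdiff(keys, empty)
  }
  if (!length(keys)) chw_abort("no estimable rates in the supplied microdata")
  rate_set(stats::setNames(unlist(num[keys]) / unlist(den[keys]), keys),
           provenance = "ESTIMATED")
}

#' Claim-experience descriptives
#'
#' One [prop_summary()] row per questionnaire item: payment perceived
#' difficult, frequent delays, payment breakup unknown, partial payment,
#' sign-off hard, paying to get incentives, payment covering 2+ months of
#' work, and the three last-payment recency categories (which sum to 100%).
#'
#' @param chws CHW questionnaire data frame.
#' @param level confidence level for the intervals.
#' @return data frame of class `survey_summary`.
#' @export
claim_experience_summary <- function(chws, level = 0.95) {
  stopifnot(is.data.frame(chws))
  n <- nrow(chws)
  if (n == 0L) chw_contract_error("no questionnaire responses")
  items <- c("payment_difficult", "delays_frequent", "unknown_breakup",
             "partial_payment", "signoff_hard", "pay_to_get",
             "months_covered_2plus")
  rows <- lapply(intersect(items, names(chws)), function(it)
    prop_summary(it, sum(chws[[it]], na.rm = TRUE), n, level))
  if ("last_payment_recency" %in% names(chws)) {
    for (lev in c("1_month", "2_months", "3plus_months")) {
      rows[[length(rows) + 1L]] <- prop_summary(
        paste0("recency_", lev), sum(chws$last_payment_recency == lev), n, level)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("survey_summary", "data.frame")
  out
}

#' Incentive-amount awareness descriptives
#'
#' For the institutional-delivery awareness item: share aware an incentive
#' exists, share quoting the exact amount, and the modal wrong answer with
#' its share of all respondents. Enforces the invariant that an
#' exact-amount-correct response implies awareness.
#'
#' @param chws CHW questionnaire data frame.
#' @param correct_amount the true incentive amount (default INR 300).
#' @param level confidence level.
#' @return data frame of class `survey_summary`; the modal wrong answer is
#'   attached as attribute `modal_wrong_amount`.
#' @export
awareness_summary <- function(chws, correct_amount = 300, level = 0.95) {
  stopifnot(is.data.frame(chws))
  n <- nrow(chws)
  if (n == 0L) chw_contract_error("no questionnaire responses")
  if (any(chws$exact_amount_correct & !chws$aware_id)) {
    chw_abort("invariant violated: exact-amount-correct response without awareness")
  }
  rows <- list(
    prop_summary("aware_institutional_delivery", sum(chws$aware_id), n, level),
    prop_summary("exact_amount_institutional_delivery",
                 sum(chws$exact_amount_correct), n, level)
  )
  wrong <- chws$amount_response_id[!is.na(chws$amount_response_id) &
                                     chws$amount_response_id != correct_amount]
  modal <- NA_real_
  if (length(wrong)) {
    tab <- table(wrong)
    modal <- as.numeric(names(tab)[which.max(tab)])
    rows[[3]] <- prop_summary(sprintf("modal_wrong_amount_%g", modal),
                              max(tab), n, level)
  }
  out <- do.call(rbind, rows)
  attr(out, "modal_wrong_amount") <- modal
  class(out) <- c("survey_summary", "data.frame")
  out
}
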