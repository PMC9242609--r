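# Synthetic linked household + CHW survey generator. Emulates the
# statistical structure the analysis assumes -- per-CHW catchments, Poisson
# beneficiary incidence at demographic rates, Bernoulli CHW-contact
# indicators, household behaviors conditional on contact (plus non-claimable
# background behavior without contact), series completion counts, payment
# records under strict or partial-completion rules, and a CHW questionnaire
# -- so that every analysis stage is testable without the real surveys.

#' Generator configuration
#'
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @param n_chw number of CHWs.
#' @param months simulation horizon in months.
#' @param catchment_population people per CHW catchment (default 1,000).
#' @param demo a [demographic_rates()] table.
#' @param true_rates a [rate_set()]: CHW action coverages and household
#'   behavior rates conditional on contact.
#' @param background_rates named vector of household behavior rates *without*
#'   CHW contact (never claimable). Default: half the conditional rate for
#'   every behavior key, a deliberately nonzero choice so the claimability
#'   rule is exercised.
#' @param series_params named list of [series_distribution()]s: completion
#'   counts conditional on contact. Defaults to [fixture_series_params()].
#' @param background_series_params completion counts without contact;
#'   defaults to [fixture_background_series_params()] (point mass at 0 for
#'   series without an entry).
#' @param payment_rules named integer vector, incentive id -> completion
#'   threshold the *payer* applies to series incentives. Defaults to each
#'   incentive's `full_threshold` (the STRICT designed rule); smaller values
#'   model PARTIAL(k) payment for partial completion.
#' @param questionnaire named list of questionnaire proportions; see
#'   [fixture_questionnaire_props()].
#' @param n_questionnaire number of CHW questionnaire respondents
#'   (default 1,502).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_chw = 100L,
                             months = 12L,
                             catchment_population = 1000,
                             demo = fixture_demographic_rates(),
                             true_rates = fixture_rate_set(),
                             background_rates = NULL,
                             series_params = fixture_series_params(),
                             background_series_params = fixture_background_series_params(),
                             payment_rules = NULL,
                             questionnaire = fixture_questionnaire_props(),
                             n_questionnaire = 1502L) {
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  if (!is_scalar_number(seed) || seed != round(seed)) note("`seed` must be an integer")
  if (!is_scalar_number(n_chw) || n_chw < 1 || n_chw != round(n_chw)) {
    note("`n_chw` must be a positive integer")
  }
  if (!is_scalar_number(months) || months < 1 || months != round(months)) {
    note("`months` must be a positive integer")
  }
  if (!is_scalar_number(catchment_population) || catchment_population <= 0) {
    note("`catchment_population` must be > 0")
  }
  if (!inherits(demo, "demographic_rates")) note("`demo` must be demographic_rates")
  if (!inherits(true_rates, "rate_set")) note("`true_rates` must be a rate_set")
  if (!is.null(background_rates)) {
    if (!is.numeric(background_rates) || is.null(names(background_rates)) ||
        any(background_rates < 0 | background_rates > 1)) {
      note("`background_rates` must be a named vector of probabilities")
    }
  }
  if (!all(vapply(series_params, inherits, logical(1), "series_distribution"))) {
    note("`series_params` must be a list of series_distribution objects")
  }
  if (!all(vapply(background_series_params, inherits, logical(1), "series_distribution"))) {
    note("`background_series_params` must be a list of series_distribution objects")
  }
  if (!is.null(payment_rules)) {
    if (is.null(names(payment_rules)) || any(payment_rules < 1) ||
        any(payment_rules != round(payment_rules))) {
      note("`payment_rules` must be a named vector of positive integer thresholds")
    }
  }
  q <- questionnaire
  props <- unlist(q[c("payment_difficult", "delays_frequent", "unknown_breakup",
                      "partial_payment", "signoff_hard", "pay_to_get",
                      "months_covered_2plus", "aware_id", "exact_amount_id",
                      "modal_wrong_share")])
  if (any(!is.finite(props)) || any(props < 0 | props > 1)) {
    note("questionnaire proportions must lie in [0,1]")
  }
  if (!is.null(q$recency) &&
      (length(q$recency) != 3L || abs(sum(q$recency) - 1) > 1e-8)) {
    note("questionnaire recency must be 3 proportions summing to 1")
  }
  if (!is.null(q$exact_amount_id) && !is.null(q$aware_id) &&
      q$exact_amount_id > q$aware_id) {
    note("exact-amount awareness cannot exceed overall awareness")
  }
  if (!is.null(q$exact_amount_id) && !is.null(q$modal_wrong_share) &&
      !is.null(q$aware_id) &&
      q$exact_amount_id + q$modal_wrong_share > q$aware_id + 1e-8) {
    note("exact + modal-wrong shares cannot exceed overall awareness")
  }
  if (!is_scalar_number(n_questionnaire) || n_questionnaire < 1) {
    note("`n_questionnaire` must be a positive integer")
  }
  if (length(problems)) {
    chw_abort(paste0("invalid generator config:\n  - ",
                     paste(problems, collapse = "\n  - ")))
  }
  structure(
    list(seed = as.integer(seed), n_chw = as.integer(n_chw),
         months = as.integer(months),
         catchment_population = as.numeric(catchment_population),
         demo = demo, true_rates = true_rates,
         background_rates = background_rates,
         series_params = series_params,
         background_series_params = background_series_params,
         payment_rules = payment_rules,
         questionnaire = questionnaire,
         n_questionnaire = as.integer(n_questionnaire)),
    class = "generator_config"
  )
}

sample_counts <- function(n, dist) {
  if (n == 0L) return(integer())
  sample.int(dist$K + 1L, n, replace = TRUE, prob = dist$probabilities) - 1L
}

default_background_rate <- function(config, key) {
  if (!is.null(config$background_rates) && key %in% names(config$background_rates)) {
    return(as.numeric(config$background_rates[[key]]))
  }
  0.5 * as.numeric(config$true_rates[[key]])
}

payer_threshold <- function(config, inc) {
  if (!is.null(config$payment_rules) && inc$id %in% names(config$payment_rules)) {
    k <- as.integer(config$payment_rules[[inc$id]])
    if (k > inc$series$full_threshold) {
      chw_abort(sprintf("payment rule for '%s' exceeds its full threshold", inc$id))
    }
    return(k)
  }
  inc$series$full_threshold  # STRICT
}

rbind_fill <- function(frames) {
  frames <- frames[vapply(frames, function(f) !is.null(f) && nrow(f) > 0, logical(1))]
  if (!length(frames)) return(NULL)
  cols <- unique(unlist(lapply(frames, names)))
  filled <- lapply(frames, function(f) {
    for (cl in setdiff(cols, names(f))) f[[cl]] <- NA
    f[cols]
  })
  do.call(rbind, c(filled, list(make.row.names = FALSE)))
}

#' Generate synthetic linked survey microdata and payment records
#'
#' For every POPULATION-scaled incentive, beneficiary counts per CHW-month
#' are Poisson with mean equal to that incentive's monthly beneficiary
#' incidence; CHW contacts are independent Bernoulli draws at the action
#' rates; household behaviors are drawn at the conditional rate given full
#' contact and at the background rate otherwise; series completion counts
#' come from `series_params` (conditional) or `background_series_params`.
#' Payments apply the payment rule per beneficiary: a claim requires full CHW
#' contact and, for series incentives, a completion count at or above the
#' payer's threshold (for others, all required behaviors); a behavior without
#' the required contact is never claimable. ROUTINE incentives are Bernoulli
#' per CHW-month at their action rates. The questionnaire is drawn
#' independently at the configured proportions.
#'
#' @param config a [generator_config()].
#' @param catalog an `incentive_catalog`; defaults to [fixture_catalog()].
#' @return list of class `chw_simulation`: `households` (one row per
#'   beneficiary event per incentive), `chw_months` (routine flags and
#'   monthly payment), `chws` (questionnaire), `payments` (per
#'   CHW-month-incentive amounts, with `n_chw`/`months` attributes), and the
#'   `config`.
#' @export
generate_microdata <- function(config, catalog = fixture_catalog()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(catalog, "incentive_catalog"))
  missing_rates <- validate_against_rates(catalog, config$true_rates)
  if (length(missing_rates)) {
    chw_abort(sprintf("true_rates missing key(s) required by the catalog: %s",
                      paste(missing_rates, collapse = ", ")))
  }
  for (inc in catalog) {
    if (!is.null(inc$series)) {
      dist <- config$series_params[[inc$id]]
      if (is.null(dist)) {
        chw_abort(sprintf("no series_params entry for series incentive '%s'", inc$id))
      }
      check_series_pair(inc, dist)
    }
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  C <- config$n_chw; M <- config$months
  catch <- catchment(config$catchment_population)
  grid_chw <- rep(seq_len(C), each = M)
  grid_month <- rep(seq_len(M), times = C)

  pop_incs <- Filter(function(i) i$scaling == "POPULATION", catalog)
  routine_incs <- Filter(function(i) i$scaling == "FIXED", catalog)

  hh_frames <- list()
  pay_frames <- list()

  for (inc in pop_incs) {
    mu <- beneficiary_incidence(inc, config$demo, catch)
    n_bm <- stats::rpois(C * M, mu)
    total <- sum(n_bm)
    if (total == 0L) next
    df <- data.frame(
      chw_id = rep(grid_chw, n_bm),
      month = rep(grid_month, n_bm),
      incentive_id = inc$id,
      beneficiary_type = inc$incidence_basis,
      stringsAsFactors = FALSE
    )

    own_action_series <- !is.null(inc$series) && length(inc$behavior_keys) == 0L
    contact_all <- rep(TRUE, total)
    if (!own_action_series) {
      for (key in inc$action_keys) {
        flag <- stats::rbinom(total, 1L, config$true_rates[[key]])
        df[[paste0("contact_", key)]] <- flag
        contact_all <- contact_all & flag == 1L
      }
    }

    if (!is.null(inc$series)) {
      cond <- config$series_params[[inc$id]]
      if (own_action_series) {
        count <- sample_counts(total, cond)
      } else {
        bg <- config$background_series_params[[inc$id]]
        count <- integer(total)
        n_c <- sum(contact_all)
        count[contact_all] <- sample_counts(n_c, cond)
        if (total - n_c > 0L) {
          count[!contact_all] <- if (is.null(bg)) 0L else
            sample_counts(total - n_c, bg)
        }
      }
      df$series_count <- count
      claim <- contact_all & count >= payer_threshold(config, inc)
    } else {
      behavior_all <- rep(TRUE, total)
      for (key in inc$behavior_keys) {
        p_cond <- config$true_rates[[key]]
        p_bg <- default_background_rate(config, key)
        p <- ifelse(contact_all, p_cond, p_bg)
        flag <- stats::rbinom(total, 1L, p)
        df[[paste0("outcome_", key)]] <- flag
        behavior_all <- behavior_all & flag == 1L
      }
      claim <- contact_all & behavior_all
    }
    df$claimable <- as.integer(claim)
    hh_frames[[inc$id]] <- df

    paid <- df[claim, c("chw_id", "month")]
    if (nrow(paid)) {
      agg <- stats::aggregate(list(n_claims = rep(1L, nrow(paid))),
                              by = paid, FUN = sum)
      agg$incentive_id <- inc$id
      agg$category <- inc$category
      agg$amount_paid <- agg$n_claims * inc$amount
      pay_frames[[inc$id]] <- agg
    }
  }

  # routine incentives: one Bernoulli flag per unique action key per CHW-month
  chw_months <- data.frame(chw_id = grid_chw, month = grid_month)
  routine_keys <- unique(unlist(lapply(routine_incs, `[[`, "action_keys")))
  for (key in routine_keys) {
    chw_months[[paste0("flag_", key)]] <-
      stats::rbinom(C * M, 1L, config$true_rates[[key]])
  }
  for (inc in routine_incs) {
    done <- rep(TRUE, C * M)
    for (key in inc$action_keys) {
      done <- done & chw_months[[paste0("flag_", key)]] == 1L
    }
    if (any(done)) {
      pay_frames[[paste0("routine_", inc$id)]] <- data.frame(
        chw_id = grid_chw[done], month = grid_month[done],
        n_claims = 1L, incentive_id = inc$id, category = inc$category,
        amount_paid = inc$amount, stringsAsFactors = FALSE
      )
    }
  }

  payments <- rbind_fill(pay_frames)
  if (is.null(payments)) {
    payments <- data.frame(chw_id = integer(), month = integer(),
                           n_claims = integer(), incentive_id = character(),
                           category = character(), amount_paid = numeric(),
                           stringsAsFactors = FALSE)
  }
  payments <- payments[order(payments$chw_id, payments$month,
                             payments$incentive_id), ]
  rownames(payments) <- NULL
  attr(payments, "n_chw") <- C
  attr(payments, "months") <- M

  monthly_pay <- stats::setNames(rep(0, C * M),
                                 paste(grid_chw, grid_month, sep = "."))
  if (nrow(payments)) {
    sums <- tapply(payments$amount_paid,
                   paste(payments$chw_id, payments$month, sep = "."), sum)
    monthly_pay[names(sums)] <- sums
  }
  chw_months$payment_inr <- as.numeric(monthly_pay)

  households <- rbind_fill(hh_frames)
  if (is.null(households)) {
    households <- data.frame(chw_id = integer(), month = integer(),
                             incentive_id = character(),
                             beneficiary_type = character(),
                             claimable = integer(), stringsAsFactors = FALSE)
  } else {
    rownames(households) <- NULL
  }

  chws <- generate_questionnaire(config)

  structure(list(households = households, chw_months = chw_months,
                 chws = chws, payments = payments, config = config),
            class = "chw_simulation")
}

generate_questionnaire <- function(config) {
  q <- config$questionnaire
  n <- config$n_questionnaire
  draw <- function(p) stats::rbinom(n, 1L, p) == 1L

  aware <- draw(q$aware_id)
  # exact-amount correctness and the modal wrong answer are nested inside
  # awareness so the invariant exact => aware holds by construction
  response <- rep(NA_real_, n)
  n_aw <- sum(aware)
  if (n_aw > 0L) {
    p_exact <- q$exact_amount_id / q$aware_id
    p_modal <- q$modal_wrong_share / q$aware_id
    p_other <- max(0, 1 - p_exact - p_modal)
    response[aware] <- sample(
      c(q$correct_amount, q$modal_wrong_amount, q$other_wrong_amount),
      n_aw, replace = TRUE, prob = c(p_exact, p_modal, p_other))
  }
  recency <- sample(names(q$recency), n, replace = TRUE, prob = q$recency)

  data.frame(
    chw_id = seq_len(n),
    aware_id = aware,
    amount_response_id = response,
    exact_amount_correct = !is.na(response) & response == q$correct_amount,
    payment_difficult = draw(q$payment_difficult),
    delays_frequent = draw(q$delays_frequent),
    unknown_breakup = draw(q$unknown_breakup),
    partial_payment = draw(q$partial_payment),
    signoff_hard = draw(q$signoff_hard),
    pay_to_get = draw(q$pay_to_get),
    last_payment_recency = recency,
    months_covered_2plus = draw(q$months_covered_2plus),
    stringsAsFactors = FALSE
  )
}

#' Mean simulated monthly payments
#'
#' @param payments the `payments` element of a [generate_microdata()] result
#'   (or the simulation itself).
#' @param by `"category"`, `"incentive"` or `"total"`.
#' @return data frame of mean INR per CHW per month, or a scalar for
#'   `by = "total"`.
#' @export
summarize_payments <- function(payments, by = c("category", "incentive", "total")) {
  by <- match.arg(by)
  if (inherits(payments, "chw_simulation")) payments <- payments$payments
  denom <- attr(payments, "n_chw") * attr(payments, "months")
  if (is.null(denom) || !is.finite(denom)) {
    chw_contract_error("payments must carry n_chw and months attributes")
  }
  if (by == "total") return(sum(payments$amount_paid) / denom)
  key <- if (by == "category") payments$category else payments$incentive_id
  if (!nrow(payments)) {
    return(data.frame(group = character(), mean_monthly_inr = numeric()))
  }
  sums <- tapply(payments$amount_paid, key, sum)
  out <- data.frame(group = names(sums),
                    mean_monthly_inr = as.numeric(sums) / denom,
                    stringsAsFactors = FALSE)
  names(out)[1] <- by
  out
}

#' Write simulated microdata to CSV files
#'
#' Writes `households.csv`, `chw_months.csv`, `chws.csv`, `payments.csv` and
#' a deterministic `manifest.json` recording the seed and the main
#' configuration scalars.
#'
#' @param sim a `chw_simulation`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_microdata <- function(sim, dir) {
  stopifnot(inherits(sim, "chw_simulation"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) chw_abort(sprintf("cannot create microdata directory: %s", dir))
  wr <- function(df, name) {
    path <- file.path(dir, name)
    tryCatch(utils::write.csv(df, path, row.names = FALSE, na = ""),
             error = function(e) chw_abort(sprintf(
               "failed writing %s: %s", path, conditionMessage(e))))
  }
  wr(sim$households, "households.csv")
  wr(sim$chw_months, "chw_months.csv")
  wr(sim$chws, "chws.csv")
  wr(cbind(sim$payments), "payments.csv")
  cfg <- sim$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_chw = cfg$n_chw, months = cfg$months,
         catchment_population = cfg$catchment_population,
         n_questionnaire = cfg$n_questionnaire,
         true_rate_hash = sum(as.numeric(cfg$true_rates) *
                                seq_along(cfg$true_rates))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read microdata written by [write_microdata()]
#'
#' @param dir directory containing the CSV files.
#' @return list with `households`, `chw_months`, `chws`, `payments`,
#'   `manifest`.
#' @export
read_microdata <- function(dir) {
  rd <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) chw_abort(sprintf("microdata file not found: %s", path))
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  payments <- rd("payments.csv")
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  attr(payments, "n_chw") <- manifest$n_chw
  attr(payments, "months") <- manifest$months
  list(households = rd("households.csv"), chw_months = rd("chw_months.csv"),
       chws = rd("chws.csv"), payments = payments, manifest = manifest)
}
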