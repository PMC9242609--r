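# The four-scenario projection engine: perfect/actual CHW crossed with
# perfect/actual household, per incentive, aggregated to categories and total.

#' Named rate set
#'
#' Probabilities for CHW actions (e.g. the proportion of pregnant women
#' counseled on facility delivery) and for household behaviors *conditional
#' on the CHW action* (e.g. the facility-delivery rate among women who
#' received counseling). Unconditional population behavior rates are never
#' used by the engine: a household that performs the behavior without CHW
#' contact generates no claim.
#'
#' @param values named numeric vector, all in `[0, 1]`.
#' @param provenance character scalar or vector: survey label or
#'   `"SYNTHETIC"`, stored as an attribute per key.
#' @return object of class `rate_set` (named numeric vector).
#' @export
rate_set <- function(values, provenance = "SYNTHETIC") {
  if (!is.numeric(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    chw_abort("`values` must be a named numeric vector")
  }
  if (anyDuplicated(names(values))) chw_abort("duplicate rate keys")
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    bad <- names(values)[!is.finite(values) | values < 0 | values > 1]
    chw_abort(sprintf("rates must lie in [0,1]: %s", paste(bad, collapse = ", ")))
  }
  provenance <- rep_len(as.character(provenance), length(values))
  names(provenance) <- names(values)
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), provenance = provenance, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> %d rates\n", length(x)))
  print(data.frame(key = names(x), value = as.numeric(x),
                   provenance = attr(x, "provenance"), row.names = NULL))
  invisible(x)
}

#' Read a rate set from CSV (columns: key, value, optional provenance)
#' @param path CSV path.
#' @return a [rate_set()].
#' @export
load_rate_set <- function(path) {
  if (!file.exists(path)) chw_abort(sprintf("rate set file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("key", "value"), names(df))
  if (length(missing_cols)) {
    chw_abort(sprintf("rate CSV missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  rate_set(stats::setNames(df$value, df$key),
           provenance = if ("provenance" %in% names(df)) df$provenance else "SYNTHETIC")
}

#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  utils::write.csv(
    data.frame(key = names(rates), value = as.numeric(rates),
               provenance = attr(rates, "provenance")),
    path, row.names = FALSE)
  invisible(path)
}

#' Scenario specification
#'
#' One of the four counterfactuals: the CHW completes all her actions
#' (`PERFECT`) or at empirically estimated rates (`ACTUAL`), crossed with
#' households responding perfectly or at their actual conditional rates.
#'
#' @param chw_mode `"PERFECT"` or `"ACTUAL"`.
#' @param household_mode `"PERFECT"` or `"ACTUAL"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(chw_mode = c("PERFECT", "ACTUAL"),
                          household_mode = c("PERFECT", "ACTUAL")) {
  structure(list(chw_mode = match.arg(chw_mode),
                 household_mode = match.arg(household_mode)),
            class = "scenario_spec")
}

#' Parse a two-letter scenario code
#'
#' First letter is the CHW mode, second the household mode: `"pp"`, `"pa"`,
#' `"ap"`, `"aa"` (e.g. `"pa"` = perfect CHW, actual household).
#'
#' @param code two-letter code.
#' @return a [scenario_spec()].
#' @export
as_scenario <- function(code) {
  if (inherits(code, "scenario_spec")) return(code)
  code <- tolower(code)
  if (!code %in% c("pp", "pa", "ap", "aa")) {
    chw_contract_error("scenario code must be one of pp, pa, ap, aa")
  }
  mode <- function(ch) if (ch == "p") "PERFECT" else "ACTUAL"
  scenario_spec(mode(substr(code, 1, 1)), mode(substr(code, 2, 2)))
}

scenario_code <- function(scenario) {
  paste0(tolower(substr(scenario$chw_mode, 1, 1)),
         tolower(substr(scenario$household_mode, 1, 1)))
}

#' Effective completion probability for a set of rate keys
#'
#' `PERFECT` mode returns 1 (every action/behavior completed); `ACTUAL` mode
#' multiplies the named rates together (independence across required
#' actions/behaviors). An empty key list returns 1 in both modes.
#'
#' @param mode `"PERFECT"` or `"ACTUAL"`.
#' @param keys character vector of rate keys.
#' @param rates a [rate_set()]; required only in `ACTUAL` mode.
#' @return probability in `[0, 1]`.
#' @export
effective_rate <- function(mode, keys, rates = NULL) {
  mode <- match.arg(mode, c("PERFECT", "ACTUAL"))
  if (mode == "PERFECT" || length(keys) == 0L) return(1)
  if (is.null(rates)) chw_config_error("ACTUAL mode requires a rate set")
  missing <- setdiff(keys, names(rates))
  if (length(missing)) {
    chw_config_error(sprintf("rate key(s) missing from rate set: %s",
                             paste(missing, collapse = ", ")))
  }
  prod(as.numeric(rates[keys]))
}

#' Project monthly earnings from one incentive under one scenario
#'
#' Earnings = beneficiary incidence x effective CHW action rate x effective
#' household behavior rate x incentive amount. Incentives with no behavior
#' keys are unaffected by the household mode. `rounding_mode =
#' "PAPER_ROUNDING"` reproduces the published worked chains, which round the
#' *rate-adjusted* incidence of population-scaled incentives to one decimal
#' before multiplying by the amount (the unadjusted perfect-perfect chain and
#' fixed routine incentives are left at full precision, as in those chains);
#' the default `"FULL_PRECISION"` performs no intermediate rounding.
#'
#' @param inc an [incentive()].
#' @param scenario a [scenario_spec()] or two-letter code.
#' @param rates a [rate_set()]; needed for ACTUAL modes.
#' @param demo a [demographic_rates()] table.
#' @param catch a [catchment()].
#' @param rounding_mode `"FULL_PRECISION"` or `"PAPER_ROUNDING"`.
#' @return expected earnings in INR per month (unrounded money).
#' @export
project_incentive <- function(inc, scenario, rates = NULL,
                              demo, catch = catchment(),
                              rounding_mode = c("FULL_PRECISION", "PAPER_ROUNDING")) {
  rounding_mode <- match.arg(rounding_mode)
  scenario <- as_scenario(scenario)
  stopifnot(inherits(inc, "incentive_definition"))
  b <- beneficiary_incidence(inc, demo, catch)
  a <- effective_rate(scenario$chw_mode, inc$action_keys, rates)
  h <- effective_rate(scenario$household_mode, inc$behavior_keys, rates)
  eff <- b * a * h
  if (rounding_mode == "PAPER_ROUNDING" && inc$scaling == "POPULATION" && a * h < 1) {
    eff <- round_one_decimal(eff)
  }
  eff * inc$amount
}

#' Project a whole catalog under one scenario
#'
#' @inheritParams project_incentive
#' @param catalog an `incentive_catalog`.
#' @return object of class `earnings_projection` with elements `scenario`,
#'   `catchment`, `rounding_mode`, `per_incentive` (named INR/month),
#'   `per_category` (named over all five categories) and `total`.
#' @export
project_all <- function(catalog, scenario, rates = NULL,
                        demo, catch = catchment(),
                        rounding_mode = c("FULL_PRECISION", "PAPER_ROUNDING")) {
  rounding_mode <- match.arg(rounding_mode)
  scenario <- as_scenario(scenario)
  stopifnot(inherits(catalog, "incentive_catalog"))
  per_incentive <- vapply(
    catalog, project_incentive, numeric(1),
    scenario = scenario, rates = rates, demo = demo, catch = catch,
    rounding_mode = rounding_mode
  )
  per_category <- stats::setNames(numeric(length(INCENTIVE_CATEGORIES)),
                                  INCENTIVE_CATEGORIES)
  if (length(catalog)) {
    sums <- tapply(per_incentive, categories(catalog), sum)
    per_category[names(sums)] <- sums
  }
  structure(
    list(scenario = scenario, catchment = catch, rounding_mode = rounding_mode,
         per_incentive = per_incentive, per_category = per_category,
         total = sum(per_incentive)),
    class = "earnings_projection"
  )
}

#' @export
print.earnings_projection <- function(x, ...) {
  cat(sprintf("<earnings_projection> %s CHW - %s household, catchment %g\n",
              x$scenario$chw_mode, x$scenario$household_mode,
              x$catchment$population))
  cat(sprintf("  total: INR %s/month\n", format(round_rupee(x$total), big.mark = ",")))
  for (cat_ in names(x$per_category)) {
    cat(sprintf("  %-13s INR %7.0f\n", cat_, round_rupee(x$per_category[[cat_]])))
  }
  invisible(x)
}

#' Project all four scenarios at once
#'
#' @inheritParams project_all
#' @return named list of [project_all()] results with elements `pp`, `pa`,
#'   `ap`, `aa`.
#' @export
project_scenarios <- function(catalog, rates, demo, catch = catchment(),
                              rounding_mode = "FULL_PRECISION") {
  stats::setNames(
    lapply(c("pp", "pa", "ap", "aa"), function(code)
      project_all(catalog, code, rates, demo, catch, rounding_mode)),
    c("pp", "pa", "ap", "aa"))
}

#' Convert INR to USD at a fixed exchange rate
#'
#' @param amount_inr money in INR.
#' @param inr_per_usd exchange rate, INR per 1 USD; must be > 0.
#' @return USD, presentation-rounded to whole dollars.
#' @export
convert_currency <- function(amount_inr, inr_per_usd) {
  assert_scalar_number(inr_per_usd, "inr_per_usd")
  if (inr_per_usd <= 0) chw_contract_error("exchange rate must be > 0")
  round(amount_inr / inr_per_usd)
}

#' Sweep projections over catchment sizes
#'
#' Reproduces the varying-catchment exercise: totals (and category subtotals)
#' under one scenario for each population in `populations`. POPULATION-scaled
#' incentives scale linearly; FIXED incentives are invariant.
#'
#' @inheritParams project_all
#' @param populations numeric vector of catchment sizes.
#' @return data frame with columns `population`, `total`, and one column per
#'   category.
#' @export
catchment_sweep <- function(catalog, scenario, rates, demo,
                            populations = c(500, 1000, 1500, 2000),
                            rounding_mode = "FULL_PRECISION") {
  rows <- lapply(populations, function(p) {
    pr <- project_all(catalog, scenario, rates, demo, catchment(p), rounding_mode)
    c(population = p, total = pr$total, pr$per_category)
  })
  as.data.frame(do.call(rbind, rows))
}
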