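# Beneficiary incidence: annual demographic rates -> expected events per
# month in one CHW catchment. This is the "b" term of every projection.

#' CHW catchment
#'
#' @param population number of people served by one CHW; must be > 0. The
#'   analysis default is 1,000.
#' @return object of class `catchment`.
#' @export
catchment <- function(population = 1000) {
  assert_scalar_number(population, "population")
  if (population <= 0) chw_contract_error("catchment population must be > 0")
  structure(list(population = as.numeric(population)), class = "catchment")
}

#' Demographic rate table
#'
#' A named map of rate key to value + basis. `PER_1000_PER_YEAR` entries are
#' annual flows per 1,000 population (e.g. crude birth rate); `PROPORTION`
#' entries are population stocks as a fraction of total population (e.g. the
#' under-5 proportion). Keys used as incidence bases by the bundled catalog:
#' `PREGNANCY`, `NEWBORN` (both proxied by the crude birth rate),
#' `CHILD_U5`, `ELIGIBLE_COUPLE`.
#'
#' @param keys character vector of rate keys.
#' @param values numeric vector of rate values.
#' @param basis character vector, each `"PER_1000_PER_YEAR"` or `"PROPORTION"`.
#' @param description optional character vector of descriptions.
#' @param source optional character vector of provenance labels.
#' @return object of class `demographic_rates`.
#' @export
demographic_rates <- function(keys, values, basis,
                              description = NA_character_,
                              source = NA_character_) {
  if (length(keys) != length(values) || length(keys) != length(basis)) {
    chw_abort("`keys`, `values` and `basis` must have equal length")
  }
  if (anyDuplicated(keys)) chw_abort("duplicate demographic rate keys")
  if (!all(basis %in% c("PER_1000_PER_YEAR", "PROPORTION"))) {
    chw_abort("basis must be PER_1000_PER_YEAR or PROPORTION")
  }
  if (any(!is.finite(values))) chw_abort("demographic rate values must be finite")
  if (any(values < 0)) chw_abort("demographic rate values must be >= 0")
  bad <- basis == "PROPORTION" & (values < 0 | values > 1)
  if (any(bad)) {
    chw_abort(sprintf("PROPORTION rates must lie in [0,1]: %s",
                      paste(keys[bad], collapse = ", ")))
  }
  structure(
    data.frame(key = as.character(keys), value = as.numeric(values),
               basis = as.character(basis),
               description = as.character(description),
               source = as.character(source), stringsAsFactors = FALSE),
    class = c("demographic_rates", "data.frame")
  )
}

#' Read a demographic rate table from CSV
#'
#' Expected columns: `key`, `value`, `basis`, optionally `description`,
#' `source`.
#'
#' @param path CSV path.
#' @return a `demographic_rates` table.
#' @export
load_demographic_rates <- function(path) {
  if (!file.exists(path)) chw_abort(sprintf("demographic rates file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("key", "value", "basis"), names(df))
  if (length(missing_cols)) {
    chw_abort(sprintf("demographic rates CSV missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  demographic_rates(df$key, df$value, df$basis,
                    description = if ("description" %in% names(df)) df$description else NA,
                    source = if ("source" %in% names(df)) df$source else NA)
}

#' @export
write_demographic_rates <- function(rates, path) {
  stopifnot(inherits(rates, "demographic_rates"))
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE)
  invisible(path)
}

demo_entry <- function(demo, key) {
  i <- match(key, demo$key)
  if (is.na(i)) return(NULL)
  list(key = demo$key[i], value = demo$value[i], basis = demo$basis[i])
}

#' Monthly events from an annual per-1,000 rate
#'
#' Converts an annual `PER_1000_PER_YEAR` demographic rate into expected
#' events per month in one catchment:
#' `value * (population / 1000) / 12`, at full precision. For a crude birth
#' rate of 27.28 and a catchment of 1,000 this gives 2.2733 pregnant women
#' per month (presented as 2.3 at one decimal).
#'
#' @param demo a [demographic_rates()] table.
#' @param key rate key to resolve.
#' @param catch a [catchment()].
#' @return expected events per month (numeric scalar).
#' @export
monthly_incidence <- function(demo, key, catch = catchment()) {
  stopifnot(inherits(demo, "demographic_rates"), inherits(catch, "catchment"))
  entry <- demo_entry(demo, key)
  if (is.null(entry)) {
    chw_config_error(sprintf("demographic rate key not found: '%s'", key))
  }
  if (entry$basis != "PER_1000_PER_YEAR") {
    chw_contract_error(sprintf(
      "monthly_incidence() requires a PER_1000_PER_YEAR rate; '%s' has basis %s",
      key, entry$basis))
  }
  entry$value * (catch$population / 1000) / 12
}

#' Beneficiary incidence for one incentive
#'
#' Resolves the incentive's `incidence_basis` against the demographic table:
#' `ROUTINE` incentives have exactly one event per month regardless of
#' catchment size; `PER_1000_PER_YEAR` bases go through
#' [monthly_incidence()]; `PROPORTION` bases give a stock
#' (`population * value`) to which the incentive's `basis_multiplier`
#' (events per eligible person per month) is applied. The multiplier is also
#' applied to flow bases (default 1).
#'
#' @param inc an [incentive()].
#' @param demo a [demographic_rates()] table.
#' @param catch a [catchment()].
#' @return expected beneficiary events per month.
#' @export
beneficiary_incidence <- function(inc, demo, catch = catchment()) {
  stopifnot(inherits(inc, "incentive_definition"))
  if (inc$incidence_basis == "ROUTINE") return(1)
  entry <- demo_entry(demo, inc$incidence_basis)
  if (is.null(entry)) {
    chw_config_error(sprintf(
      "incidence basis '%s' of incentive '%s' not found in demographic rates",
      inc$incidence_basis, inc$id))
  }
  base <- switch(entry$basis,
    PER_1000_PER_YEAR = monthly_incidence(demo, inc$incidence_basis, catch),
    PROPORTION = catch$population * entry$value
  )
  base * inc$basis_multiplier
}
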