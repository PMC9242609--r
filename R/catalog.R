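# Incentive catalog: definitions, validation, JSON/CSV round trip, and
# observed government payment records.

#' Incentive categories
#'
#' The five categories the analysed incentives fall into: antenatal care and
#' institutional delivery (`ANC_ID`), newborn and child health / postnatal
#' care (`PNC`), family planning (`FP`), routine immunization
#' (`IMMUNIZATION`), and routine recurring activities (`ROUTINE`).
#'
#' @export
INCENTIVE_CATEGORIES <- c("ANC_ID", "PNC", "FP", "IMMUNIZATION", "ROUTINE")

CATALOG_SCHEMA_VERSION <- 1L

#' Define a single incentive
#'
#' An incentive is a fixed rupee amount paid per claimable unit. A unit is a
#' beneficiary event (a pregnancy, a newborn, an eligible couple, ...) for
#' which the CHW completed the required actions and, where applicable, the
#' household completed the required behaviors. Series incentives pay a single
#' lump sum for completing `full_threshold` of `n_components` component
#' activities (e.g. 4 antenatal check-ups, 6 of 7 postnatal home visits).
#'
#' Series incentives must designate exactly one *completion key*: the single
#' behavior key when completion is a household behavior conditional on CHW
#' contact, or the single action key when the series consists of the CHW's
#' own visits. The rate bound to that key is interpreted as
#' P(completion count >= full_threshold | contact), which keeps the analytic
#' engine, the synthetic generator and rate re-estimation consistent.
#'
#' @param id short unique string key.
#' @param name human-readable label.
#' @param category one of [INCENTIVE_CATEGORIES].
#' @param amount incentive amount in INR per claimable unit; must be > 0.
#' @param incidence_basis demographic-rate key driving beneficiary incidence
#'   (e.g. `"PREGNANCY"`, `"NEWBORN"`, `"CHILD_U5"`, `"ELIGIBLE_COUPLE"`), or
#'   `"ROUTINE"` for a fixed one-event-per-month activity.
#' @param action_keys character vector of rate keys for required CHW actions.
#' @param behavior_keys character vector of rate keys for required household
#'   behaviors (empty for incentives independent of household behavior).
#' @param series optional list `list(n_components =, full_threshold =)`.
#' @param scaling `"POPULATION"` (earnings scale linearly with catchment) or
#'   `"FIXED"` (independent of catchment size). `incidence_basis == "ROUTINE"`
#'   if and only if `scaling == "FIXED"`.
#' @param basis_multiplier events per eligible person per month applied on top
#'   of the resolved incidence; used mainly with `PROPORTION` bases, where the
#'   demographic rate gives a population stock rather than a monthly flow.
#' @param placeholder_amount logical; `TRUE` marks amounts that are fixture
#'   placeholders rather than published values.
#' @return an object of class `incentive_definition`.
#' @export
incentive <- function(id, name, category, amount, incidence_basis,
                      action_keys = character(), behavior_keys = character(),
                      series = NULL,
                      scaling = c("POPULATION", "FIXED"),
                      basis_multiplier = 1,
                      placeholder_amount = FALSE) {
  scaling <- match.arg(scaling)
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    note("`id` must be a nonempty string")
  }
  if (!is.character(name) || length(name) != 1L) note("`name` must be a string")
  if (!is.character(category) || length(category) != 1L ||
      !category %in% INCENTIVE_CATEGORIES) {
    note("`category` must be one of %s", paste(INCENTIVE_CATEGORIES, collapse = ", "))
  }
  if (!is_scalar_number(amount) || amount <= 0) note("`amount` must be > 0")
  if (!is.character(incidence_basis) || length(incidence_basis) != 1L) {
    note("`incidence_basis` must be a string")
  }
  action_keys <- as.character(action_keys)
  behavior_keys <- as.character(behavior_keys)
  bad_key <- function(k) !grepl("^[a-z][a-z0-9_]*$", k)
  if (any(vapply(action_keys, bad_key, logical(1)))) {
    note("action keys must match ^[a-z][a-z0-9_]*$")
  }
  if (any(vapply(behavior_keys, bad_key, logical(1)))) {
    note("behavior keys must match ^[a-z][a-z0-9_]*$")
  }
  if (!is.null(series)) {
    if (!is.list(series) || is.null(series$n_components) ||
        is.null(series$full_threshold)) {
      note("`series` must be list(n_components =, full_threshold =)")
    } else {
      K <- series$n_components
      kf <- series$full_threshold
      if (!is_scalar_number(K) || K < 1 || K != round(K)) {
        note("series n_components must be a positive integer")
      }
      if (!is_scalar_number(kf) || kf < 1 || kf != round(kf) ||
          (is_scalar_number(K) && kf > K)) {
        note("series full_threshold must satisfy 1 <= full_threshold <= n_components")
      }
      series <- list(n_components = as.integer(K), full_threshold = as.integer(kf))
      if (length(behavior_keys) > 1L) {
        note("series incentives take at most one behavior key (the completion key)")
      }
      if (length(behavior_keys) == 0L && length(action_keys) != 1L) {
        note("series incentives without a behavior key need exactly one action key (the completion key)")
      }
    }
  }
  if (is.character(incidence_basis) && length(incidence_basis) == 1L) {
    if ((incidence_basis == "ROUTINE") != (scaling == "FIXED")) {
      note("incidence_basis == 'ROUTINE' if and only if scaling == 'FIXED'")
    }
  }
  if (!is_scalar_number(basis_multiplier) || basis_multiplier <= 0) {
    note("`basis_multiplier` must be > 0")
  }
  if (length(problems)) {
    chw_abort(paste0(
      "invalid incentive definition", if (is.character(id) && length(id) == 1L)
        sprintf(" '%s'", id) else "", ":\n  - ",
      paste(problems, collapse = "\n  - ")
    ))
  }

  structure(
    list(
      id = id, name = name, category = category, amount = as.numeric(amount),
      incidence_basis = incidence_basis,
      action_keys = action_keys, behavior_keys = behavior_keys,
      series = series, scaling = scaling,
      basis_multiplier = as.numeric(basis_multiplier),
      placeholder_amount = isTRUE(placeholder_amount)
    ),
    class = "incentive_definition"
  )
}

#' Build an incentive catalog from definitions
#'
#' @param definitions list of [incentive()] objects.
#' @return object of class `incentive_catalog` (a named list keyed by id).
#' @export
incentive_catalog <- function(definitions = list()) {
  if (!is.list(definitions)) chw_abort("`definitions` must be a list")
  ok <- vapply(definitions, inherits, logical(1), "incentive_definition")
  if (length(definitions) && !all(ok)) {
    chw_abort("all catalog entries must be incentive_definition objects")
  }
  ids <- vapply(definitions, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    chw_abort(sprintf("duplicate incentive ids: %s", paste(dup, collapse = ", ")))
  }
  names(definitions) <- ids
  structure(definitions, class = "incentive_catalog")
}

#' @export
print.incentive_catalog <- function(x, ...) {
  cat(sprintf("<incentive_catalog> %d incentives, %d categories\n",
              length(x), length(unique(categories(x)))))
  if (length(x)) print(as.data.frame(x)[, c("id", "category", "amount", "incidence_basis")])
  invisible(x)
}

categories <- function(catalog) {
  vapply(catalog, `[[`, character(1), "category")
}

#' @export
as.data.frame.incentive_catalog <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(
      id = character(), name = character(), category = character(),
      amount = numeric(), incidence_basis = character(),
      action_keys = character(), behavior_keys = character(),
      series_n_components = integer(), series_full_threshold = integer(),
      scaling = character(), basis_multiplier = numeric(),
      placeholder_amount = logical(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    id = vapply(x, `[[`, character(1), "id"),
    name = vapply(x, `[[`, character(1), "name"),
    category = categories(x),
    amount = vapply(x, `[[`, numeric(1), "amount"),
    incidence_basis = vapply(x, `[[`, character(1), "incidence_basis"),
    action_keys = vapply(x, function(d) paste(d$action_keys, collapse = ";"), character(1)),
    behavior_keys = vapply(x, function(d) paste(d$behavior_keys, collapse = ";"), character(1)),
    series_n_components = vapply(x, function(d)
      if (is.null(d$series)) NA_integer_ else d$series$n_components, integer(1)),
    series_full_threshold = vapply(x, function(d)
      if (is.null(d$series)) NA_integer_ else d$series$full_threshold, integer(1)),
    scaling = vapply(x, `[[`, character(1), "scaling"),
    basis_multiplier = vapply(x, `[[`, numeric(1), "basis_multiplier"),
    placeholder_amount = vapply(x, `[[`, logical(1), "placeholder_amount"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

split_keys <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
}

catalog_from_data_frame <- function(df) {
  required <- c("id", "name", "category", "amount", "incidence_basis", "scaling")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    chw_abort(sprintf("catalog table is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  defs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    series <- NULL
    if ("series_n_components" %in% names(df) && !is.na(row$series_n_components)) {
      series <- list(n_components = row$series_n_components,
                     full_threshold = row$series_full_threshold)
    }
    incentive(
      id = row$id, name = row$name, category = row$category,
      amount = row$amount, incidence_basis = row$incidence_basis,
      action_keys = split_keys(if ("action_keys" %in% names(df)) row$action_keys else ""),
      behavior_keys = split_keys(if ("behavior_keys" %in% names(df)) row$behavior_keys else ""),
      series = series, scaling = row$scaling,
      basis_multiplier = if ("basis_multiplier" %in% names(df) &&
                             !is.na(row$basis_multiplier)) row$basis_multiplier else 1,
      placeholder_amount = if ("placeholder_amount" %in% names(df))
        isTRUE(as.logical(row$placeholder_amount)) else FALSE
    )
  })
  incentive_catalog(defs)
}

#' Load an incentive catalog from JSON or CSV
#'
#' The JSON schema is `{"schema_version": 1, "incentives": [...]}` with one
#' object per incentive mirroring the fields of [incentive()]. The CSV schema
#' is one row per incentive with `;`-separated key lists and optional series
#' columns (`series_n_components`, `series_full_threshold`). An empty
#' incentive list is valid and yields an empty catalog.
#'
#' @param path path to a `.json` or `.csv` file.
#' @return an `incentive_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) chw_abort(sprintf("catalog file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) chw_abort(sprintf(
                      "catalog JSON parse failure in %s: %s", path, conditionMessage(e))))
    if (is.null(doc$schema_version)) {
      chw_abort("catalog JSON is missing field `schema_version`")
    }
    if (doc$schema_version != CATALOG_SCHEMA_VERSION) {
      chw_abort(sprintf("unsupported catalog schema_version %s (expected %d)",
                        doc$schema_version, CATALOG_SCHEMA_VERSION))
    }
    if (is.null(doc$incentives)) chw_abort("catalog JSON is missing field `incentives`")
    defs <- lapply(doc$incentives, function(e) {
      incentive(
        id = e$id %||% chw_abort("catalog entry missing field `id`"),
        name = e$name %||% chw_abort("catalog entry missing field `name`"),
        category = e$category %||% chw_abort("catalog entry missing field `category`"),
        amount = e$amount %||% chw_abort("catalog entry missing field `amount`"),
        incidence_basis = e$incidence_basis %||%
          chw_abort("catalog entry missing field `incidence_basis`"),
        action_keys = unlist(e$action_keys) %||% character(),
        behavior_keys = unlist(e$behavior_keys) %||% character(),
        series = e$series,
        scaling = e$scaling %||% chw_abort("catalog entry missing field `scaling`"),
        basis_multiplier = e$basis_multiplier %||% 1,
        placeholder_amount = e$placeholder_amount %||% FALSE
      )
    })
    incentive_catalog(defs)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(incentive_catalog())
    catalog_from_data_frame(df)
  } else {
    chw_abort(sprintf("unsupported catalog format (expected .json or .csv): %s", path))
  }
}

#' Serialize an incentive catalog
#'
#' Format is chosen from the file extension; round-trips through
#' [load_catalog()] to an equal catalog.
#'
#' @param catalog an `incentive_catalog`.
#' @param path destination `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "incentive_catalog"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    entries <- lapply(unname(catalog), function(d) {
      e <- d[c("id", "name", "category", "amount", "incidence_basis",
               "action_keys", "behavior_keys", "scaling", "basis_multiplier",
               "placeholder_amount")]
      e$action_keys <- as.list(e$action_keys)
      e$behavior_keys <- as.list(e$behavior_keys)
      if (!is.null(d$series)) e$series <- d$series
      e
    })
    jsonlite::write_json(
      list(schema_version = CATALOG_SCHEMA_VERSION, incentives = entries),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(as.data.frame(catalog), path, row.names = FALSE, na = "")
  } else {
    chw_abort(sprintf("unsupported catalog format (expected .json or .csv): %s", path))
  }
  invisible(path)
}

#' All rate keys referenced by a catalog
#'
#' @param catalog an `incentive_catalog`.
#' @return named list with elements `action` and `behavior` (unique keys).
#' @export
rate_keys <- function(catalog) {
  list(
    action = unique(unlist(lapply(catalog, `[[`, "action_keys"))) %||% character(),
    behavior = unique(unlist(lapply(catalog, `[[`, "behavior_keys"))) %||% character()
  )
}

#' Check that a rate set covers a catalog
#'
#' Reports every action/behavior rate key referenced by the catalog but
#' missing from the rate set. An empty report means the catalog is
#' projectable under ACTUAL modes.
#'
#' @param catalog an `incentive_catalog`.
#' @param rates a [rate_set()].
#' @return character vector of missing keys (empty when complete).
#' @export
validate_against_rates <- function(catalog, rates) {
  keys <- rate_keys(catalog)
  referenced <- unique(c(keys$action, keys$behavior))
  missing <- setdiff(referenced, names(rates))
  if (length(missing)) missing else character()
}

#' Observed government payment records
#'
#' Mean monthly payments per incentive category, used as the "observed" arm
#' of the gap decomposition.
#'
#' @param category character vector of categories (subset of
#'   [INCENTIVE_CATEGORIES]).
#' @param mean_monthly_inr nonnegative mean monthly payment per category.
#' @param fiscal_year label, e.g. `"2017-2018"`.
#' @param source free-text provenance label.
#' @return data frame of class `observed_payments`.
#' @export
observed_payments <- function(category, mean_monthly_inr,
                              fiscal_year = NA_character_,
                              source = NA_character_) {
  if (length(category) != length(mean_monthly_inr)) {
    chw_abort("`category` and `mean_monthly_inr` must have the same length")
  }
  if (!all(category %in% INCENTIVE_CATEGORIES)) {
    chw_abort(sprintf("unknown payment category: %s",
                      paste(setdiff(category, INCENTIVE_CATEGORIES), collapse = ", ")))
  }
  if (anyDuplicated(category)) chw_abort("duplicate payment categories")
  if (any(!is.finite(mean_monthly_inr)) || any(mean_monthly_inr < 0)) {
    chw_abort("payments must be finite and >= 0")
  }
  structure(
    data.frame(category = category,
               mean_monthly_inr = as.numeric(mean_monthly_inr),
               fiscal_year = fiscal_year, source = source,
               stringsAsFactors = FALSE),
    class = c("observed_payments", "data.frame")
  )
}

#' Read observed payments from CSV
#'
#' Expected columns: `category`, `mean_monthly_inr`, and optionally
#' `fiscal_year`, `source`.
#'
#' @param path CSV path.
#' @return an `observed_payments` data frame.
#' @export
load_observed_payments <- function(path) {
  if (!file.exists(path)) chw_abort(sprintf("payments file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("category", "mean_monthly_inr"), names(df))
  if (length(missing_cols)) {
    chw_abort(sprintf("payments CSV missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  observed_payments(
    df$category, df$mean_monthly_inr,
    fiscal_year = if ("fiscal_year" %in% names(df)) df$fiscal_year else NA_character_,
    source = if ("source" %in% names(df)) df$source else NA_character_
  )
}
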