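# Gap decomposition: differences among scenario totals and observed payments.
#
#   design gap         = potential (PP) - achievable (PA)
#   lost opportunity   = achievable (PA) - modeled actual (AA)
#   implementation gap = observed - modeled actual (positive => overpayment)

#' Lost opportunity
#'
#' Earnings the CHW forgoes by not completing all actions under her control:
#' achievable (perfect CHW, actual household) minus modeled actual earnings.
#' Nonnegative whenever rates are valid probabilities; a negative value (bad
#' inputs) is returned with a warning.
#'
#' @param pa_total achievable (perfect CHW-actual household) total, INR/month.
#' @param aa_total modeled actual (actual-actual) total, INR/month.
#' @return `pa_total - aa_total`.
#' @export
lost_opportunity <- function(pa_total, aa_total) {
  assert_scalar_number(pa_total, "pa_total")
  assert_scalar_number(aa_total, "aa_total")
  out <- pa_total - aa_total
  if (out < 0) {
    warning("negative lost opportunity: achievable total below modeled actual")
  }
  out
}

#' Implementation gap (overpayment when positive)
#'
#' Observed mean government payment minus modeled actual earnings. A positive
#' gap means the system pays more than the modeled claimable amount --
#' attributed to full payment for partial series completion.
#'
#' @param observed observed mean monthly payment, INR.
#' @param aa_total modeled actual total, INR/month.
#' @return signed `observed - aa_total`.
#' @export
overpayment <- function(observed, aa_total) {
  assert_scalar_number(observed, "observed")
  assert_scalar_number(aa_total, "aa_total")
  observed - aa_total
}

#' Percentage shares of a money breakdown
#'
#' @param values named numeric vector (category -> INR), total > 0.
#' @return data frame with columns `category`, `value`, `share` (unrounded
#'   percent) and `share_pct` (nearest-integer percent for presentation).
#' @export
category_shares <- function(values) {
  if (!is.numeric(values) || is.null(names(values))) {
    chw_abort("`values` must be a named numeric vector")
  }
  total <- sum(values)
  if (!is.finite(total) || total <= 0) {
    chw_contract_error("category shares need a positive total")
  }
  share <- 100 * values / total
  data.frame(category = names(values), value = as.numeric(values),
             share = as.numeric(share), share_pct = as.integer(round(share)),
             row.names = NULL, stringsAsFactors = FALSE)
}

projection_totals <- function(projections) {
  needed <- c("pp", "pa", "ap", "aa")
  if (!is.list(projections) || !all(needed %in% names(projections))) {
    chw_contract_error("`projections` must be a named list with elements pp, pa, ap, aa")
  }
  for (nm in needed) {
    if (!inherits(projections[[nm]], "earnings_projection")) {
      chw_contract_error(sprintf("projections$%s is not an earnings_projection", nm))
    }
  }
  pops <- vapply(projections[needed], function(p) p$catchment$population, numeric(1))
  ids <- lapply(projections[needed], function(p) names(p$per_incentive))
  if (length(unique(pops)) != 1L || length(unique(ids)) != 1L) {
    chw_contract_error("the four projections must share one catalog and catchment")
  }
  projections[needed]
}

#' Full gap report over four scenario projections and observed payments
#'
#' One row per scope (`TOTAL` plus each category) with potential (PP),
#' achievable (PA), modeled actual (AA), observed payments, and the three
#' derived gaps. Shares of the potential base (which activities are designed
#' to earn most) and of the observed base (where earnings actually come from)
#' are attached as the `potential_shares` / `observed_shares` attributes.
#'
#' @param projections named list of the four [project_all()] results
#'   (`pp`, `pa`, `ap`, `aa`) on the same catalog and catchment.
#' @param observed an [observed_payments()] data frame, or `NULL` to omit the
#'   implementation gap.
#' @return data frame of class `gap_report`.
#' @export
gap_report <- function(projections, observed = NULL) {
  projections <- projection_totals(projections)
  cats <- INCENTIVE_CATEGORIES
  obs_by_cat <- stats::setNames(rep(NA_real_, length(cats)), cats)
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "observed_payments"))
    obs_by_cat[observed$category] <- observed$mean_monthly_inr
  }
  scope <- c("TOTAL", cats)
  pick <- function(proj, sc) if (sc == "TOTAL") proj$total else proj$per_category[[sc]]
  rows <- lapply(scope, function(sc) {
    pot <- pick(projections$pp, sc)
    ach <- pick(projections$pa, sc)
    act <- pick(projections$aa, sc)
    obs <- if (sc == "TOTAL") {
      if (all(is.na(obs_by_cat))) NA_real_ else sum(obs_by_cat, na.rm = TRUE)
    } else obs_by_cat[[sc]]
    data.frame(
      scope = sc, potential = pot, achievable = ach, modeled_actual = act,
      observed = obs,
      design_gap = pot - ach,
      lost_opportunity = ach - act,
      implementation_gap = if (is.na(obs)) NA_real_ else obs - act,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  pot_cat <- projections$pp$per_category
  attr(report, "potential_shares") <-
    if (sum(pot_cat) > 0) category_shares(pot_cat) else NULL
  attr(report, "observed_shares") <-
    if (!all(is.na(obs_by_cat)) && sum(obs_by_cat, na.rm = TRUE) > 0)
      category_shares(obs_by_cat[!is.na(obs_by_cat)]) else NULL
  class(report) <- c("gap_report", "data.frame")
  report
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> INR/month (unrounded)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_rupee)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "observed_shares"))) {
    cat("shares of observed payments (%):\n")
    print(attr(x, "observed_shares")[, c("category", "share_pct")], row.names = FALSE)
  }
  invisible(x)
}

#' Bar chart of scenario totals by category
#'
#' Mirrors the usual presentation of the four scenario models: grouped bars of
#' category subtotals under each scenario, with observed payments appended
#' when given.
#'
#' @param projections named list of the four projections (`pp`,`pa`,`ap`,`aa`).
#' @param observed optional [observed_payments()].
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, the plotted matrix.
#' @export
plot_scenario_totals <- function(projections, observed = NULL, file = NULL) {
  projections <- projection_totals(projections)
  m <- sapply(projections, function(p) p$per_category)
  colnames(m) <- toupper(names(projections))
  if (!is.null(observed)) {
    obs <- stats::setNames(rep(0, nrow(m)), rownames(m))
    obs[observed$category] <- observed$mean_monthly_inr
    m <- cbind(m, OBSERVED = obs)
  }
  draw <- function() {
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      ylab = "INR/month", xlab = "scenario",
                      main = "Projected monthly CHW earnings by category")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(m)
}
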