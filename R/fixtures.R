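# Bundled fixtures: a 23-incentive, 5-category catalog skeleton with the
# published amounts where the main text prints them (INR 300 institutional
# delivery, INR 300 ANC series so the combined ANC+ID amount is INR 600,
# INR 100 full immunization in the first year, INR 100 monthly
# recordkeeping) and clearly flagged placeholder amounts elsewhere; the
# demographic-rate table whose crude birth rate (27.28/1,000/year) reproduces
# the published incidence arithmetic; a complete rate set; observed
# per-category payments; and the headline scenario totals, which are
# fixtures by construction (per-incentive rates are not published).

#' Bundled incentive catalog (23 incentives, 5 categories)
#'
#' A faithful structural skeleton of the analysed incentive list, not a
#' verified transcription: only amounts printed in the main analysis are
#' verbatim; entries with `placeholder_amount = TRUE` carry plausible
#' fixture amounts. Mirrors `inst/extdata/catalog.json`.
#'
#' @return an `incentive_catalog` of 23 definitions.
#' @export
fixture_catalog <- function() {
  incentive_catalog(list(
    # --- ANC and institutional delivery -----------------------------------
    incentive("anc_series", "ANC check-up series (4 check-ups)", "ANC_ID", 300,
              "PREGNANCY", action_keys = "anc_home_visit",
              behavior_keys = "anc_full_series_given_visit",
              series = list(n_components = 4, full_threshold = 4)),
    incentive("inst_delivery", "Institutional delivery at public facility",
              "ANC_ID", 300, "PREGNANCY",
              action_keys = "counsel_facility_delivery",
              behavior_keys = "facility_delivery_given_counseling"),
    incentive("preg_registration", "Early pregnancy registration", "ANC_ID",
              100, "PREGNANCY", action_keys = "register_pregnancy",
              placeholder_amount = TRUE),
    incentive("delivery_escort", "Escort to facility for delivery", "ANC_ID",
              100, "PREGNANCY", action_keys = "escort_to_facility",
              behavior_keys = "facility_delivery_given_escort",
              placeholder_amount = TRUE),
    # --- Newborn and child health (PNC) -----------------------------------
    incentive("pnc_series", "Postnatal home-visit series (6 of 7 visits)",
              "PNC", 250, "NEWBORN", action_keys = "pnc_visit_series",
              series = list(n_components = 7, full_threshold = 6),
              placeholder_amount = TRUE),
    incentive("sick_newborn_referral", "Referral of critically sick newborn",
              "PNC", 100, "NEWBORN", action_keys = "identify_sick_newborn",
              behavior_keys = "sncu_admission_given_referral",
              basis_multiplier = 0.1, placeholder_amount = TRUE),
    incentive("sncu_followup", "Follow-up of newborn discharged from SNCU",
              "PNC", 50, "NEWBORN", action_keys = "sncu_followup_visit",
              basis_multiplier = 0.08, placeholder_amount = TRUE),
    incentive("underweight_child_visit", "Monthly visit to severely wasted child",
              "PNC", 50, "CHILD_U5", action_keys = "visit_underweight_child",
              basis_multiplier = 0.04, placeholder_amount = TRUE),
    incentive("nrc_referral", "Referral to nutritional rehabilitation centre",
              "PNC", 100, "CHILD_U5", action_keys = "refer_nrc",
              behavior_keys = "nrc_admission_given_referral",
              basis_multiplier = 0.002, placeholder_amount = TRUE),
    # --- Family planning ---------------------------------------------------
    incentive("female_sterilization", "Female sterilization after 2 children",
              "FP", 300, "ELIGIBLE_COUPLE", action_keys = "counsel_limiting",
              behavior_keys = "sterilization_given_counseling",
              basis_multiplier = 0.008, placeholder_amount = TRUE),
    incentive("male_sterilization", "Male sterilization", "FP", 400,
              "ELIGIBLE_COUPLE", action_keys = "counsel_limiting",
              behavior_keys = "male_sterilization_given_counseling",
              basis_multiplier = 0.0005, placeholder_amount = TRUE),
    incentive("ppiucd", "Postpartum IUCD adoption", "FP", 150, "PREGNANCY",
              action_keys = "counsel_ppiucd",
              behavior_keys = "ppiucd_adoption_given_counseling",
              placeholder_amount = TRUE),
    incentive("birth_spacing", "Two-year birth spacing", "FP", 500,
              "ELIGIBLE_COUPLE", action_keys = "counsel_spacing",
              behavior_keys = "spacing_adopted_given_counseling",
              basis_multiplier = 0.01, placeholder_amount = TRUE),
    incentive("contraceptive_distribution", "Home delivery of contraceptives",
              "FP", 50, "ELIGIBLE_COUPLE",
              action_keys = "home_delivery_contraceptives",
              basis_multiplier = 0.02, placeholder_amount = TRUE),
    incentive("unmet_need_followup", "Follow-up of couples with unmet need",
              "FP", 100, "ELIGIBLE_COUPLE", action_keys = "counsel_spacing",
              basis_multiplier = 0.005, placeholder_amount = TRUE),
    # --- Routine immunization ----------------------------------------------
    incentive("full_immunization_y1", "Full immunization in first year",
              "IMMUNIZATION", 100, "NEWBORN",
              action_keys = "mobilize_immunization",
              behavior_keys = "full_immunization_given_mobilization",
              series = list(n_components = 5, full_threshold = 5)),
    incentive("full_immunization_y2", "Completion of boosters in second year",
              "IMMUNIZATION", 50, "NEWBORN",
              action_keys = "mobilize_immunization",
              behavior_keys = "booster_completion_given_mobilization",
              series = list(n_components = 2, full_threshold = 2),
              placeholder_amount = TRUE),
    incentive("vhnd_mobilization", "Village health and nutrition day mobilization",
              "IMMUNIZATION", 150, "ROUTINE", action_keys = "attend_vhnd",
              scaling = "FIXED", placeholder_amount = TRUE),
    incentive("imm_session_support", "Immunization session support", "IMMUNIZATION",
              50, "NEWBORN", action_keys = "mobilize_immunization",
              placeholder_amount = TRUE),
    # --- Routine recurring activities --------------------------------------
    incentive("recordkeeping", "Monthly recordkeeping of births and deaths",
              "ROUTINE", 100, "ROUTINE", action_keys = "recordkeeping",
              scaling = "FIXED"),
    incentive("household_survey_update", "Village household survey update",
              "ROUTINE", 100, "ROUTINE", action_keys = "update_household_survey",
              scaling = "FIXED", placeholder_amount = TRUE),
    incentive("monthly_meeting", "Attendance at monthly block meeting",
              "ROUTINE", 150, "ROUTINE", action_keys = "attend_block_meeting",
              scaling = "FIXED", placeholder_amount = TRUE),
    incentive("eligible_couple_list", "Eligible-couple register update",
              "ROUTINE", 100, "ROUTINE", action_keys = "update_couple_list",
              scaling = "FIXED", placeholder_amount = TRUE)
  ))
}

#' Bundled demographic-rate table
#'
#' The crude-birth-rate proxy for pregnant-woman (and newborn) incidence is
#' 27.28 per 1,000 per year, the value under which the published worked
#' chain is exact: 27.28 / 12 = 2.2733 events per month in a catchment of
#' 1,000 (printed as 2.3), and 2.2733 x 300 = 682.0.
#'
#' @return a `demographic_rates` table.
#' @export
fixture_demographic_rates <- function() {
  demographic_rates(
    keys = c("PREGNANCY", "NEWBORN", "CHILD_U5", "ELIGIBLE_COUPLE",
             "INFANT_MORTALITY", "NEONATAL_MORTALITY", "SEVERE_WASTING_U5"),
    values = c(27.28, 27.28, 0.136, 0.17, 43, 30, 0.04),
    basis = c("PER_1000_PER_YEAR", "PER_1000_PER_YEAR", "PROPORTION",
              "PROPORTION", "PER_1000_PER_YEAR", "PER_1000_PER_YEAR",
              "PROPORTION"),
    description = c(
      "annual crude birth rate, rural; proxies monthly pregnant-woman incidence",
      "annual live births per 1,000 population",
      "children under 5 as a share of total population (census projection)",
      "eligible couples as a share of total population",
      "infant deaths per 1,000 live births per year (informational fixture)",
      "neonatal deaths per 1,000 live births per year (informational fixture)",
      "severely wasted share among children under 5"
    ),
    source = c("vital-registration bulletin (fixture)",
               "vital-registration bulletin (fixture)",
               "census projection (fixture)", "government order (fixture)",
               "vital-registration bulletin (fixture)",
               "vital-registration report (fixture)",
               "child nutrition survey (fixture)")
  )
}

#' Bundled rate set covering the fixture catalog
#'
#' CHW action and conditional household behavior probabilities. The three
#' rates printed in the published worked chains are verbatim (counseling
#' coverage 0.6, facility delivery given counseling 0.66, recordkeeping
#' 0.75), as are the two published series completion rates (0.264 for 4+ ANC
#' check-ups, 0.511 full immunization); the rest are synthetic placeholders.
#'
#' @return a [rate_set()].
#' @export
fixture_rate_set <- function() {
  action <- c(
    anc_home_visit = 0.55,
    counsel_facility_delivery = 0.6,
    register_pregnancy = 0.7,
    escort_to_facility = 0.5,
    pnc_visit_series = 0.22,
    identify_sick_newborn = 0.4,
    sncu_followup_visit = 0.35,
    visit_underweight_child = 0.3,
    refer_nrc = 0.25,
    counsel_limiting = 0.45,
    counsel_spacing = 0.4,
    home_delivery_contraceptives = 0.5,
    counsel_ppiucd = 0.35,
    mobilize_immunization = 0.65,
    attend_vhnd = 0.8,
    recordkeeping = 0.75,
    update_household_survey = 0.7,
    attend_block_meeting = 0.85,
    update_couple_list = 0.6
  )
  behavior <- c(
    anc_full_series_given_visit = 0.264,
    facility_delivery_given_counseling = 0.66,
    facility_delivery_given_escort = 0.68,
    sncu_admission_given_referral = 0.5,
    nrc_admission_given_referral = 0.35,
    sterilization_given_counseling = 0.04,
    male_sterilization_given_counseling = 0.005,
    ppiucd_adoption_given_counseling = 0.1,
    spacing_adopted_given_counseling = 0.15,
    full_immunization_given_mobilization = 0.511,
    booster_completion_given_mobilization = 0.4
  )
  values <- c(action, behavior)
  prov <- rep("SYNTHETIC", length(values))
  names(prov) <- names(values)
  prov[c("counsel_facility_delivery", "facility_delivery_given_counseling")] <-
    "linked household survey"
  prov["recordkeeping"] <- "recordkeeping audit"
  prov["anc_full_series_given_visit"] <- "government health statistics"
  prov["full_immunization_given_mobilization"] <- "national family health survey"
  rate_set(values, provenance = prov)
}

#' Bundled series completion-count distributions
#'
#' Conditional on CHW contact where the series is a household behavior. The
#' fixture distributions are constructed so that the probability of reaching
#' the full threshold equals the corresponding completion rate in
#' [fixture_rate_set()] (e.g. P(ANC count >= 4) = 0.264), which keeps the
#' analytic engine and the synthetic generator mutually consistent.
#'
#' @return named list of [series_distribution()] objects.
#' @export
fixture_series_params <- function() {
  list(
    anc_series = series_distribution(
      "anc_series", c(0.25, 0.20, 0.15, 0.136, 0.264)),        # P(>=4) = 0.264
    pnc_series = series_distribution(
      "pnc_series", c(0.10, 0.15, 0.15, 0.15, 0.12, 0.11, 0.12, 0.10)), # P(>=6) = 0.22
    full_immunization_y1 = series_distribution(
      "full_immunization_y1", c(0.08, 0.10, 0.12, 0.10, 0.089, 0.511)), # P(>=5) = 0.511
    full_immunization_y2 = series_distribution(
      "full_immunization_y2", c(0.30, 0.30, 0.40))              # P(>=2) = 0.40
  )
}

#' Bundled background (no CHW contact) series distributions
#'
#' Completion counts for household series behaviors in the absence of CHW
#' contact; mass shifted toward zero. Counts arising here are never
#' claimable. The PNC series is the CHW's own visits, so it has no
#' background distribution.
#'
#' @return named list of [series_distribution()] objects.
#' @export
fixture_background_series_params <- function() {
  list(
    anc_series = series_distribution(
      "anc_series", c(0.60, 0.20, 0.10, 0.06, 0.04)),
    full_immunization_y1 = series_distribution(
      "full_immunization_y1", c(0.40, 0.20, 0.15, 0.10, 0.08, 0.07)),
    full_immunization_y2 = series_distribution(
      "full_immunization_y2", c(0.60, 0.25, 0.15))
  )
}

#' Bundled observed government payments by category
#'
#' Mean monthly payments per category: routine activities 941, ANC and
#' institutional delivery 789, newborn and child health 376, routine
#' immunization 387, and family planning 87 (the residual closing the 2,580
#' total), fiscal year 2017-2018.
#'
#' @return an [observed_payments()] data frame.
#' @export
fixture_observed_payments <- function() {
  observed_payments(
    category = c("ROUTINE", "ANC_ID", "PNC", "IMMUNIZATION", "FP"),
    mean_monthly_inr = c(941, 789, 376, 387, 87),
    fiscal_year = "2017-2018",
    source = "state payment records (bundled fixture)"
  )
}

#' Bundled headline scenario totals
#'
#' The published grand totals are not recomputable from printed inputs
#' (per-incentive rates live in unpublished supplementary tables); they enter
#' the gap arithmetic as fixtures: potential (perfect-perfect) 5,867,
#' achievable (perfect CHW-actual household) 3,000, modeled actual 1,325 and
#' observed payments 2,580 INR/month.
#'
#' @return named list with elements `pp`, `pa`, `aa`, `observed`.
#' @export
fixture_scenario_totals <- function() {
  list(pp = 5867, pa = 3000, aa = 1325, observed = 2580)
}

#' Bundled questionnaire proportions
#'
#' Proportions driving the synthetic CHW questionnaire: claim-experience
#' items (payment perceived difficult 0.72; delays always/most of the time
#' 0.55; payment breakup unknown 0.65; partial payment 0.47; sign-off hard
#' 0.26; paying to get incentives 0.26), last-payment recency (previous month
#' 0.34, two months 0.31, earlier 0.35), payment covering 2+ months of work
#' 0.55, and the institutional-delivery awareness pattern (aware 1.00, exact
#' amount correct 0.30, modal wrong answer 600 with share 0.68).
#'
#' @return named list of proportions.
#' @export
fixture_questionnaire_props <- function() {
  list(
    payment_difficult = 0.72,
    delays_frequent = 0.55,
    unknown_breakup = 0.65,
    partial_payment = 0.47,
    signoff_hard = 0.26,
    pay_to_get = 0.26,
    recency = c(`1_month` = 0.34, `2_months` = 0.31, `3plus_months` = 0.35),
    months_covered_2plus = 0.55,
    aware_id = 1.00,
    exact_amount_id = 0.30,
    modal_wrong_share = 0.68,
    modal_wrong_amount = 600,
    correct_amount = 300,
    other_wrong_amount = 200
  )
}

#' Path to a bundled extdata fixture file
#'
#' @param file file name under `inst/extdata`, or empty for the directory.
#' @return absolute path.
#' @export
chwearn_extdata <- function(file = "") {
  system.file("extdata", file, package = "chwearn", mustWork = nzchar(file))
}
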