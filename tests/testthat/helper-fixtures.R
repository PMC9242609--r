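# Shared helpers: small catalogs, random case generators for the property
# suites, and Monte-Carlo standard errors. All fixtures are built in code.

demo_fix <- fixture_demographic_rates()
rates_fix <- fixture_rate_set()

# single-incentive helpers -------------------------------------------------

delivery_incentive <- function(amount = 300) {
  incentive("inst_delivery", "institutional delivery", "ANC_ID", amount,
            "PREGNANCY", action_keys = "counsel_facility_delivery",
            behavior_keys = "facility_delivery_given_counseling")
}

recordkeeping_incentive <- function(amount = 100) {
  incentive("recordkeeping", "monthly recordkeeping", "ROUTINE", amount,
            "ROUTINE", action_keys = "recordkeeping", scaling = "FIXED")
}

anc_like_incentive <- function(amount = 300) {
  incentive("anc_series", "ANC series", "ANC_ID", amount, "PREGNANCY",
            action_keys = "anc_home_visit",
            behavior_keys = "anc_full_series_given_visit",
            series = list(n_components = 4, full_threshold = 4))
}

pnc_like_incentive <- function(amount = 250) {
  incentive("pnc_series", "PNC visit series", "PNC", amount, "NEWBORN",
            action_keys = "pnc_visit_series",
            series = list(n_components = 7, full_threshold = 6))
}

series_test_incentive <- function(K = 2, k_full = K, amount = 100) {
  incentive("series_test", "test series", "PNC", amount, "NEWBORN",
            action_keys = "pnc_visit_series",
            series = list(n_components = K, full_threshold = k_full))
}

# random-case generators for property tests --------------------------------

random_simplex <- function(n) {
  g <- stats::rgamma(n, shape = 1)
  g / sum(g)
}

random_case <- function() {
  n_act <- sample(0:2, 1)
  n_beh <- sample(0:2, 1)
  routine <- n_beh == 0 && stats::runif(1) < 0.3
  act <- if (n_act) paste0("a", seq_len(n_act)) else character()
  beh <- if (n_beh) paste0("b", seq_len(n_beh)) else character()
  inc <- incentive(
    "x", "random case", sample(INCENTIVE_CATEGORIES, 1),
    amount = stats::runif(1, 1, 1000),
    incidence_basis = if (routine) "ROUTINE" else
      sample(c("PREGNANCY", "NEWBORN", "CHILD_U5", "ELIGIBLE_COUPLE"), 1),
    action_keys = act, behavior_keys = beh,
    scaling = if (routine) "FIXED" else "POPULATION",
    basis_multiplier = stats::runif(1, 0.01, 1)
  )
  keys <- c(act, beh)
  rates <- if (length(keys)) {
    rate_set(stats::setNames(stats::runif(length(keys)), keys))
  } else {
    rate_set(c(dummy = 0.5))
  }
  list(inc = inc, rates = rates)
}

project4 <- function(inc, rates, catch = catchment(1000)) {
  vapply(c("pp", "pa", "ap", "aa"), function(code)
    project_incentive(inc, code, rates, demo_fix, catch), numeric(1))
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)
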