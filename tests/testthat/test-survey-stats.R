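test_that("prop_summary: interval behaviour and small-n fallback", {
  s <- prop_summary("item", 72, 100)
  expect_equal(s$proportion, 0.72)
  expect_true(s$ci_lower < 0.72 && s$ci_upper > 0.72)
  # width shrinks like 1/sqrt(n) on nested samples
  widths <- vapply(c(100, 400, 1600), function(n)
    with(prop_summary("i", round(0.3 * n), n), ci_upper - ci_lower), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.1)
  # boundary/small-n cases use the exact interval and stay in [0, 1]
  s0 <- prop_summary("i", 0, 20)
  expect_identical(s0$ci_lower, 0)
  sN <- prop_summary("i", 20, 20)
  expect_identical(sN$ci_upper, 1)
  expect_error(prop_summary("i", 5, 0), class = "chwearn_contract_error")
  expect_error(prop_summary("i", 6, 5), class = "chwearn_contract_error")
})

test_that("estimate_rates recovers generator truth on a moderate sample", {
  catalog <- incentive_catalog(list(delivery_incentive(),
                                    recordkeeping_incentive()))
  true_rates <- rate_set(c(counsel_facility_delivery = 0.6,
                           facility_delivery_given_counseling = 0.66,
                           recordkeeping = 0.75))
  config <- generator_config(seed = 41, n_chw = 500, months = 12,
                             true_rates = true_rates, n_questionnaire = 10)
  sim <- generate_microdata(config, catalog)
  est <- estimate_rates(sim$households, catalog, sim$chw_months)
  n_ben <- nrow(sim$households)
  expect_lt(abs(est[["counsel_facility_delivery"]] - 0.6),
            3 * binom_se(0.6, n_ben))
  n_contact <- sum(sim$households$contact_counsel_facility_delivery == 1)
  expect_lt(abs(est[["facility_delivery_given_counseling"]] - 0.66),
            3 * binom_se(0.66, n_contact))
  expect_lt(abs(est[["recordkeeping"]] - 0.75), 3 * binom_se(0.75, 500 * 12))
  expect_identical(unique(attr(est, "provenance")), "ESTIMATED")
})

test_that("estimate_rates: all-contact data, empty strata, order invariance", {
  catalog <- incentive_catalog(list(delivery_incentive()))
  base <- generate_microdata(
    generator_config(seed = 3, n_chw = 100, months = 6,
                     true_rates = rate_set(c(counsel_facility_delivery = 1,
                                             facility_delivery_given_counseling = 0.66)),
                     n_questionnaire = 5),
    catalog)
  est <- estimate_rates(base$households, catalog)
  expect_identical(est[["counsel_facility_delivery"]], 1)

  # zero contacted beneficiaries: conditional behavior rate omitted with warning
  none <- generate_microdata(
    generator_config(seed = 3, n_chw = 100, months = 6,
                     true_rates = rate_set(c(counsel_facility_delivery = 0,
                                             facility_delivery_given_counseling = 0.66)),
                     n_questionnaire = 5),
    catalog)
  expect_warning(est0 <- estimate_rates(none$households, catalog),
                 "empty conditioning stratum")
  expect_false("facility_delivery_given_counseling" %in% names(est0))

  # row order does not change estimates
  shuffled <- base$households[sample(nrow(base$households)), ]
  expect_equal(as.numeric(estimate_rates(shuffled, catalog)),
               as.numeric(est), tolerance = 1e-12)
})

test_that("series completion keys are estimated from counts, conditionally", {
  catalog <- incentive_catalog(list(anc_like_incentive(), pnc_like_incentive()))
  config <- generator_config(
    seed = 13, n_chw = 800, months = 12,
    true_rates = rate_set(c(anc_home_visit = 0.55,
                            anc_full_series_given_visit = 0.264,
                            pnc_visit_series = 0.22)),
    n_questionnaire = 5)
  sim <- generate_microdata(config, catalog)
  est <- estimate_rates(sim$households, catalog)
  hh <- sim$households
  anc <- hh[hh$incentive_id == "anc_series" & hh$contact_anc_home_visit == 1, ]
  expect_lt(abs(est[["anc_full_series_given_visit"]] - 0.264),
            3 * binom_se(0.264, nrow(anc)))
  n_pnc <- sum(hh$incentive_id == "pnc_series")
  expect_lt(abs(est[["pnc_visit_series"]] - 0.22), 3 * binom_se(0.22, n_pnc))
})

test_that("claim-experience summaries recover the generator proportions", {
  config <- generator_config(seed = 29, n_chw = 2, months = 1,
                             true_rates = fixture_rate_set())
  chws <- generate_microdata(config, incentive_catalog())$chws
  expect_identical(nrow(chws), 1502L)
  ce <- claim_experience_summary(chws)
  expected <- c(payment_difficult = 0.72, delays_frequent = 0.55,
                unknown_breakup = 0.65, partial_payment = 0.47,
                signoff_hard = 0.26, pay_to_get = 0.26,
                months_covered_2plus = 0.55,
                recency_1_month = 0.34, recency_2_months = 0.31,
                recency_3plus_months = 0.35)
  for (item in names(expected)) {
    row <- ce[ce$item == item, ]
    expect_identical(nrow(row), 1L)
    expect_lt(abs(row$proportion - expected[[item]]),
              3 * binom_se(expected[[item]], 1502))
  }
  # recency categories partition the sample
  expect_identical(sum(ce$numerator[grepl("^recency_", ce$item)]), 1502L)
  # all-true item is exactly 100%
  all_true <- chws; all_true$payment_difficult <- TRUE
  ce2 <- claim_experience_summary(all_true)
  expect_equal(ce2$proportion[ce2$item == "payment_difficult"], 1)
})

test_that("awareness summaries recover the 1.00 / 0.30 / modal-600 pattern", {
  config <- generator_config(seed = 37, n_chw = 2, months = 1,
                             true_rates = fixture_rate_set())
  chws <- generate_microdata(config, incentive_catalog())$chws
  aw <- awareness_summary(chws)
  expect_equal(aw$proportion[aw$item == "aware_institutional_delivery"], 1)
  expect_lt(abs(aw$proportion[aw$item == "exact_amount_institutional_delivery"] -
                  0.30), 3 * binom_se(0.30, 1502))
  expect_identical(attr(aw, "modal_wrong_amount"), 600)
  expect_lt(abs(aw$proportion[aw$item == "modal_wrong_amount_600"] - 0.68),
            3 * binom_se(0.68, 1502))
  # exact-correct implies aware by construction
  expect_true(all(chws$aware_id[chws$exact_amount_correct]))

  # nobody aware: exact-correct is 0 by the invariant
  q <- fixture_questionnaire_props()
  q$aware_id <- 0; q$exact_amount_id <- 0; q$modal_wrong_share <- 0
  none <- generate_microdata(
    generator_config(seed = 37, n_chw = 2, months = 1, questionnaire = q,
                     n_questionnaire = 50, true_rates = fixture_rate_set()),
    incentive_catalog())$chws
  aw0 <- awareness_summary(none)
  expect_equal(aw0$proportion[aw0$item == "exact_amount_institutional_delivery"], 0)

  # violating input is rejected
  bad <- chws; bad$exact_amount_correct[1] <- TRUE; bad$aware_id[1] <- FALSE
  expect_error(awareness_summary(bad), class = "chwearn_validation_error")
})
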