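mini_catalog <- function() {
  incentive_catalog(list(delivery_incentive(), anc_like_incentive(),
                         recordkeeping_incentive()))
}

mini_rates <- function(action = 0.6, behavior = 0.66) {
  rate_set(c(counsel_facility_delivery = action,
             facility_delivery_given_counseling = behavior,
             anc_home_visit = 0.55, anc_full_series_given_visit = 0.264,
             recordkeeping = 0.75))
}

mini_config <- function(seed = 7, n_chw = 50, months = 6, ...) {
  generator_config(seed = seed, n_chw = n_chw, months = months,
                   true_rates = mini_rates(),
                   series_params = fixture_series_params()["anc_series"],
                   n_questionnaire = 40, ...)
}

test_that("generation is deterministic under a seed and varies across seeds", {
  s1 <- generate_microdata(mini_config(seed = 7), mini_catalog())
  s2 <- generate_microdata(mini_config(seed = 7), mini_catalog())
  s3 <- generate_microdata(mini_config(seed = 8), mini_catalog())
  expect_identical(s1$households, s2$households)
  expect_identical(s1$chws, s2$chws)
  expect_identical(s1$payments, s2$payments)
  expect_false(identical(s1$households, s3$households))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_microdata(mini_config(), mini_catalog()))
  expect_identical(stats::runif(1), before)
})

test_that("claimability: behaviors without the required contact never pay", {
  sim <- generate_microdata(mini_config(n_chw = 120, months = 12), mini_catalog())
  hh <- sim$households
  id_rows <- hh[hh$incentive_id == "inst_delivery", ]
  # background behavior exists (outcomes without contact) ...
  expect_gt(sum(id_rows$outcome_facility_delivery_given_counseling == 1 &
                  id_rows$contact_counsel_facility_delivery == 0), 0)
  # ... but is never claimable
  expect_true(all(id_rows$claimable[id_rows$contact_counsel_facility_delivery == 0] == 0))
  anc_rows <- hh[hh$incentive_id == "anc_series", ]
  expect_true(all(anc_rows$claimable[anc_rows$contact_anc_home_visit == 0] == 0))
  # claims match the strict rule exactly
  expect_identical(
    id_rows$claimable,
    as.integer(id_rows$contact_counsel_facility_delivery == 1 &
                 id_rows$outcome_facility_delivery_given_counseling == 1))
  expect_identical(
    anc_rows$claimable,
    as.integer(anc_rows$contact_anc_home_visit == 1 & anc_rows$series_count >= 4))
})

test_that("certainty case: rates of 1 make every beneficiary claimable and
           the simulated mean equals the perfect-perfect projection", {
  catalog <- incentive_catalog(list(delivery_incentive()))
  config <- generator_config(
    seed = 31, n_chw = 300, months = 12,
    true_rates = rate_set(c(counsel_facility_delivery = 1,
                            facility_delivery_given_counseling = 1)),
    background_rates = c(facility_delivery_given_counseling = 0.3),
    n_questionnaire = 10)
  sim <- generate_microdata(config, catalog)
  expect_true(all(sim$households$claimable == 1))
  sim_mean <- summarize_payments(sim, by = "total")
  pp <- project_all(catalog, "pp", config$true_rates, config$demo)$total
  # only Poisson noise in beneficiary counts remains
  mc_se <- pp / sqrt(2.2733 * 300 * 12)
  expect_lt(abs(sim_mean - pp), 3 * mc_se)
})

test_that("strict-rule mean payments converge to the actual-actual projection", {
  config <- mini_config(seed = 17, n_chw = 2000, months = 12)
  sim <- generate_microdata(config, mini_catalog())
  sim_cat <- summarize_payments(sim, by = "category")
  aa <- project_all(mini_catalog(), "aa", mini_rates(), config$demo)
  for (cat_ in sim_cat$category) {
    expect_equal(sim_cat$mean_monthly_inr[sim_cat$category == cat_],
                 aa$per_category[[cat_]], tolerance = 0.05)
  }
  expect_equal(summarize_payments(sim, by = "total"), aa$total, tolerance = 0.03)
})

test_that("partial-completion payment rules pay more than the strict rule", {
  strict <- generate_microdata(mini_config(seed = 5, n_chw = 500, months = 12),
                               mini_catalog())
  relaxed <- generate_microdata(
    mini_config(seed = 5, n_chw = 500, months = 12,
                payment_rules = c(anc_series = 1L)),
    mini_catalog())
  s <- summarize_payments(strict, by = "incentive")
  r <- summarize_payments(relaxed, by = "incentive")
  expect_gt(r$mean_monthly_inr[r$incentive == "anc_series"],
            s$mean_monthly_inr[s$incentive == "anc_series"])
})

test_that("microdata round-trips through CSV with identical summaries", {
  sim <- generate_microdata(mini_config(n_chw = 60, months = 6), mini_catalog())
  dir <- withr::local_tempdir()
  write_microdata(sim, dir)
  back <- read_microdata(dir)
  expect_equal(
    estimate_rates(back$households, mini_catalog(), back$chw_months),
    estimate_rates(sim$households, mini_catalog(), sim$chw_months),
    tolerance = 1e-12)
  expect_equal(summarize_payments(back$payments, "category"),
               summarize_payments(sim, "category"))
  expect_equal(claim_experience_summary(back$chws),
               claim_experience_summary(sim$chws))
  expect_identical(back$manifest$seed, sim$config$seed)
})

test_that("routine-only catalogs yield header-only household files", {
  catalog <- incentive_catalog(list(recordkeeping_incentive()))
  config <- generator_config(seed = 2, n_chw = 5, months = 2,
                             true_rates = rate_set(c(recordkeeping = 0.75)),
                             n_questionnaire = 5)
  sim <- generate_microdata(config, catalog)
  expect_identical(nrow(sim$households), 0L)
  dir <- withr::local_tempdir()
  write_microdata(sim, dir)
  expect_identical(nrow(utils::read.csv(file.path(dir, "households.csv"))), 0L)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(generator_config(seed = 1.5), class = "chwearn_validation_error")
  expect_error(generator_config(n_chw = 0), class = "chwearn_validation_error")
  q <- fixture_questionnaire_props(); q$payment_difficult <- 1.4
  expect_error(generator_config(questionnaire = q),
               class = "chwearn_validation_error")
  q2 <- fixture_questionnaire_props(); q2$exact_amount_id <- 0.9; q2$aware_id <- 0.5
  expect_error(generator_config(questionnaire = q2),
               class = "chwearn_validation_error")
  # catalog rates must be covered
  expect_error(
    generate_microdata(generator_config(true_rates = rate_set(c(x = 0.5)),
                                        n_questionnaire = 5),
                       incentive_catalog(list(delivery_incentive()))),
    class = "chwearn_validation_error")
  # series incentive without a completion distribution
  expect_error(
    generate_microdata(
      generator_config(true_rates = mini_rates(), series_params = list(),
                       n_questionnaire = 5),
      incentive_catalog(list(anc_like_incentive()))),
    class = "chwearn_validation_error")
})
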