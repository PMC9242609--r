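test_that("expected series payment: certainty and enumerated cases", {
  inc <- series_test_incentive(K = 2, k_full = 2, amount = 100)
  # all mass at K: every beneficiary completes, any threshold pays in full
  certain <- series_distribution("series_test", c(0, 0, 1))
  for (k in 1:2) {
    expect_equal(expected_series_payment(inc, certain, k, incidence = 1.7),
                 1.7 * 100)
  }
  # dist {p0 = 0.5, p1 = 0.3, p2 = 0.2}: P(>=1) = 0.5, P(>=2) = 0.2
  dist <- series_distribution("series_test", c(0.5, 0.3, 0.2))
  expect_equal(expected_series_payment(inc, dist, 1, 1), 50)
  expect_equal(expected_series_payment(inc, dist, 2, 1), 20)
})

test_that("contract and validation errors for malformed series inputs", {
  inc <- series_test_incentive(K = 2)
  dist <- series_distribution("series_test", c(0.5, 0.3, 0.2))
  expect_error(expected_series_payment(inc, dist, 0, 1),
               class = "chwearn_contract_error")
  expect_error(expected_series_payment(inc, dist, 3, 1),
               class = "chwearn_contract_error")
  expect_error(series_distribution("x", c(0.5, 0.6)),
               class = "chwearn_validation_error")
  expect_error(series_distribution("x", c(-0.1, 1.1)),
               class = "chwearn_validation_error")
  # K mismatch with the incentive's component count
  dist3 <- series_distribution("series_test", c(0.25, 0.25, 0.25, 0.25))
  expect_error(expected_series_payment(inc, dist3, 1, 1),
               class = "chwearn_contract_error")
  nonseries <- delivery_incentive()
  expect_error(expected_series_payment(nonseries, dist, 1, 1),
               class = "chwearn_contract_error")
})

test_that("survival-function monotonicity and the incidence x amount bound", {
  set.seed(21)
  for (i in 1:50) {
    K <- sample(2:8, 1)
    dist <- series_distribution("series_test", random_simplex(K + 1))
    inc <- series_test_incentive(K = K, k_full = K,
                                 amount = stats::runif(1, 10, 500))
    incidence <- stats::runif(1, 0, 5)
    exp_k <- vapply(seq_len(K), function(k)
      expected_series_payment(inc, dist, k, incidence), numeric(1))
    expect_true(all(diff(exp_k) <= 1e-12))
    expect_true(all(exp_k <= incidence * inc$amount + 1e-12))
  }
})

test_that("fit_relaxation: exact-strict observation and zero observation", {
  inc <- series_test_incentive(K = 4, k_full = 4, amount = 200)
  dist <- series_distribution("series_test", c(0.2, 0.2, 0.2, 0.2, 0.2))
  incidence <- 2
  strict <- expected_series_payment(inc, dist, 4, incidence)
  fit <- fit_relaxation(inc, dist, incidence, strict)
  expect_identical(fit$fitted_threshold, 4L)
  expect_equal(fit$discrepancy, 0)
  # observed 0: the smallest candidate expectation is at the full threshold
  fit0 <- fit_relaxation(inc, dist, incidence, 0)
  expect_identical(fit0$fitted_threshold, 4L)
  expect_equal(nrow(fit0$candidates), 4L)
  expect_error(fit_relaxation(inc, dist, incidence, -1),
               class = "chwearn_contract_error")
})

test_that("ties break toward the largest (least relaxed) threshold", {
  inc <- series_test_incentive(K = 2, k_full = 2, amount = 100)
  dist <- series_distribution("series_test", c(0.4, 0.3, 0.3))
  # expectations at k = 1, 2 are 60 and 30; observed 45 is equidistant
  fit <- fit_relaxation(inc, dist, incidence = 1, observed = 45)
  expect_identical(fit$fitted_threshold, 2L)
})

test_that("generative recovery: payments simulated under a relaxed rule fit back", {
  # >= 10,000 beneficiary-months under a 2+-of-7 payment rule
  catalog <- incentive_catalog(list(pnc_like_incentive()))
  config <- generator_config(
    seed = 99, n_chw = 400, months = 12,
    true_rates = rate_set(c(pnc_visit_series = 0.22)),
    series_params = fixture_series_params()["pnc_series"],
    payment_rules = c(pnc_series = 2L),
    n_questionnaire = 10
  )
  sim <- generate_microdata(config, catalog)
  expect_gt(nrow(sim$households), 10000)
  observed <- summarize_payments(sim, by = "incentive")
  inc <- catalog[["pnc_series"]]
  incidence <- beneficiary_incidence(inc, config$demo, catchment(1000))
  fit <- fit_relaxation(inc, fixture_series_params()$pnc_series, incidence,
                        observed$mean_monthly_inr[observed$incentive == "pnc_series"])
  expect_identical(fit$fitted_threshold, 2L)
})

test_that("series distributions load from the bundled CSV", {
  dists <- load_series_distributions(chwearn_extdata("series_distributions.csv"))
  expect_setequal(names(dists), c("anc_series", "pnc_series",
                                  "full_immunization_y1", "full_immunization_y2"))
  expect_equal(dists$anc_series$probabilities,
               fixture_series_params()$anc_series$probabilities)
  expect_identical(dists$pnc_series$K, 7L)
})
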