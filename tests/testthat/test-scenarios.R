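test_that("effective_rate: perfect mode is identity, actual mode multiplies", {
  rates <- rate_set(c(anc_counseling = 0.6, k1 = 0.5, k2 = 0.5))
  expect_identical(effective_rate("PERFECT", "anc_counseling", rates), 1)
  expect_identical(effective_rate("ACTUAL", character(), rates), 1)
  expect_equal(effective_rate("ACTUAL", "anc_counseling", rates), 0.6)
  # independence product, checked against enumeration of the joint Bernoulli
  # outcomes of (k1, k2)
  joint <- expand.grid(x1 = 0:1, x2 = 0:1)
  p <- with(joint, (0.5^x1 * 0.5^(1 - x1)) * (0.5^x2 * 0.5^(1 - x2)))
  oracle <- sum(p[joint$x1 == 1 & joint$x2 == 1])
  expect_equal(effective_rate("ACTUAL", c("k1", "k2"), rates), oracle)
  expect_equal(oracle, 0.25)
  expect_error(effective_rate("ACTUAL", "absent", rates),
               class = "chwearn_config_error")
  expect_error(effective_rate("ACTUAL", "k1", NULL),
               class = "chwearn_config_error")
})

test_that("published worked chains reproduce per incentive", {
  id <- delivery_incentive()
  rk <- recordkeeping_incentive()
  rates <- rates_fix
  # perfect-perfect: 2.2733 x 300 = 682.0 (both rounding modes)
  for (mode in c("FULL_PRECISION", "PAPER_ROUNDING")) {
    expect_equal(project_incentive(id, "pp", rates, demo_fix, rounding_mode = mode),
                 682, tolerance = 1e-6)
  }
  # actual-actual with the printed chain: 2.2733 x 0.6 x 0.66 -> 0.9 -> 270
  expect_equal(project_incentive(id, "aa", rates, demo_fix,
                                 rounding_mode = "PAPER_ROUNDING"), 270)
  # full precision keeps 0.90024 x 300 = 270.072
  expect_equal(project_incentive(id, "aa", rates, demo_fix), 270.072,
               tolerance = 1e-6)
  # routine recordkeeping in actual-CHW modes: 1 x 0.75 x 100 = 75
  expect_equal(project_incentive(rk, "ap", rates, demo_fix,
                                 rounding_mode = "PAPER_ROUNDING"), 75)
  expect_equal(project_incentive(rk, "aa", rates, demo_fix), 75)
})

test_that("incentives without behavior keys ignore the household mode", {
  rk <- recordkeeping_incentive()
  expect_equal(project_incentive(rk, "pp", rates_fix, demo_fix),
               project_incentive(rk, "pa", rates_fix, demo_fix))
  expect_equal(project_incentive(rk, "ap", rates_fix, demo_fix),
               project_incentive(rk, "aa", rates_fix, demo_fix))
})

test_that("project_all aggregates: routine catalog and empty catalog", {
  catalog <- incentive_catalog(list(recordkeeping_incentive()))
  rates <- rate_set(c(recordkeeping = 0.75))
  totals <- vapply(c("pp", "pa", "ap", "aa"), function(code)
    project_all(catalog, code, rates, demo_fix)$total, numeric(1))
  expect_equal(unname(totals), c(100, 100, 75, 75))

  empty <- project_all(incentive_catalog(), "pp", rates, demo_fix)
  expect_identical(empty$total, 0)
  expect_true(all(empty$per_category == 0))
})

test_that("category subtotals sum to member incentives and total", {
  proj <- project_all(fixture_catalog(), "aa", rates_fix, demo_fix)
  expect_equal(sum(proj$per_incentive), proj$total)
  expect_equal(sum(proj$per_category), proj$total)
  cats <- vapply(fixture_catalog(), `[[`, character(1), "category")
  for (cat_ in INCENTIVE_CATEGORIES) {
    expect_equal(proj$per_category[[cat_]],
                 sum(proj$per_incentive[cats == cat_]))
  }
})

test_that("factorization: AA = a x PA and AA = h x AP for one-key incentives", {
  set.seed(4)
  for (i in 1:25) {
    a <- stats::runif(1); h <- stats::runif(1)
    rates <- rate_set(c(act = a, beh = h))
    inc <- incentive("x", "x", "ANC_ID", stats::runif(1, 1, 500), "PREGNANCY",
                     action_keys = "act", behavior_keys = "beh")
    v <- project4(inc, rates)
    expect_equal(v[["aa"]], a * v[["pa"]], tolerance = 1e-10)
    expect_equal(v[["aa"]], h * v[["ap"]], tolerance = 1e-10)
  }
})

test_that("linearity in amount and catchment; FIXED incentives are invariant", {
  set.seed(5)
  rates <- rate_set(c(act = 0.4, beh = 0.7, recordkeeping = 0.75))
  pop_inc <- incentive("x", "x", "PNC", 120, "NEWBORN",
                       action_keys = "act", behavior_keys = "beh")
  base <- project_incentive(pop_inc, "aa", rates, demo_fix, catchment(1000))
  for (k in stats::runif(10, 0.2, 4)) {
    expect_equal(project_incentive(pop_inc, "aa", rates, demo_fix,
                                   catchment(1000 * k)),
                 k * base, tolerance = 1e-10)
  }
  amt2 <- incentive("x", "x", "PNC", 240, "NEWBORN",
                    action_keys = "act", behavior_keys = "beh")
  expect_equal(project_incentive(amt2, "aa", rates, demo_fix), 2 * base)
  rk <- recordkeeping_incentive()
  sweep <- catchment_sweep(incentive_catalog(list(rk)), "aa", rates, demo_fix,
                           populations = c(250, 1000, 4000))
  expect_true(all(sweep$total == sweep$total[1]))
})

test_that("currency conversion matches the published INR/USD pairs", {
  expect_identical(convert_currency(2580, 71.7), 36)
  expect_identical(convert_currency(5867, 75.2), 78)
  expect_identical(convert_currency(0, 70), 0)
  expect_error(convert_currency(100, 0), class = "chwearn_contract_error")
})

test_that("rate sets validate and round-trip with provenance", {
  expect_error(rate_set(c(a = 1.2)), class = "chwearn_validation_error")
  expect_error(rate_set(c(0.5)), class = "chwearn_validation_error")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_set(rates_fix, path)
  back <- load_rate_set(path)
  expect_equal(as.numeric(back), as.numeric(rates_fix))
  expect_identical(attr(back, "provenance"), attr(rates_fix, "provenance"))
})
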