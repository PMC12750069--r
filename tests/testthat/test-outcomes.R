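test_that("trapezoid QALYs match closed forms", {
  # constant utility 1.0 over 8 weeks: 56 days / 365.25
  expect_equal(qaly_trapezoid(c(0, 4, 8), c(1, 1, 1)), 56 / 365.25)
  # one declining interval: mean utility 0.9 over 28 days
  expect_equal(qaly_trapezoid(c(0, 4), c(1.0, 0.8)), 0.9 * 28 / 365.25)
  # convention is configurable
  expect_equal(qaly_trapezoid(c(0, 4, 8), c(1, 1, 1), days_per_year = 364),
               56 / 364)
})

test_that("trapezoid QALYs are additive and linear", {
  set.seed(21)
  for (i in 1:50) {
    u <- runif(3, 0.6, 1.07)
    whole <- qaly_trapezoid(c(0, 4, 8), u)
    split <- qaly_trapezoid(c(0, 4), u[1:2]) + qaly_trapezoid(c(4, 8), u[2:3])
    expect_equal(whole, split, tolerance = 1e-12)
    c_scale <- runif(1, 0.1, 3)
    expect_equal(qaly_trapezoid(c(0, 4, 8), c_scale * u), c_scale * whole,
                 tolerance = 1e-12)
  }
})

test_that("trapezoid preconditions are enforced", {
  expect_error(qaly_trapezoid(0, 1), "at least 2")
  expect_error(qaly_trapezoid(c(0, 4, 4), c(1, 1, 1)), "strictly increasing")
  expect_error(qaly_trapezoid(c(4, 0), c(1, 1)), "strictly increasing")
  expect_error(qaly_trapezoid(c(0, 4), c(1, NA)), "missing")
})

test_that("LOCF fills forward and only forward", {
  s <- data.frame(week = c(0, 4, 8), utility = c(0.90, 0.85, NA))
  out <- locf_impute_utilities(s)
  expect_equal(out$utility, c(0.90, 0.85, 0.85))
  # repeated carry from baseline
  s2 <- data.frame(week = c(0, 4, 8), utility = c(0.90, NA, NA))
  expect_equal(locf_impute_utilities(s2)$utility, rep(0.90, 3))
  # fully observed series unchanged; idempotent
  s3 <- data.frame(week = c(0, 4, 8), utility = c(0.9, 0.8, 0.7))
  expect_equal(locf_impute_utilities(s3), s3)
  expect_equal(locf_impute_utilities(out), out)
  # missing baseline is an error naming the patient
  s4 <- data.frame(week = c(0, 4), utility = c(NA, 0.8))
  expect_error(locf_impute_utilities(s4, patient_id = "P42"), "P42")
})

test_that("center-mean imputation uses the same center, then the others", {
  patients <- data.frame(patient_id = c("A", "B", "C", "D", "E"),
                         center = c(1, 1, 1, 2, 3))
  costs <- data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    category = "MEDICAL",
    amount = c(100, 200, NA, 400, 150),
    currency = "USD"
  )
  out <- impute_costs_center_mean(costs, patients)
  expect_equal(out$amount[3], 150)             # mean of center 1's {100, 200}
  expect_true(out$imputed[3])
  expect_identical(out$imputed[-3], rep(FALSE, 4))

  # whole center missing the category: pooled mean over the other centers
  costs2 <- data.frame(
    patient_id = c("A", "B", "D", "E"),
    category = "PHARMACEUTICAL",
    amount = c(100, 300, NA, NA),   # centers 2 and 3 unobserved
    currency = "USD"
  )
  out2 <- impute_costs_center_mean(costs2, patients)
  expect_equal(out2$amount[3:4], c(200, 200))

  # no missing rows: identity (plus the imputed flag)
  costs3 <- costs
  costs3$amount[3] <- 50
  out3 <- impute_costs_center_mean(costs3, patients)
  expect_equal(out3$amount, costs3$amount)

  # a category observed nowhere cannot be imputed
  costs4 <- data.frame(patient_id = c("A", "B"), category = "TRANSPORT",
                       amount = c(NA, NA), currency = "USD")
  expect_error(impute_costs_center_mean(costs4, patients), "TRANSPORT")
})

test_that("total cost respects perspective and currency", {
  ledger <- data.frame(category = c("MEDICAL", "PHARMACEUTICAL"),
                       amount = c(196.44, 193.96), currency = "USD")
  expect_equal(total_cost(ledger), 390.40)
  # the trial-year exchange rate
  krw <- data.frame(category = "MEDICAL", amount = 128800, currency = "KRW")
  expect_equal(total_cost(krw, fx_rate = 1288), 100)
  # caregiving is excluded from the healthcare-system perspective
  mixed <- rbind(ledger,
                 data.frame(category = "CAREGIVING", amount = 50, currency = "USD"))
  expect_equal(total_cost(mixed, "HEALTHCARE_SYSTEM"), 390.40)
  expect_equal(total_cost(mixed, "LIMITED_SOCIETAL"), 440.40)
  expect_error(total_cost(data.frame(category = "LODGING", amount = 1,
                                     currency = "USD")), "unknown")
})

test_that("IQR rule flags the right values", {
  f <- iqr_outlier_filter(c(10, 12, 11, 13, 100))
  expect_identical(f$excluded, 5L)
  expect_equal(f$lower, 11 - 1.5 * 2)
  expect_equal(f$upper, 13 + 1.5 * 2)
  # equal values: bounds collapse, nothing excluded
  expect_length(iqr_outlier_filter(rep(7, 6))$excluded, 0)
  # enormous multiplier excludes nothing
  expect_length(iqr_outlier_filter(c(1, 2, 3, 1000), k = 1e9)$excluded, 0)
  expect_error(iqr_outlier_filter(c(1, 2, 3)), "at least 4")
})

test_that("per-patient outcomes integrate mapping, LOCF and cost totals", {
  tr <- toy_trial()
  out <- compute_outcomes(tr)
  expect_identical(nrow(out), 3L)
  # all-zero CAT items: utility 1.0661 at every visit
  expect_equal(out$qaly_0_8, rep(1.0661 * 56 / 365.25, 3))
  expect_equal(out$qaly_0_4 + out$qaly_4_8, out$qaly_0_8, tolerance = 1e-12)
  expect_equal(out$cost_total_healthcare, c(150, 350, 200))
  expect_false(any(out$utility_imputed))

  # blank a follow-up CAT block: LOCF carries week 4 forward
  tr2 <- drop_cat_block(tr, "A", week = 8)
  out2 <- compute_outcomes(tr2)
  expect_true(out2$utility_imputed[out2$patient_id == "A"])
  expect_equal(out2$qaly_0_8, out$qaly_0_8)   # carried value equals the constant
})

test_that("societal totals always contain the healthcare totals", {
  cfg <- trial_config(n_dtx = 30, n_control = 30, dropout_to_pps = c(25, 26),
                      seed = 5)
  out <- compute_outcomes(inject_missingness(generate_trial(cfg)))
  expect_true(all(out$cost_total_societal >= out$cost_total_healthcare))
})
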