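test_that("the PSA is reproducible from its seed", {
  cfg <- psa_config(n_iter = 200, seed = 123)
  p1 <- run_psa(ref_dtx(), ref_control(), cfg)
  p2 <- run_psa(ref_dtx(), ref_control(), cfg)
  expect_identical(p1$iterates, p2$iterates)
  p3 <- run_psa(ref_dtx(), ref_control(), psa_config(n_iter = 200, seed = 124))
  expect_false(identical(p1$iterates, p3$iterates))
})

test_that("zero dispersion collapses the PSA onto the point estimate", {
  a <- arm_summary("DTX", 43, 390.40, 0, 0.1568, 0)
  b <- arm_summary("CONTROL", 41, 305.06, 0, 0.1473, 0)
  psa <- run_psa(a, b, psa_config(n_iter = 50, seed = 1))
  expect_equal(unique(psa$iterates$delta_cost), 85.34)
  expect_equal(unique(psa$iterates$delta_qaly), 0.0095)
  qs <- quadrant_summary(psa)
  expect_equal(unname(qs$shares["NE"]), 1)
  expect_equal(qs$p_cost_effective, 1)
  # CEAC is a step function at the base-case ratio
  base_icur <- 85.34 / 0.0095
  cc <- ceac(psa, c(0, floor(base_icur), ceiling(base_icur), 40000))
  expect_equal(cc$p_dtx, c(0, 0, 1, 1))
})

test_that("quadrant shares are exact counts that sum to one", {
  psa <- run_psa(ref_dtx(), ref_control(), psa_config(n_iter = 500, seed = 7))
  qs <- quadrant_summary(psa)
  expect_identical(sum(qs$counts), 500L)
  expect_equal(sum(qs$shares), 1)
  # conditional x NE share equals the overall NE-below-WTP share
  expect_equal(qs$ne_below_wtp_conditional * qs$shares[["NE"]],
               qs$ne_below_wtp_overall)
  # complementarity of the two CEAC curves
  cc <- ceac(psa, c(0, 19410, 40000))
  expect_equal(cc$p_dtx + cc$p_control, rep(1, 3))
})

test_that("gamma sampling recovers the targeted cost moments", {
  psa <- run_psa(ref_dtx(), ref_control(),
                 psa_config(n_iter = 2e5, seed = 77))
  it <- psa$iterates
  expect_equal(mean(it$cost_a), 390.40, tolerance = 0.005)
  expect_equal(sd(it$cost_a), 193.09 / sqrt(43), tolerance = 0.02)
  expect_equal(mean(it$cost_b), 305.06, tolerance = 0.005)
  expect_equal(sd(it$cost_b), 220.18 / sqrt(41), tolerance = 0.02)
  expect_true(all(it$cost_a > 0 & it$cost_b > 0))
  # dispersion switch: SD mode widens the cost draws by sqrt(n)
  psa_sd <- run_psa(ref_dtx(), ref_control(),
                    psa_config(n_iter = 2e5, seed = 77, cost_dispersion = "SD"))
  expect_equal(sd(psa_sd$iterates$cost_a), 193.09, tolerance = 0.02)
})

test_that("the cost-effectiveness probability matches a closed-form oracle", {
  # under a normal approximation, P(NMB > 0) = pnorm(E[NMB] / SD[NMB]);
  # the gamma cost shapes here are ~176 and ~79 so the approximation is tight
  psa <- run_psa(ref_dtx(), ref_control(),
                 psa_config(n_iter = 1e5, seed = 99))
  wtp <- 19410
  e_nmb <- wtp * (0.1568 - 0.1473) - (390.40 - 305.06)
  sd_nmb <- sqrt(wtp^2 * (0.016^2 + 0.013^2) +
                   193.09^2 / 43 + 220.18^2 / 41)
  p_mc <- mean(wtp * psa$iterates$delta_qaly - psa$iterates$delta_cost > 0)
  expect_equal(p_mc, pnorm(e_nmb / sd_nmb), tolerance = 0.01)
})

test_that("the CEAC is monotone when every draw gains QALYs", {
  a <- arm_summary("DTX", 43, 390.40, 193.09, 0.1568, 1e-6)
  b <- arm_summary("CONTROL", 41, 305.06, 220.18, 0.1473, 1e-6)
  psa <- run_psa(a, b, psa_config(n_iter = 2000, seed = 3))
  expect_true(all(psa$iterates$delta_qaly > 0))
  cc <- ceac(psa, seq(0, 40000, by = 1000))
  expect_false(is.unsorted(cc$p_dtx))
})

test_that("one-way DSA entries match brute-force recomputation", {
  a <- ref_dtx(); b <- ref_control()
  tor <- one_way_dsa(a, b)
  expect_identical(nrow(tor), 4L)
  expect_false(is.unsorted(rev(tor$width)))
  base <- list(cost_a = 390.40, cost_b = 305.06, qaly_a = 0.1568, qaly_b = 0.1473)
  icur_at <- function(p) (p$cost_a - p$cost_b) / (p$qaly_a - p$qaly_b)
  halfwidth <- list(cost_a = 1.96 * 193.09 / sqrt(43),
                    cost_b = 1.96 * 220.18 / sqrt(41),
                    qaly_a = 1.96 * 0.016 / sqrt(43),
                    qaly_b = 1.96 * 0.013 / sqrt(41))
  for (par in names(halfwidth)) {
    row <- tor[tor$parameter == par, ]
    lo <- base; lo[[par]] <- base[[par]] - halfwidth[[par]]
    hi <- base; hi[[par]] <- base[[par]] + halfwidth[[par]]
    expect_equal(row$icur_low, icur_at(lo))
    expect_equal(row$icur_high, icur_at(hi))
    expect_equal(row$width, abs(icur_at(hi) - icur_at(lo)))
  }
  # the widest bar is the parameter with the largest recomputed excursion
  widths <- vapply(names(halfwidth), function(par) {
    lo <- base; lo[[par]] <- base[[par]] - halfwidth[[par]]
    hi <- base; hi[[par]] <- base[[par]] + halfwidth[[par]]
    abs(icur_at(hi) - icur_at(lo))
  }, numeric(1))
  expect_identical(tor$parameter[1], names(which.max(widths)))
})

test_that("DSA perturbing a cost mean shifts the ICUR affinely", {
  a <- ref_dtx(); b <- ref_control()
  x <- 25
  tor <- one_way_dsa(a, b, ranges = list(cost_b = c(305.06 - x, 305.06 + x)))
  row <- tor[tor$parameter == "cost_b", ]
  dq <- 0.1568 - 0.1473
  base_icur <- (390.40 - 305.06) / dq
  expect_equal(row$icur_low, base_icur + x / dq)   # cheaper comparator -> higher ICUR
  expect_equal(row$icur_high, base_icur - x / dq)
  # degenerate range collapses to a zero-width bar
  tor0 <- one_way_dsa(a, b, ranges = list(cost_b = c(305.06, 305.06)))
  expect_equal(tor0[tor0$parameter == "cost_b", "width"], 0)
  expect_error(one_way_dsa(a, b, ranges = list(cost_b = c(400, 300))),
               "low > high")
  expect_error(one_way_dsa(a, b, ranges = list(cost_b = c(400, 500))),
               "bracket")
})

test_that("alternative-mapping scenarios enter the tornado as one entry", {
  tor <- one_way_dsa(ref_dtx(), ref_control(),
                     scenarios = list(alt1 = list(qaly_a = 0.160, qaly_b = 0.150),
                                      alt2 = list(qaly_a = 0.150, qaly_b = 0.145)))
  row <- tor[tor$parameter == "mapping_algorithm", ]
  expect_equal(row$icur_low, min(85.34 / 0.010, 85.34 / 0.005))
  expect_equal(row$icur_high, max(85.34 / 0.010, 85.34 / 0.005))
})
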