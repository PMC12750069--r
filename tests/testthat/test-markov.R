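test_that("mMRC grades map onto the default and custom state cuts", {
  expect_identical(mmrc_to_state(0), "NORMAL")
  expect_identical(mmrc_to_state(4), "SEVERE")
  expect_identical(mmrc_to_state(c(1, 2, 3, NA)),
                   c("MILD", "MODERATE", "SEVERE", NA))
  custom <- c("NORMAL", "NORMAL", "MILD", "MODERATE", "SEVERE")
  expect_identical(mmrc_to_state(1, custom), "NORMAL")
  expect_error(mmrc_to_state(5), "0..4")
  expect_error(mmrc_to_state(0, mapping = c("NORMAL", "DEATH", "MILD",
                                            "MODERATE", "SEVERE")), "living")
})

test_that("transition estimation equals a pair-counting oracle", {
  # from MILD: 2 stay, 1 improves to NORMAL
  v <- data.frame(patient_id = rep(c("a", "b", "c"), each = 2),
                  week = rep(c(0, 4), 3),
                  mmrc = c(1, 1, 1, 1, 1, 0))
  m <- estimate_transitions(v)
  expect_equal(unname(m["MILD", ]), c(1 / 3, 2 / 3, 0, 0, 0))
  expect_equal(rowSums(m), setNames(rep(1, 5), markov_states()))
  # never-observed origins keep their state and are flagged
  expect_true("SEVERE" %in% attr(m, "flagged_rows"))
  expect_equal(unname(m["SEVERE", ]), c(0, 0, 0, 1, 0))
  expect_equal(unname(m["DEATH", "DEATH"]), 1)

  # a static cohort yields the identity matrix
  v2 <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                   week = rep(c(0, 4, 8), 2),
                   mmrc = c(0, 0, 0, 3, 3, 3))
  expect_equal(unname(estimate_transitions(v2)), diag(5),
               ignore_attr = TRUE)

  # week 0->4 and 4->8 pairs are pooled; an 8-week gap is not a pair
  v3 <- data.frame(patient_id = "a", week = c(0, 8), mmrc = c(1, 1))
  expect_error(estimate_transitions(v3), "no observed")
})

test_that("random trial transitions are row-stochastic with DEATH absorbing", {
  cfg <- trial_config(n_dtx = 40, n_control = 40, dropout_to_pps = c(35, 35),
                      seed = 17)
  tr <- inject_missingness(generate_trial(cfg))
  for (arm in c("DTX", "CONTROL")) {
    ids <- tr$patients$patient_id[tr$patients$arm == arm]
    m <- estimate_transitions(tr$visits[tr$visits$patient_id %in% ids, ])
    expect_equal(rowSums(m), setNames(rep(1, 5), markov_states()),
                 tolerance = 1e-9)
    expect_equal(unname(m["DEATH", "DEATH"]), 1)
    expect_true(all(m >= 0))
  }
})

static_spec <- function(u = 0.9, cost = 100, n_cycles = 13) {
  markov_spec(diag(5), c(cost, 0, 0, 0, 0), c(u, 0, 0, 0, 0),
              c(1, 0, 0, 0, 0), n_cycles = n_cycles)
}

test_that("cohort traces match closed forms", {
  tr <- run_cohort(static_spec())
  expect_equal(tr$total_qaly, 0.9 * 13 * 28 / 365.25)
  expect_equal(tr$total_cost, 100 * 13)
  expect_equal(rowSums(tr$occupancy), setNames(rep(1, 14), 0:13))

  # everyone dies in the first cycle: rewards accrue for cycle 1 only
  die <- matrix(0, 5, 5); die[, 5] <- 1; die[5, ] <- c(0, 0, 0, 0, 1)
  sp <- markov_spec(die, c(100, 0, 0, 0, 0), c(0.9, 0, 0, 0, 0),
                    c(1, 0, 0, 0, 0), n_cycles = 13)
  tr2 <- run_cohort(sp)
  expect_equal(tr2$total_cost, 100)
  expect_equal(tr2$total_qaly, 0.9 * 28 / 365.25)
  expect_false(is.unsorted(tr2$occupancy[, "DEATH"]))

  # without mortality, doubling the horizon doubles the QALY
  expect_equal(run_cohort(static_spec(n_cycles = 26))$total_qaly,
               2 * run_cohort(static_spec(n_cycles = 13))$total_qaly)
})

test_that("a two-state chain matches exhaustive path enumeration", {
  p_adv <- 0.1
  m <- diag(5)
  m[1, 1] <- 1 - p_adv; m[1, 2] <- p_adv
  costs <- c(50, 200, 0, 0, 0)
  utils_ <- c(0.95, 0.70, 0, 0, 0)
  sp <- markov_spec(m, costs, utils_, c(1, 0, 0, 0, 0), n_cycles = 3)
  tr <- run_cohort(sp)

  # enumerate all 2^3 paths over {NORMAL, MILD}
  paths <- expand.grid(s1 = 1:2, s2 = 1:2, s3 = 1:2)
  total_cost <- 0; total_qaly <- 0
  for (k in seq_len(nrow(paths))) {
    st <- c(1, as.integer(paths[k, ]))
    pr <- prod(vapply(1:3, function(t) m[st[t], st[t + 1]], numeric(1)))
    if (pr == 0) next
    # rewards accrue on the state occupied at the start of each cycle
    total_cost <- total_cost + pr * sum(costs[st[1:3]])
    total_qaly <- total_qaly + pr * sum(utils_[st[1:3]]) * 28 / 365.25
  }
  expect_equal(tr$total_cost, total_cost, tolerance = 1e-12)
  expect_equal(tr$total_qaly, total_qaly, tolerance = 1e-12)
})

test_that("half-cycle correction averages adjacent occupancies", {
  p_adv <- 0.2
  m <- diag(5); m[1, 1] <- 0.8; m[1, 2] <- 0.2
  sp <- markov_spec(m, c(100, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
                    c(1, 0, 0, 0, 0), n_cycles = 2, half_cycle = TRUE)
  tr <- run_cohort(sp)
  # occupancies of NORMAL: 1, 0.8, 0.64 -> accruals 0.9 and 0.72
  expect_equal(tr$cycle_costs, c(90, 72))
})

test_that("invalid Markov specifications are rejected", {
  bad_rows <- diag(5); bad_rows[1, 1] <- 0.5
  expect_error(markov_spec(bad_rows, rep(0, 5), rep(0, 5), c(1, 0, 0, 0, 0)),
               "sum to 1")
  leaky_death <- diag(5); leaky_death[5, 5] <- 0.9; leaky_death[5, 1] <- 0.1
  expect_error(markov_spec(leaky_death, rep(0, 5), rep(0, 5), c(1, 0, 0, 0, 0)),
               "absorbing")
  expect_error(markov_spec(diag(5), c(0, 0, 0, 0, 5), rep(0, 5),
                           c(1, 0, 0, 0, 0)), "DEATH")
  expect_error(markov_spec(diag(5), rep(0, 5), rep(0, 5), c(0.5, 0, 0, 0, 0)),
               "initial")
})

test_that("two-arm Markov analysis composes with the incremental core", {
  sp <- static_spec()
  same <- markov_cua(sp, sp)
  expect_equal(same$incremental$delta_cost, 0)
  expect_equal(same$incremental$delta_qaly, 0)
  expect_identical(same$incremental$status, "UNDEFINED")

  # DTx-favouring toy chain over 2 cycles, hand-computed ratio
  m_a <- diag(5); m_a[2, 2] <- 0.5; m_a[2, 1] <- 0.5   # MILD improves
  costs <- c(100, 150, 0, 0, 0)
  utils_ <- c(1.0, 0.8, 0, 0, 0)
  sp_a <- markov_spec(m_a, costs, utils_, c(0, 1, 0, 0, 0), n_cycles = 2)
  sp_b <- markov_spec(diag(5), costs, utils_, c(0, 1, 0, 0, 0), n_cycles = 2)
  out <- markov_cua(sp_a, sp_b)
  # arm A: cycle 1 from MILD (150, 0.8), cycle 2 half MILD half NORMAL
  dcost <- (150 + 125) - 300
  dqaly <- ((0.8 + 0.9) - 1.6) * 28 / 365.25
  expect_equal(out$incremental$delta_cost, dcost)
  expect_equal(out$incremental$delta_qaly, dqaly)
  expect_equal(out$incremental$icur, dcost / dqaly)
  # cheaper and more effective: dominant, southeast quadrant
  expect_identical(out$incremental$quadrant, "SE")
  expect_identical(out$incremental$status, "DOMINANT")
  expect_error(markov_cua(sp_a, static_spec(n_cycles = 5)), "cycle structure")
})

test_that("the trial-driven 1-year extrapolation stays below the threshold", {
  cfg <- trial_config(seed = 42)
  tr <- inject_missingness(generate_trial(cfg))
  out <- markov_from_trial(tr, wtp = 19410)
  expect_identical(out$incremental$quadrant, "NE")
  expect_lt(out$incremental$icur, 19410)
  # occupancy conservation and absorbing death in both arms
  for (trace in list(out$trace_a, out$trace_b)) {
    expect_equal(unname(rowSums(trace$occupancy)), rep(1, 14),
                 tolerance = 1e-12)
    expect_false(is.unsorted(trace$occupancy[, "DEATH"]))
  }
})
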