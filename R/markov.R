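#' Markov health states
#'
#' The 1-year extrapolation uses five health states defined on the mMRC
#' dyspnea scale — NORMAL, MILD, MODERATE, SEVERE — plus an absorbing
#' DEATH state with zero cost and utility.
#'
#' @return Character vector of the five state names, in model order.
#' @export
markov_states <- function() {
  c("NORMAL", "MILD", "MODERATE", "SEVERE", "DEATH")
}

#' Map mMRC scores to Markov health states
#'
#' Default cut points: 0 = NORMAL, 1 = MILD, 2 = MODERATE, 3--4 = SEVERE.
#' mMRC is a 0--4 scale and the model needs four living states, so the two
#' most breathless grades share SEVERE; the mapping is configurable.
#'
#' @param mmrc Integer vector of mMRC scores in 0--4 (`NA` passes through).
#' @param mapping Character vector of length 5 assigning a living state to
#'   each mMRC grade 0..4.
#' @return Character vector of state names.
#' @export
mmrc_to_state <- function(mmrc,
                          mapping = c("NORMAL", "MILD", "MODERATE",
                                      "SEVERE", "SEVERE")) {
  if (length(mapping) != 5L || !all(mapping %in% markov_states()[1:4])) {
    stop("mapping must assign one living state to each mMRC grade 0..4",
         call. = FALSE)
  }
  ok <- is.na(mmrc) | (mmrc %in% 0:4)
  if (!all(ok)) stop("mMRC scores must lie in 0..4", call. = FALSE)
  out <- rep(NA_character_, length(mmrc))
  obs <- !is.na(mmrc)
  out[obs] <- mapping[mmrc[obs] + 1L]
  out
}

#' Estimate 4-week transition probabilities from trial visits
#'
#' Pools every observed 4-week state pair (week 0 to 4 and week 4 to 8)
#' across the supplied patients and estimates each row of the transition
#' matrix as the empirical fraction of destinations.  States never observed
#' as an origin get a stay probability of 1 (and are flagged); the DEATH
#' row is forced absorbing.
#'
#' @param visits Visits data frame (`patient_id`, `week`, `mmrc`) for the
#'   patients of one arm.
#' @param mapping mMRC-to-state mapping, see [mmrc_to_state()].
#' @return 5x5 row-stochastic matrix with state dimnames; attribute
#'   `flagged_rows` lists states with no observed origin, and `n_pairs`
#'   the number of pooled transitions.
#' @export
estimate_transitions <- function(visits,
                                 mapping = c("NORMAL", "MILD", "MODERATE",
                                             "SEVERE", "SEVERE")) {
  stopifnot(all(c("patient_id", "week", "mmrc") %in% names(visits)))
  states <- markov_states()
  counts <- matrix(0L, 5, 5, dimnames = list(states, states))
  visits <- visits[order(visits$patient_id, visits$week), , drop = FALSE]
  for (pid in unique(visits$patient_id)) {
    pv <- visits[visits$patient_id == pid, , drop = FALSE]
    st <- mmrc_to_state(pv$mmrc, mapping)
    for (i in seq_len(nrow(pv) - 1L)) {
      if (pv$week[i + 1L] - pv$week[i] == 4 &&
          !is.na(st[i]) && !is.na(st[i + 1L])) {
        counts[st[i], st[i + 1L]] <- counts[st[i], st[i + 1L]] + 1L
      }
    }
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0L) {
    stop("no observed 4-week transition pairs", call. = FALSE)
  }
  m <- matrix(0, 5, 5, dimnames = list(states, states))
  flagged <- character()
  for (s in states) {
    tot <- sum(counts[s, ])
    if (s == "DEATH" || tot == 0L) {
      m[s, s] <- 1
      if (s != "DEATH") flagged <- c(flagged, s)
    } else {
      m[s, ] <- counts[s, ] / tot
    }
  }
  structure(m, flagged_rows = flagged, n_pairs = n_pairs)
}

#' Specify a Markov cohort model
#'
#' @param transitions 5x5 row-stochastic transition matrix in
#'   [markov_states()] order, with DEATH absorbing.
#' @param state_costs Per-state cost accrued per 4-week cycle (USD);
#'   DEATH must be 0.
#' @param state_utilities Per-state utility weight; DEATH must be 0.
#' @param initial Initial state-occupancy distribution (sums to 1).
#' @param n_cycles Number of cycles; the default 13 cycles of 28 days
#'   approximate a 1-year horizon (364 days).
#' @param cycle_days Cycle length in days (default 28).
#' @param half_cycle Apply the half-cycle correction (average adjacent
#'   occupancies when accruing cost and QALYs); default off.
#' @return A `markov_spec`.
#' @export
markov_spec <- function(transitions, state_costs, state_utilities, initial,
                        n_cycles = 13, cycle_days = 28, half_cycle = FALSE) {
  states <- markov_states()
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(5, 5))) {
    stop("transition matrix must be 5x5 in state order ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  dimnames(transitions) <- list(states, states)
  if (any(transitions < 0) || any(abs(rowSums(transitions) - 1) > 1e-9)) {
    stop("transition rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(transitions["DEATH", "DEATH"] - 1) > 1e-9) {
    stop("DEATH must be absorbing", call. = FALSE)
  }
  for (v in list(state_costs = state_costs, state_utilities = state_utilities,
                 initial = initial)) {
    if (length(v) != 5L) stop("per-state vectors must have length 5", call. = FALSE)
  }
  state_costs <- stats::setNames(as.numeric(state_costs), states)
  state_utilities <- stats::setNames(as.numeric(state_utilities), states)
  initial <- stats::setNames(as.numeric(initial), states)
  if (state_costs["DEATH"] != 0 || state_utilities["DEATH"] != 0) {
    stop("DEATH carries zero cost and utility", call. = FALSE)
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("initial distribution must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot_scalar_number(n_cycles, "n_cycles", lower = 1)
  stopifnot_scalar_number(cycle_days, "cycle_days", lower = 1)
  structure(
    list(transitions = transitions, state_costs = state_costs,
         state_utilities = state_utilities, initial = initial,
         n_cycles = as.integer(n_cycles), cycle_days = cycle_days,
         half_cycle = isTRUE(half_cycle)),
    class = "markov_spec"
  )
}

#' Propagate a cohort through a Markov model
#'
#' Starting from the initial distribution, the occupancy vector is
#' multiplied by the transition matrix once per cycle.  Cycle `t`
#' (t = 1..n) accrues cost `occ_{t-1} . state_costs` and QALYs
#' `occ_{t-1} . state_utilities * cycle_days / days_per_year` — i.e.
#' state membership at the start of a cycle earns that cycle's reward;
#' with the half-cycle correction the average of the start and end
#' occupancies is used instead.
#'
#' @param spec A [markov_spec()].
#' @param days_per_year Annualization denominator for QALYs.
#' @return A `cohort_trace`: `occupancy` matrix ((n_cycles + 1) x 5, rows
#'   are cycles 0..n), `cycle_costs`, `cycle_qalys`, `total_cost`,
#'   `total_qaly`.
#' @export
run_cohort <- function(spec, days_per_year = 365.25) {
  stopifnot(inherits(spec, "markov_spec"))
  stopifnot_scalar_number(days_per_year, "days_per_year", lower = 1e-9)
  n <- spec$n_cycles
  occ <- matrix(NA_real_, n + 1L, 5L,
                dimnames = list(0:n, markov_states()))
  occ[1L, ] <- spec$initial
  for (t in seq_len(n)) {
    occ[t + 1L, ] <- occ[t, ] %*% spec$transitions
  }
  accrual <- if (spec$half_cycle) {
    (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(n), , drop = FALSE]
  }
  cycle_costs <- as.vector(accrual %*% spec$state_costs)
  cycle_qalys <- as.vector(accrual %*% spec$state_utilities) *
    spec$cycle_days / days_per_year
  structure(
    list(occupancy = occ, cycle_costs = cycle_costs,
         cycle_qalys = cycle_qalys,
         total_cost = sum(cycle_costs), total_qaly = sum(cycle_qalys)),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- length(x$cycle_costs)
  cat(sprintf("Markov cohort trace: %d cycles, total cost %.2f USD, total QALY %.4f\n",
              n, x$total_cost, x$total_qaly))
  invisible(x)
}

#' Incremental cost-utility analysis of two Markov arms
#'
#' Runs the cohort model for the intervention and comparator
#' specifications and feeds the cumulative costs and QALYs into
#' [incremental_analysis()].
#'
#' @param spec_a,spec_b [markov_spec()] objects sharing cycle structure.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param days_per_year Annualization denominator.
#' @return List with the two `cohort_trace`s (`trace_a`, `trace_b`) and the
#'   `incremental` result.
#' @export
markov_cua <- function(spec_a, spec_b, wtp = 19410, days_per_year = 365.25) {
  if (spec_a$n_cycles != spec_b$n_cycles ||
      spec_a$cycle_days != spec_b$cycle_days) {
    stop("arm specifications must share the cycle structure", call. = FALSE)
  }
  ta <- run_cohort(spec_a, days_per_year)
  tb <- run_cohort(spec_b, days_per_year)
  inc <- incremental_analysis(
    list(cost_mean = ta$total_cost, qaly_mean = ta$total_qaly),
    list(cost_mean = tb$total_cost, qaly_mean = tb$total_qaly),
    wtp = wtp
  )
  list(trace_a = ta, trace_b = tb, incremental = inc)
}

#' Derive state costs, utilities and initial distributions from a trial
#'
#' State utilities are the mean mapped utility over all patient-visits in
#' each state; state 4-week costs are the mean per-interval healthcare cost
#' (a patient's 8-week total divided by the two intervals) over the visits
#' opening an interval in that state; the initial distribution is the
#' week-0 state mix.  States never observed fall back to the overall mean
#' (flagged).  DEATH gets zero cost and utility.
#'
#' @param trial A `dtx_trial`.
#' @param arm Arm label to derive values for.
#' @param algorithm CAT-to-utility mapping.
#' @param mapping mMRC-to-state mapping.
#' @param fx_rate Korean won per USD.
#' @return List with `state_costs`, `state_utilities`, `initial`,
#'   `flagged` (states with no observations).
#' @export
derive_state_values <- function(trial, arm, algorithm = cat_eq5d_model3(),
                                mapping = c("NORMAL", "MILD", "MODERATE",
                                            "SEVERE", "SEVERE"),
                                fx_rate = 1288) {
  stopifnot(inherits(trial, "dtx_trial"))
  states <- markov_states()
  pats <- trial$patients[trial$patients$arm == arm, , drop = FALSE]
  v <- trial$visits[trial$visits$patient_id %in% pats$patient_id, , drop = FALSE]
  v$state <- mmrc_to_state(v$mmrc, mapping)
  v$utility <- map_cat_frame(v, algorithm)

  costs <- impute_costs_center_mean(trial$costs, trial$patients)
  cur <- if ("currency" %in% names(costs)) costs$currency else rep("USD", nrow(costs))
  costs$amount_usd <- ifelse(cur == "KRW", costs$amount / fx_rate, costs$amount)
  hc <- costs[costs$category %in% perspective_categories("HEALTHCARE_SYSTEM"), ]
  tot <- tapply(hc$amount_usd, hc$patient_id, sum)
  v$interval_cost <- as.numeric(tot[as.character(v$patient_id)]) / 2

  obs_u <- !is.na(v$state) & !is.na(v$utility)
  obs_c <- !is.na(v$state) & v$week < 8 & !is.na(v$interval_cost)
  su <- stats::setNames(numeric(5), states)
  sc <- stats::setNames(numeric(5), states)
  flagged <- character()
  for (s in states[1:4]) {
    iu <- obs_u & v$state == s
    ic <- obs_c & v$state == s
    if (!any(iu) || !any(ic)) flagged <- c(flagged, s)
    su[s] <- if (any(iu)) mean(v$utility[iu]) else mean(v$utility[obs_u])
    sc[s] <- if (any(ic)) mean(v$interval_cost[ic]) else mean(v$interval_cost[obs_c])
  }
  w0 <- v[v$week == 0 & !is.na(v$state), , drop = FALSE]
  init <- stats::setNames(numeric(5), states)
  tab <- table(factor(w0$state, levels = states))
  init[] <- as.numeric(tab) / sum(tab)
  list(state_costs = sc, state_utilities = su, initial = init,
       flagged = flagged)
}

#' One-year Markov extrapolation straight from a trial
#'
#' Convenience wrapper: estimates per-arm transition matrices from the
#' observed mMRC trajectories, derives state costs/utilities and initial
#' distributions from the patient-level data, and runs the two-arm Markov
#' cost-utility analysis.
#'
#' @param trial A `dtx_trial`.
#' @param wtp Willingness-to-pay threshold.
#' @param n_cycles Number of 4-week cycles (default 13, about 1 year).
#' @param algorithm CAT-to-utility mapping.
#' @param half_cycle Half-cycle correction flag.
#' @param days_per_year Annualization denominator.
#' @return As [markov_cua()], plus the two `markov_spec`s.
#' @export
markov_from_trial <- function(trial, wtp = 19410, n_cycles = 13,
                              algorithm = cat_eq5d_model3(),
                              half_cycle = FALSE, days_per_year = 365.25) {
  build <- function(arm) {
    pats <- trial$patients[trial$patients$arm == arm, , drop = FALSE]
    v <- trial$visits[trial$visits$patient_id %in% pats$patient_id, , drop = FALSE]
    tm <- estimate_transitions(v)
    sv <- derive_state_values(trial, arm, algorithm)
    markov_spec(tm, sv$state_costs, sv$state_utilities, sv$initial,
                n_cycles = n_cycles, half_cycle = half_cycle)
  }
  spec_a <- build("DTX")
  spec_b <- build("CONTROL")
  out <- markov_cua(spec_a, spec_b, wtp = wtp, days_per_year = days_per_year)
  out$spec_a <- spec_a
  out$spec_b <- spec_b
  out
}
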