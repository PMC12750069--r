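#' Build a tridiagonal mMRC transition matrix
#'
#' Four-week transition probabilities on the mMRC grades 0..4: from each
#' grade the score improves by one with probability `p_improve`, worsens by
#' one with probability `p_worsen`, and otherwise stays; at the ends of the
#' scale the impossible move folds into staying.
#'
#' @param p_improve,p_worsen Per-cycle move probabilities
#'   (`p_improve + p_worsen <= 1`).
#' @return 5x5 row-stochastic matrix over grades 0..4.
#' @export
mmrc_transition_matrix <- function(p_improve, p_worsen) {
  stopifnot_scalar_number(p_improve, "p_improve", lower = 0, upper = 1)
  stopifnot_scalar_number(p_worsen, "p_worsen", lower = 0, upper = 1)
  if (p_improve + p_worsen > 1) {
    stop("p_improve + p_worsen must not exceed 1", call. = FALSE)
  }
  m <- matrix(0, 5, 5, dimnames = list(0:4, 0:4))
  for (g in 1:5) {
    up <- if (g > 1) p_improve else 0
    down <- if (g < 5) p_worsen else 0
    if (g > 1) m[g, g - 1L] <- up
    if (g < 5) m[g, g + 1L] <- down
    m[g, g] <- 1 - up - down
  }
  m
}

#' Configuration of the synthetic trial generator
#'
#' Defaults emulate the arm-level structure of the 8-week
#' pulmonary-rehabilitation trial the package analyses: 43 DTx and 41
#' control patients across 3 centers, total costs of 390.40 (SD 193.09) and
#' 305.06 (SD 220.18) USD, 8-week QALYs of 0.1568 (SD 0.016) and 0.1473
#' (SD 0.013), per-protocol completers 36 and 33, a diagnosis mix of about
#' 58% COPD / 30% ILD / 12% other, a DTx usage fee of 93.17 USD booked in
#' the DTx arm's ledger, and a mild-to-moderate baseline mMRC (mean about
#' 1.3) evolving under arm-specific 4-week transition matrices that favour
#' improvement in the DTx arm.
#'
#' @param n_dtx,n_control Arm sizes (>= 2).
#' @param n_centers Number of clinical centers.
#' @param cost_mean,cost_sd Target total-cost mean/SD per arm,
#'   `c(dtx, control)`, USD.
#' @param pharm_share Mean fraction of non-fee cost that is pharmaceutical.
#' @param qaly_mean,qaly_sd Target 8-week QALY mean/SD per arm.
#' @param dropout_to_pps Per-protocol completer counts per arm,
#'   `c(dtx, control)`.
#' @param diagnosis_mix Named fractions over COPD / ILD / OTHER (sum 1).
#' @param dtx_fee DTx usage fee for the 8-week period (USD), included as a
#'   medical-cost ledger line in the DTx arm.
#' @param age_mean,age_sd Baseline age moments per arm.
#' @param male_share Share of male patients per arm.
#' @param mmrc_baseline_probs Baseline mMRC distribution over grades 0..4.
#' @param mmrc_transition_dtx,mmrc_transition_control 5x5 4-week mMRC
#'   transition matrices (see [mmrc_transition_matrix()]).
#' @param p_missing_cost Probability that a patient's pharmaceutical cost
#'   is missing (to exercise center-mean imputation).
#' @param visit_sigma SD of the visit-level utility noise around the
#'   patient's mean utility.
#' @param n_visits_societal,caregiving_attendance,caregiving_hours,
#'   caregiving_wage,caregiving_employment,transport_fare Factors for the
#'   caregiving (`visits x attendance x hours x wage x employment`) and
#'   transport (`visits x fare x 2`) ledger lines of the limited societal
#'   perspective; identical across arms.
#' @param days_per_year Annualization denominator the QALY targets assume.
#' @param algorithm Mapping algorithm whose item structure the generated
#'   CAT responses are solved against.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `trial_config` list.
#' @export
trial_config <- function(n_dtx = 43, n_control = 41, n_centers = 3,
                         cost_mean = c(390.40, 305.06),
                         cost_sd = c(193.09, 220.18),
                         pharm_share = 0.66,
                         qaly_mean = c(0.1568, 0.1473),
                         qaly_sd = c(0.016, 0.013),
                         dropout_to_pps = c(36, 33),
                         diagnosis_mix = c(COPD = 0.58, ILD = 0.30, OTHER = 0.12),
                         dtx_fee = 93.17,
                         age_mean = c(63.4, 67.78), age_sd = c(10.36, 6.93),
                         male_share = c(0.79, 0.88),
                         mmrc_baseline_probs = c(0.12, 0.52, 0.31, 0.05, 0),
                         mmrc_transition_dtx = mmrc_transition_matrix(0.25, 0.05),
                         mmrc_transition_control = mmrc_transition_matrix(0.10, 0.10),
                         p_missing_cost = 0.05,
                         visit_sigma = 0.005,
                         n_visits_societal = 3,
                         caregiving_attendance = 0.5, caregiving_hours = 2,
                         caregiving_wage = 8, caregiving_employment = 0.65,
                         transport_fare = 2,
                         days_per_year = 365.25,
                         algorithm = cat_eq5d_model3(),
                         seed = 1L) {
  stopifnot_scalar_number(n_dtx, "n_dtx", lower = 2)
  stopifnot_scalar_number(n_control, "n_control", lower = 2)
  stopifnot_scalar_number(n_centers, "n_centers", lower = 1)
  stopifnot_scalar_number(pharm_share, "pharm_share", lower = 0, upper = 1)
  stopifnot_scalar_number(dtx_fee, "dtx_fee", lower = 0)
  stopifnot_scalar_number(p_missing_cost, "p_missing_cost", lower = 0, upper = 1)
  for (v in list(cost_mean = cost_mean, cost_sd = cost_sd,
                 qaly_mean = qaly_mean, qaly_sd = qaly_sd,
                 dropout_to_pps = dropout_to_pps)) {
    if (length(v) != 2L || anyNA(v)) {
      stop("per-arm parameters must be length-2 c(dtx, control) vectors",
           call. = FALSE)
    }
  }
  if (any(cost_sd < 0) || any(qaly_sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (abs(sum(diagnosis_mix) - 1) > 1e-9 || any(diagnosis_mix < 0)) {
    stop("diagnosis_mix fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(diagnosis_mix), c("COPD", "ILD", "OTHER"))) {
    stop("diagnosis_mix must be named COPD, ILD, OTHER", call. = FALSE)
  }
  if (any(dropout_to_pps > c(n_dtx, n_control)) || any(dropout_to_pps < 0)) {
    stop("per-protocol counts must lie between 0 and the arm size", call. = FALSE)
  }
  if (length(mmrc_baseline_probs) != 5L ||
      abs(sum(mmrc_baseline_probs) - 1) > 1e-9) {
    stop("mmrc_baseline_probs must be 5 probabilities summing to 1", call. = FALSE)
  }
  if (cost_mean[1L] <= dtx_fee) {
    stop("DTx arm cost mean must exceed the DTx fee", call. = FALSE)
  }
  cfg <- structure(
    list(n_dtx = as.integer(n_dtx), n_control = as.integer(n_control),
         n_centers = as.integer(n_centers),
         cost_mean = cost_mean, cost_sd = cost_sd, pharm_share = pharm_share,
         qaly_mean = qaly_mean, qaly_sd = qaly_sd,
         dropout_to_pps = as.integer(dropout_to_pps),
         diagnosis_mix = diagnosis_mix[c("COPD", "ILD", "OTHER")],
         dtx_fee = dtx_fee,
         age_mean = age_mean, age_sd = age_sd, male_share = male_share,
         mmrc_baseline_probs = mmrc_baseline_probs,
         mmrc_transition_dtx = mmrc_transition_dtx,
         mmrc_transition_control = mmrc_transition_control,
         p_missing_cost = p_missing_cost, visit_sigma = visit_sigma,
         n_visits_societal = n_visits_societal,
         caregiving_attendance = caregiving_attendance,
         caregiving_hours = caregiving_hours,
         caregiving_wage = caregiving_wage,
         caregiving_employment = caregiving_employment,
         transport_fare = transport_fare,
         days_per_year = days_per_year, algorithm = algorithm,
         seed = as.integer(seed)),
    class = "trial_config"
  )
  utility_beta_params(cfg)  # fail early when the QALY targets are infeasible
  cfg
}

# Utility range attainable under the config's mapping algorithm
utility_bounds <- function(algorithm) {
  lo <- algorithm$intercept - 5 * sum(algorithm$coefficients) -
    40 * algorithm$total_coefficient
  c(lower = lo, upper = algorithm$intercept)
}

# Patient-level mean utilities are drawn from a beta rescaled to the
# attainable utility range, moment-matched per arm to the mean/SD implied by
# the QALY targets (QALY = 56/days_per_year * mean utility for a flat
# trajectory over weeks 0/4/8).  A beta honours the hard ceiling at the
# mapping intercept, which a normal could not without heavy truncation.
utility_beta_params <- function(config) {
  b <- utility_bounds(config$algorithm)
  w <- 56 / config$days_per_year
  lapply(1:2, function(i) {
    m_u <- config$qaly_mean[i] / w
    if (m_u <= b["lower"] || m_u >= b["upper"]) {
      stop("target QALY mean for arm ", i,
           " implies a mean utility outside the attainable range", call. = FALSE)
    }
    # subtract the visit-noise contribution to the QALY variance
    v_q <- config$qaly_sd[i]^2 -
      1176 * config$visit_sigma^2 / config$days_per_year^2
    if (v_q < 0) {
      stop("visit_sigma alone exceeds the target QALY SD for arm ", i,
           call. = FALSE)
    }
    v_u <- v_q / w^2
    span <- b["upper"] - b["lower"]
    m <- (m_u - b["lower"]) / span
    v <- v_u / span^2
    if (v >= m * (1 - m)) {
      stop("target QALY SD for arm ", i,
           " is infeasible on the attainable utility range", call. = FALSE)
    }
    k <- m * (1 - m) / v - 1
    list(shape1 = m * k, shape2 = (1 - m) * k, lower = unname(b["lower"]),
         upper = unname(b["upper"]))
  })
}

# Solve CAT item scores so the mapped utility approximates `target`.
# Greedy integer allocation over the mapped items in decreasing coefficient
# order, then a final bump on the smallest-coefficient item to halve the
# quantization error.  Vectorised over targets; returns an n x 8 matrix.
solve_cat_items <- function(target, algorithm) {
  b <- utility_bounds(algorithm)
  target <- pmin(pmax(target, b["lower"]), b["upper"])
  coefs <- algorithm$coefficients
  mapped <- names(coefs)[coefs > 0]
  mapped <- mapped[order(coefs[mapped], decreasing = TRUE)]
  n <- length(target)
  items <- matrix(0L, n, 8, dimnames = list(NULL, paste0("q", 1:8)))
  resid <- algorithm$intercept - target
  for (q in mapped) {
    s <- pmin(5L, as.integer(floor(resid / coefs[q] + 1e-9)))
    items[, q] <- s
    resid <- resid - coefs[q] * s
  }
  smallest <- mapped[length(mapped)]
  bump <- resid > coefs[smallest] / 2 & items[, smallest] < 5L
  items[bump, smallest] <- items[bump, smallest] + 1L
  items
}

sample_mmrc_path <- function(baseline, transition) {
  n <- length(baseline)
  step <- function(state) {
    vapply(state, function(g) {
      sample.int(5L, 1L, prob = transition[g + 1L, ]) - 1L
    }, integer(1))
  }
  w4 <- step(baseline)
  w8 <- step(w4)
  cbind(w0 = baseline, w4 = w4, w8 = w8)
}

#' Generate a complete synthetic trial
#'
#' Draws a patient-level dataset with the structure the downstream analysis
#' assumes: demographics and diagnoses per arm; strictly positive,
#' right-skewed costs from a gamma distribution moment-matched to the arm
#' targets, split into pharmaceutical and medical lines (plus the DTx fee
#' line in the DTx arm and identical caregiving/transport lines for the
#' societal perspective); CAT item responses solved so the mapped utilities
#' integrate to the arm QALY targets; and mMRC trajectories evolving under
#' the arm transition matrices.  The dataset is complete — apply
#' [inject_missingness()] to obtain dropout and missing costs.
#'
#' @param config A [trial_config()].
#' @return A `dtx_trial`: list of data frames `patients` (patient_id, arm,
#'   center, age, sex, diagnosis, pps_flag), `visits` (patient_id, week,
#'   q1..q8, mmrc) and `costs` (patient_id, category, amount, currency),
#'   with the config attached.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(config$seed, {
    ns <- c(config$n_dtx, config$n_control)
    arms <- rep(c("DTX", "CONTROL"), ns)
    n <- sum(ns)
    arm_idx <- rep(1:2, ns)   # 1 = DTX, 2 = CONTROL

    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      arm = arms,
      center = sample.int(config$n_centers, n, replace = TRUE),
      age = round(pmin(95, pmax(30, stats::rnorm(n, config$age_mean[arm_idx],
                                                 config$age_sd[arm_idx])))),
      sex = ifelse(stats::runif(n) < config$male_share[arm_idx], "M", "F"),
      diagnosis = sample(names(config$diagnosis_mix), n, replace = TRUE,
                         prob = config$diagnosis_mix),
      pps_flag = TRUE,
      stringsAsFactors = FALSE
    )

    # costs: gamma-distributed non-fee total, beta-noised pharmaceutical split
    fee <- ifelse(arms == "DTX", config$dtx_fee, 0)
    nonfee_mean <- config$cost_mean[arm_idx] - fee
    nonfee <- rgamma_matched_vec(n, nonfee_mean, config$cost_sd[arm_idx])
    share <- stats::rbeta(n, config$pharm_share * 30,
                          (1 - config$pharm_share) * 30)
    pharm <- nonfee * share
    medical <- nonfee - pharm
    caregiving <- config$n_visits_societal * config$caregiving_attendance *
      config$caregiving_hours * config$caregiving_wage *
      config$caregiving_employment
    transport <- config$n_visits_societal * config$transport_fare * 2
    costs <- rbind(
      data.frame(patient_id = patients$patient_id, category = "MEDICAL",
                 amount = medical, stringsAsFactors = FALSE),
      data.frame(patient_id = patients$patient_id, category = "PHARMACEUTICAL",
                 amount = pharm, stringsAsFactors = FALSE),
      data.frame(patient_id = patients$patient_id[arms == "DTX"],
                 category = "DTX_FEE",
                 amount = rep(config$dtx_fee, sum(arms == "DTX")),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = patients$patient_id, category = "CAREGIVING",
                 amount = rep(caregiving, n), stringsAsFactors = FALSE),
      data.frame(patient_id = patients$patient_id, category = "TRANSPORT",
                 amount = rep(transport, n), stringsAsFactors = FALSE)
    )
    costs$currency <- "USD"
    costs <- costs[order(match(costs$patient_id, patients$patient_id),
                         match(costs$category, cost_categories)), ]
    rownames(costs) <- NULL

    # utilities: flat per-patient trajectory + visit noise, solved to items
    beta_par <- utility_beta_params(config)
    u_pat <- numeric(n)
    for (i in 1:2) {
      sel <- arm_idx == i
      bp <- beta_par[[i]]
      u_pat[sel] <- bp$lower + (bp$upper - bp$lower) *
        stats::rbeta(sum(sel), bp$shape1, bp$shape2)
    }
    weeks <- c(0L, 4L, 8L)
    u_visit <- rep(u_pat, each = 3L) +
      stats::rnorm(3L * n, 0, config$visit_sigma)
    items <- solve_cat_items(u_visit, config$algorithm)
    # unmapped items carry no utility signal; draw them independently
    unmapped <- names(config$algorithm$coefficients)[
      config$algorithm$coefficients == 0]
    if (config$algorithm$total_coefficient == 0 && length(unmapped)) {
      items[, unmapped] <- matrix(
        stats::rbinom(length(unmapped) * nrow(items), 5L, 0.35),
        ncol = length(unmapped))
    }

    # mMRC trajectories per arm
    mmrc <- matrix(NA_integer_, n, 3L)
    base_grade <- sample(0:4, n, replace = TRUE,
                         prob = config$mmrc_baseline_probs)
    for (i in 1:2) {
      sel <- arm_idx == i
      tm <- if (i == 1) config$mmrc_transition_dtx else config$mmrc_transition_control
      mmrc[sel, ] <- sample_mmrc_path(base_grade[sel], tm)
    }

    visits <- data.frame(
      patient_id = rep(patients$patient_id, each = 3L),
      week = rep(weeks, n),
      items,
      mmrc = as.integer(t(mmrc)),
      stringsAsFactors = FALSE
    )

    structure(list(patients = patients, visits = visits, costs = costs,
                   config = config),
              class = "dtx_trial")
  })
}

# vectorised gamma with element-wise moment matching
rgamma_matched_vec <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  if (any(mean <= 0)) stop("cost targets must be positive", call. = FALSE)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    shape <- (mean[pos] / sd[pos])^2
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              scale = sd[pos]^2 / mean[pos])
  }
  out
}

#' @export
print.dtx_trial <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat(sprintf("Synthetic DTx trial: %d patients (DTX %d / CONTROL %d), %d centers\n",
              nrow(x$patients), tab[["DTX"]], tab[["CONTROL"]],
              length(unique(x$patients$center))))
  cat(sprintf("  visits: %d rows; cost lines: %d; PPS completers: %d\n",
              nrow(x$visits), nrow(x$costs), sum(x$patients$pps_flag)))
  invisible(x)
}

#' Inject missingness and define the per-protocol set
#'
#' Removes the week-8 CAT block and mMRC of randomly selected patients per
#' arm (missing completely at random within arm) until the number of fully
#' adherent patients equals the configured per-protocol counts, marking
#' dropouts with `pps_flag = FALSE`; additionally blanks the pharmaceutical
#' cost amount of a random subset of patients at rate `p_missing_cost`.
#' The RNG stream is derived from the config seed (offset by one) so a
#' generate-and-inject pipeline is reproducible end to end.
#'
#' @param trial A complete `dtx_trial` from [generate_trial()].
#' @param config The [trial_config()]; defaults to the one attached to the
#'   trial.
#' @return The trial with missingness applied.
#' @export
inject_missingness <- function(trial, config = trial$config) {
  stopifnot(inherits(trial, "dtx_trial"), inherits(config, "trial_config"))
  with_seed(config$seed + 1L, {
    for (i in 1:2) {
      arm <- c("DTX", "CONTROL")[i]
      ids <- trial$patients$patient_id[trial$patients$arm == arm]
      n_drop <- length(ids) - config$dropout_to_pps[i]
      if (n_drop < 0) {
        stop("per-protocol target exceeds arm size for ", arm, call. = FALSE)
      }
      if (n_drop > 0) {
        drop_ids <- sample(ids, n_drop)
        trial <- drop_cat_block(trial, drop_ids, week = 8)
        trial$patients$pps_flag[trial$patients$patient_id %in% drop_ids] <- FALSE
      }
    }
    if (config$p_missing_cost > 0) {
      miss <- trial$patients$patient_id[
        stats::runif(nrow(trial$patients)) < config$p_missing_cost]
      sel <- trial$costs$patient_id %in% miss &
        trial$costs$category == "PHARMACEUTICAL"
      trial$costs$amount[sel] <- NA_real_
    }
    trial
  })
}

#' Blank the CAT block of named patients at one visit week
#'
#' Targeted missingness edit: sets `q1..q8` and `mmrc` to `NA` for the
#' given patients at `week`, leaving every other visit untouched.
#'
#' @param trial A `dtx_trial`.
#' @param patient_ids Character vector of patient ids.
#' @param week Visit week to blank.
#' @return The edited trial.
#' @export
drop_cat_block <- function(trial, patient_ids, week) {
  sel <- trial$visits$patient_id %in% patient_ids & trial$visits$week == week
  trial$visits[sel, c(paste0("q", 1:8), "mmrc")] <- NA
  trial
}

#' Read / write a trial as CSV tables
#'
#' `write_trial()` writes `patients.csv`, `visits.csv` and `costs.csv` into
#' a directory; `read_trial()` reassembles a `dtx_trial` from them.  These
#' are the package's plain-text interchange schemas.
#'
#' @param trial A `dtx_trial`.
#' @param dir Directory path (created if needed).
#' @return `write_trial()` the directory invisibly; `read_trial()` a
#'   `dtx_trial`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "dtx_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$costs, file.path(dir, "costs.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  read1 <- function(f) utils::read.csv(file.path(dir, f),
                                       stringsAsFactors = FALSE)
  structure(list(patients = read1("patients.csv"),
                 visits = read1("visits.csv"),
                 costs = read1("costs.csv"),
                 config = NULL),
            class = "dtx_trial")
}
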