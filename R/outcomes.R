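#' @importFrom stats setNames quantile complete.cases aggregate
NULL

cost_categories <- c("MEDICAL", "PHARMACEUTICAL", "DTX_FEE",
                     "CAREGIVING", "TRANSPORT")

#' Analysis perspectives
#'
#' The health-care-system perspective counts medical, pharmaceutical and
#' DTx-fee line items; the limited societal perspective additionally counts
#' informal caregiving and transport, while excluding productivity losses
#' (which this package does not model).
#'
#' @param name `"HEALTHCARE_SYSTEM"` or `"LIMITED_SOCIETAL"`.
#' @return Character vector of included cost categories.
#' @export
perspective_categories <- function(name = c("HEALTHCARE_SYSTEM", "LIMITED_SOCIETAL")) {
  name <- match.arg(name)
  base <- c("MEDICAL", "PHARMACEUTICAL", "DTX_FEE")
  if (name == "LIMITED_SOCIETAL") c(base, "CAREGIVING", "TRANSPORT") else base
}

#' QALYs by the trapezoid rule
#'
#' Accumulates quality-adjusted life years over a utility trajectory
#' observed at visit weeks: each consecutive pair of visits contributes the
#' mean of the two utilities times the interval length in years.
#'
#' @param weeks Strictly increasing numeric vector of visit weeks.
#' @param utilities Utility at each visit (same length as `weeks`).
#' @param days_per_year Annualization denominator; defaults to 365.25.  The
#'   choice shifts every QALY by a common factor and cancels in ratio-based
#'   quantities such as the ICUR.
#' @return QALYs accrued between the first and last visit.
#' @examples
#' qaly_trapezoid(c(0, 4, 8), c(1, 1, 1))          # 56/365.25
#' qaly_trapezoid(c(0, 4), c(1.0, 0.8))            # 0.9 * 28/365.25
#' @export
qaly_trapezoid <- function(weeks, utilities, days_per_year = 365.25) {
  stopifnot_scalar_number(days_per_year, "days_per_year", lower = 1e-9)
  if (length(weeks) < 2L) {
    stop("need at least 2 visits to integrate a utility trajectory", call. = FALSE)
  }
  if (length(utilities) != length(weeks)) {
    stop("weeks and utilities must have the same length", call. = FALSE)
  }
  if (anyNA(weeks) || anyNA(utilities)) {
    stop("missing weeks or utilities; impute first", call. = FALSE)
  }
  d <- diff(weeks)
  if (any(d <= 0)) stop("weeks must be strictly increasing", call. = FALSE)
  mid <- (utilities[-length(utilities)] + utilities[-1L]) / 2
  sum(mid * d * 7 / days_per_year)
}

#' Last observation carried forward for a utility series
#'
#' Replaces each missing utility with the most recent observed value.
#' The baseline (first-week) utility must be observed.  Idempotent.
#'
#' @param series Data frame with columns `week` and `utility` (possibly
#'   `NA`), one patient.
#' @param patient_id Optional label used in error messages.
#' @return The series with missing utilities filled in, sorted by week.
#' @export
locf_impute_utilities <- function(series, patient_id = NULL) {
  stopifnot(is.data.frame(series), all(c("week", "utility") %in% names(series)))
  series <- series[order(series$week), , drop = FALSE]
  u <- series$utility
  if (length(u) == 0L || is.na(u[1L])) {
    stop("baseline utility missing for patient ",
         patient_id %||% "<unknown>", "; cannot carry forward", call. = FALSE)
  }
  for (i in seq_along(u)[-1L]) {
    if (is.na(u[i])) u[i] <- u[i - 1L]
  }
  series$utility <- u
  rownames(series) <- NULL
  series
}

#' Impute missing cost amounts with center means
#'
#' A patient's missing amount for a cost category is replaced by the mean
#' observed amount for that category among patients at the same clinical
#' center; if the whole center lacks observations for the category, the
#' pooled mean over the other centers is used instead.
#'
#' @param costs Cost ledger data frame (`patient_id`, `category`, `amount`,
#'   `currency`); missing amounts are `NA`.
#' @param patients Patient table with `patient_id` and `center`.
#' @return The ledger with amounts filled in and a logical `imputed` column.
#' @export
impute_costs_center_mean <- function(costs, patients) {
  stopifnot(all(c("patient_id", "category", "amount") %in% names(costs)),
            all(c("patient_id", "center") %in% names(patients)))
  costs$imputed <- is.na(costs$amount)
  if (!any(costs$imputed)) return(costs)
  center <- patients$center[match(costs$patient_id, patients$patient_id)]
  if (anyNA(center)) stop("cost rows for unknown patients", call. = FALSE)
  for (i in which(costs$imputed)) {
    cat_i <- costs$category[i]
    obs <- !is.na(costs$amount) & costs$category == cat_i
    if (!any(obs)) {
      stop("no observed costs anywhere for category ", cat_i, call. = FALSE)
    }
    same <- obs & center == center[i]
    pool <- if (any(same)) costs$amount[same] else costs$amount[obs]
    costs$amount[i] <- mean(pool)
  }
  costs
}

#' Total cost for one patient under a perspective
#'
#' Sums the ledger amounts for the categories a perspective includes,
#' converting Korean won to US dollars at `fx_rate`.
#'
#' @param ledger Cost rows for one patient (`category`, `amount`,
#'   `currency` in `{"KRW", "USD"}`).
#' @param perspective `"HEALTHCARE_SYSTEM"` (default) or `"LIMITED_SOCIETAL"`.
#' @param fx_rate Korean won per US dollar; the trial-year rate was 1288.
#' @return Total cost in USD.
#' @export
total_cost <- function(ledger, perspective = "HEALTHCARE_SYSTEM", fx_rate = 1288) {
  stopifnot(all(c("category", "amount") %in% names(ledger)))
  stopifnot_scalar_number(fx_rate, "fx_rate", lower = 1e-9)
  unknown <- setdiff(unique(ledger$category), cost_categories)
  if (length(unknown)) {
    stop("unknown cost categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyNA(ledger$amount)) {
    stop("ledger has missing amounts; impute first", call. = FALSE)
  }
  if (any(ledger$amount < 0)) stop("negative cost amounts", call. = FALSE)
  cur <- if ("currency" %in% names(ledger)) ledger$currency else rep("USD", nrow(ledger))
  usd <- ifelse(cur == "KRW", ledger$amount / fx_rate, ledger$amount)
  keep <- ledger$category %in% perspective_categories(perspective)
  sum(usd[keep])
}

#' Interquartile-range outlier rule
#'
#' Flags values outside (Q1 - k IQR, Q3 + k IQR).  Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7) by default.
#'
#' @param values Numeric vector, at least 4 values.
#' @param k IQR multiplier (default 1.5).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return List with `kept` and `excluded` index vectors and the `lower` /
#'   `upper` bounds.
#' @export
iqr_outlier_filter <- function(values, k = 1.5, type = 7) {
  if (length(values) < 4L) {
    stop("IQR rule needs at least 4 values", call. = FALSE)
  }
  if (anyNA(values)) stop("missing values; impute first", call. = FALSE)
  stopifnot_scalar_number(k, "k", lower = 0)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = type)
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - k * iqr
  upper <- q[2L] + k * iqr
  out <- values < lower | values > upper
  list(kept = which(!out), excluded = which(out), lower = lower, upper = upper)
}

#' Per-patient outcomes: QALYs and costs
#'
#' The workhorse that turns a patient-level trial into one analysis row per
#' patient: utilities are mapped from CAT responses, missing follow-up
#' utilities are carried forward from the last observation, QALYs are
#' accumulated by the trapezoid rule over weeks 0--4, 4--8 and 0--8, missing
#' cost amounts are imputed with center means, and totals are computed under
#' both perspectives.
#'
#' @param trial A `dtx_trial` (see [generate_trial()] / [read_trial()]).
#' @param algorithm CAT-to-utility [mapping_algorithm()].
#' @param days_per_year Annualization denominator for QALYs.
#' @param fx_rate Korean won per US dollar for KRW ledger lines.
#' @param cap_at_one Cap mapped utilities at 1 (default off).
#' @return Data frame with one row per patient: `patient_id`, `arm`,
#'   `center`, `age`, `sex`, `diagnosis`, `pps_flag`, `qaly_0_4`,
#'   `qaly_4_8`, `qaly_0_8`, `cost_medical`, `cost_pharm`,
#'   `cost_total_healthcare`, `cost_total_societal`, `utility_imputed`,
#'   `cost_imputed`.
#' @export
compute_outcomes <- function(trial, algorithm = cat_eq5d_model3(),
                             days_per_year = 365.25, fx_rate = 1288,
                             cap_at_one = FALSE) {
  stopifnot(inherits(trial, "dtx_trial"))
  patients <- trial$patients
  visits <- trial$visits
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient ids", call. = FALSE)
  }
  costs <- impute_costs_center_mean(trial$costs, patients)

  visits$utility <- map_cat_frame(visits, algorithm, cap_at_one)
  cur <- if ("currency" %in% names(costs)) costs$currency else rep("USD", nrow(costs))
  costs$amount_usd <- ifelse(cur == "KRW", costs$amount / fx_rate, costs$amount)

  # utilities on the visit-week grid, patients x weeks
  grid <- sort(unique(visits$week))
  pid_idx <- match(visits$patient_id, patients$patient_id)
  if (anyNA(pid_idx)) stop("visits for unknown patients", call. = FALSE)
  if (anyDuplicated(visits[c("patient_id", "week")])) {
    stop("duplicate patient-week visit rows", call. = FALSE)
  }
  um <- matrix(NA_real_, nrow(patients), length(grid))
  um[cbind(pid_idx, match(visits$week, grid))] <- visits$utility
  utility_imputed <- apply(um, 1L, anyNA)
  if (any(is.na(um[, 1L]))) {
    stop("baseline utility missing for patient ",
         patients$patient_id[which(is.na(um[, 1L]))[1L]],
         "; cannot carry forward", call. = FALSE)
  }
  for (j in seq_along(grid)[-1L]) {           # LOCF column-wise
    um[, j] <- ifelse(is.na(um[, j]), um[, j - 1L], um[, j])
  }
  interval <- function(w1, w2) {
    j1 <- match(w1, grid); j2 <- match(w2, grid)
    if (is.na(j1) || is.na(j2)) return(rep(NA_real_, nrow(um)))
    out <- numeric(nrow(um))
    for (j in j1:(j2 - 1L)) {
      out <- out + (um[, j] + um[, j + 1L]) / 2 *
        (grid[j + 1L] - grid[j]) * 7 / days_per_year
    }
    out
  }
  q04 <- interval(0, 4)
  q48 <- interval(4, 8)
  q08 <- interval(grid[1L], grid[length(grid)])

  by_cat <- function(cats) {
    sel <- costs$category %in% cats
    s <- tapply(costs$amount_usd[sel], costs$patient_id[sel], sum)
    out <- as.numeric(s[patients$patient_id])
    ifelse(is.na(out), 0, out)
  }
  imp <- tapply(costs$imputed, costs$patient_id, any)
  cost_imputed <- as.logical(imp[patients$patient_id])
  cost_imputed[is.na(cost_imputed)] <- FALSE

  keep <- intersect(c("patient_id", "arm", "center", "age", "sex",
                      "diagnosis", "pps_flag"), names(patients))
  cbind(
    patients[keep],
    data.frame(
      qaly_0_4 = q04, qaly_4_8 = q48, qaly_0_8 = q08,
      cost_medical = by_cat(c("MEDICAL", "DTX_FEE")),
      cost_pharm = by_cat("PHARMACEUTICAL"),
      cost_total_healthcare = by_cat(perspective_categories("HEALTHCARE_SYSTEM")),
      cost_total_societal = by_cat(perspective_categories("LIMITED_SOCIETAL")),
      utility_imputed = utility_imputed,
      cost_imputed = cost_imputed
    )
  )
}
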