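#' Base-case cost-utility analysis of a trial
#'
#' Runs the full base-case chain — center-mean cost imputation, CAT-to-
#' utility mapping with last-observation-carried-forward, trapezoid QALYs,
#' arm summaries and the incremental analysis — and returns a report
#' mirroring the trial's cost-utility table.
#'
#' @param trial A `dtx_trial`.
#' @param analysis_set `"FAS"` (default) or `"PPS"`.
#' @param perspective `"HEALTHCARE_SYSTEM"` (default) or
#'   `"LIMITED_SOCIETAL"`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param algorithm CAT-to-utility mapping algorithm.
#' @param days_per_year QALY annualization denominator.
#' @param fx_rate Korean won per USD.
#' @param outcomes Optionally, precomputed [compute_outcomes()] output (to
#'   reuse across scenarios).
#' @return A `cua_report`: the per-patient `outcomes`, the two arm
#'   summaries, the `incremental` result and the `settings` in force.
#' @export
run_base_case <- function(trial, analysis_set = c("FAS", "PPS"),
                          perspective = c("HEALTHCARE_SYSTEM", "LIMITED_SOCIETAL"),
                          wtp = 19410, algorithm = cat_eq5d_model3(),
                          days_per_year = 365.25, fx_rate = 1288,
                          outcomes = NULL) {
  analysis_set <- match.arg(analysis_set)
  perspective <- match.arg(perspective)
  if (is.null(outcomes)) {
    outcomes <- compute_outcomes(trial, algorithm = algorithm,
                                 days_per_year = days_per_year,
                                 fx_rate = fx_rate)
  }
  cost_col <- if (perspective == "LIMITED_SOCIETAL") {
    "cost_total_societal"
  } else {
    "cost_total_healthcare"
  }
  sa <- summarize_arm(outcomes, "DTX", analysis_set, cost_col = cost_col)
  sb <- summarize_arm(outcomes, "CONTROL", analysis_set, cost_col = cost_col)
  structure(
    list(outcomes = outcomes, summary_dtx = sa, summary_control = sb,
         incremental = incremental_analysis(sa, sb, wtp = wtp),
         settings = list(analysis_set = analysis_set,
                         perspective = perspective, wtp = wtp,
                         days_per_year = days_per_year, fx_rate = fx_rate,
                         algorithm = algorithm$name,
                         n_utility_imputed = sum(outcomes$utility_imputed),
                         n_cost_imputed = sum(outcomes$cost_imputed))),
    class = "cua_report"
  )
}

#' @export
print.cua_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Cost-utility analysis (%s, %s perspective, WTP %.0f USD/QALY)\n",
              s$analysis_set, s$perspective, s$wtp))
  cat(sprintf("  imputed: %d utility series, %d cost lines\n",
              s$n_utility_imputed, s$n_cost_imputed))
  print(x$summary_dtx)
  print(x$summary_control)
  print(x$incremental)
  invisible(x)
}

#' Write a cost-utility report as CSV
#'
#' Emits `cua_summary.csv` (per-arm medical, pharmaceutical and total cost,
#' total QALY, the deltas and the ICUR) and `per_patient_outcomes.csv`.
#'
#' @param report A `cua_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cua_report <- function(report, dir) {
  stopifnot(inherits(report, "cua_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- report$summary_dtx
  b <- report$summary_control
  inc <- report$incremental
  summary_df <- data.frame(
    row = c("DTX", "CONTROL", "DIFFERENCE"),
    n = c(a$n, b$n, NA),
    medical = c(a$medical_mean, b$medical_mean,
                a$medical_mean - b$medical_mean),
    pharmaceutical = c(a$pharm_mean, b$pharm_mean,
                       a$pharm_mean - b$pharm_mean),
    total_cost = c(a$cost_mean, b$cost_mean, inc$delta_cost),
    total_qaly = c(a$qaly_mean, b$qaly_mean, inc$delta_qaly),
    icur = c(NA, NA, inc$icur)
  )
  utils::write.csv(summary_df, file.path(dir, "cua_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$outcomes,
                   file.path(dir, "per_patient_outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Subgroup cost-utility analyses
#'
#' Repeats the base-case computation within the per-protocol set, the age
#' strata (at the 65-year baseline threshold) and the COPD and ILD
#' diagnosis strata.  Strata with fewer than 2 patients in either arm are
#' skipped with a warning.
#'
#' @inheritParams run_base_case
#' @param age_threshold Age cut for the age strata (default 65).
#' @return Data frame with one row per stratum (plus the base case):
#'   `subgroup`, `n_dtx`, `n_control`, `delta_cost`, `delta_qaly`, `icur`.
#' @export
run_subgroups <- function(trial, wtp = 19410, algorithm = cat_eq5d_model3(),
                          days_per_year = 365.25, fx_rate = 1288,
                          age_threshold = 65) {
  outcomes <- compute_outcomes(trial, algorithm = algorithm,
                               days_per_year = days_per_year,
                               fx_rate = fx_rate)
  strata <- list(
    base_case = rep(TRUE, nrow(outcomes)),
    pps = outcomes$pps_flag,
    age_ge_65 = outcomes$age >= age_threshold,
    age_lt_65 = outcomes$age < age_threshold,
    copd = outcomes$diagnosis == "COPD",
    ild = outcomes$diagnosis == "ILD"
  )
  rows <- lapply(names(strata), function(nm) {
    sub <- outcomes[strata[[nm]], , drop = FALSE]
    na <- sum(sub$arm == "DTX")
    nb <- sum(sub$arm == "CONTROL")
    if (na < 2 || nb < 2) {
      warning("subgroup ", nm, " skipped: fewer than 2 patients per arm",
              call. = FALSE)
      return(NULL)
    }
    inc <- incremental_analysis(summarize_arm(sub, "DTX"),
                                summarize_arm(sub, "CONTROL"), wtp = wtp)
    data.frame(subgroup = nm, n_dtx = na, n_control = nb,
               delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
               icur = inc$icur, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario analyses
#'
#' Runs the three robustness scenarios alongside the base case: the
#' limited societal perspective (adding caregiving and transport costs),
#' exclusion of cost outliers by the interquartile-range rule (applied per
#' cost category over both arms pooled), and the 1-year five-state Markov
#' extrapolation.
#'
#' @inheritParams run_base_case
#' @param iqr_k IQR multiplier for the outlier rule.
#' @param n_cycles Markov cycles (default 13 x 4 weeks, about one year).
#' @return List with `table` (one row per scenario: n per arm, deltas,
#'   ICUR) and the detailed per-scenario results.
#' @export
run_scenarios <- function(trial, wtp = 19410, algorithm = cat_eq5d_model3(),
                          days_per_year = 365.25, fx_rate = 1288,
                          iqr_k = 1.5, n_cycles = 13) {
  outcomes <- compute_outcomes(trial, algorithm = algorithm,
                               days_per_year = days_per_year,
                               fx_rate = fx_rate)
  base <- run_base_case(trial, wtp = wtp, outcomes = outcomes)
  societal <- run_base_case(trial, perspective = "LIMITED_SOCIETAL",
                            wtp = wtp, outcomes = outcomes)

  # outlier exclusion: drop patients outside the IQR bounds of any
  # category, computed over both arms pooled
  excluded <- rep(FALSE, nrow(outcomes))
  for (col in c("cost_medical", "cost_pharm")) {
    f <- iqr_outlier_filter(outcomes[[col]], k = iqr_k)
    excluded[f$excluded] <- TRUE
  }
  trimmed <- run_base_case(trial, wtp = wtp,
                           outcomes = outcomes[!excluded, , drop = FALSE])

  markov <- markov_from_trial(trial, wtp = wtp, n_cycles = n_cycles,
                              algorithm = algorithm,
                              days_per_year = days_per_year)

  row <- function(name, rep, n_excluded = 0) {
    data.frame(scenario = name,
               n_dtx = rep$summary_dtx$n, n_control = rep$summary_control$n,
               delta_cost = rep$incremental$delta_cost,
               delta_qaly = rep$incremental$delta_qaly,
               icur = rep$incremental$icur,
               n_excluded = n_excluded, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("base_case", base),
    row("limited_societal", societal),
    row("excluding_outliers", trimmed, n_excluded = sum(excluded)),
    data.frame(scenario = "markov_1yr",
               n_dtx = base$summary_dtx$n, n_control = base$summary_control$n,
               delta_cost = markov$incremental$delta_cost,
               delta_qaly = markov$incremental$delta_qaly,
               icur = markov$incremental$icur,
               n_excluded = 0, stringsAsFactors = FALSE)
  )
  list(table = tab, base = base, societal = societal, trimmed = trimmed,
       markov = markov, n_outliers_excluded = sum(excluded))
}
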