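#' Arm-level summary statistics
#'
#' Means and sample standard deviations (n - 1 denominator) of total cost
#' and total QALY over the patients of one arm, the sufficient statistics
#' for the incremental analysis and the probabilistic sensitivity analysis.
#'
#' @param outcomes Per-patient outcomes from [compute_outcomes()], or any
#'   data frame with `arm`, a cost column and a QALY column.
#' @param arm `"DTX"` or `"CONTROL"`.
#' @param analysis_set `"FAS"` (all randomized, default) or `"PPS"`
#'   (patients with `pps_flag == TRUE`).
#' @param cost_col,qaly_col Column names used for the totals; switch
#'   `cost_col` to `"cost_total_societal"` for the limited societal
#'   perspective.
#' @return An `arm_summary`: list with `arm`, `n`, `cost_mean`, `cost_sd`,
#'   `qaly_mean`, `qaly_sd`, and component means `medical_mean`,
#'   `pharm_mean` when the columns are present.
#' @export
summarize_arm <- function(outcomes, arm, analysis_set = c("FAS", "PPS"),
                          cost_col = "cost_total_healthcare",
                          qaly_col = "qaly_0_8") {
  analysis_set <- match.arg(analysis_set)
  stopifnot(is.data.frame(outcomes), "arm" %in% names(outcomes),
            cost_col %in% names(outcomes), qaly_col %in% names(outcomes))
  sel <- outcomes$arm == arm
  if (analysis_set == "PPS") {
    if (!"pps_flag" %in% names(outcomes)) {
      stop("PPS requested but outcomes carry no pps_flag", call. = FALSE)
    }
    sel <- sel & outcomes$pps_flag
  }
  x <- outcomes[sel, , drop = FALSE]
  if (nrow(x) < 2L) {
    stop("arm ", arm, " (", analysis_set, ") has fewer than 2 patients",
         call. = FALSE)
  }
  arm_summary(
    arm = arm, n = nrow(x),
    cost_mean = mean(x[[cost_col]]), cost_sd = sample_sd(x[[cost_col]]),
    qaly_mean = mean(x[[qaly_col]]), qaly_sd = sample_sd(x[[qaly_col]]),
    medical_mean = if ("cost_medical" %in% names(x)) mean(x$cost_medical) else NA_real_,
    pharm_mean = if ("cost_pharm" %in% names(x)) mean(x$cost_pharm) else NA_real_
  )
}

#' Construct an arm summary from known statistics
#'
#' Use this to analyse published arm-level results directly, without
#' patient-level data.
#'
#' @param arm Arm label.
#' @param n Number of patients (>= 2).
#' @param cost_mean,cost_sd Total cost mean and SD (USD).
#' @param qaly_mean,qaly_sd Total QALY mean and SD.
#' @param medical_mean,pharm_mean Optional component means.
#' @export
arm_summary <- function(arm, n, cost_mean, cost_sd, qaly_mean, qaly_sd,
                        medical_mean = NA_real_, pharm_mean = NA_real_) {
  stopifnot_scalar_number(n, "n", lower = 2)
  stopifnot_scalar_number(cost_sd, "cost_sd", lower = 0)
  stopifnot_scalar_number(qaly_sd, "qaly_sd", lower = 0)
  structure(
    list(arm = arm, n = as.integer(n),
         cost_mean = cost_mean, cost_sd = cost_sd,
         qaly_mean = qaly_mean, qaly_sd = qaly_sd,
         medical_mean = medical_mean, pharm_mean = pharm_mean),
    class = "arm_summary"
  )
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("Arm %s (n=%d): cost %.2f (SD %.2f) USD, QALY %.4f (SD %.4f)\n",
              x$arm, x$n, x$cost_mean, x$cost_sd, x$qaly_mean, x$qaly_sd))
  invisible(x)
}

classify_quadrant <- function(delta_cost, delta_qaly) {
  # zero deltas are classified as positive but flagged by the caller
  if (delta_qaly >= 0) {
    if (delta_cost >= 0) "NE" else "SE"
  } else {
    if (delta_cost >= 0) "NW" else "SW"
  }
}

#' Incremental cost-utility analysis
#'
#' Computes the cost and QALY differences between an intervention arm and a
#' comparator, the incremental cost-utility ratio (ICUR), the
#' cost-effectiveness-plane quadrant, and the net monetary benefit (NMB)
#' at a willingness-to-pay (WTP) threshold.
#'
#' @param summary_a Intervention arm: an [arm_summary()] or any list with
#'   `cost_mean` and `qaly_mean`.
#' @param summary_b Comparator arm, same form.
#' @param wtp Willingness-to-pay threshold in USD per QALY; the default is
#'   the Korean reference threshold of 19,410.
#' @return An `incremental_result`: `delta_cost`, `delta_qaly`, `icur`
#'   (`NA` when `delta_qaly == 0`), `status` in
#'   `{"RATIO", "DOMINANT", "DOMINATED", "UNDEFINED"}`, `quadrant`,
#'   `nmb`, `wtp`, and `boundary` flagging a zero delta.
#' @examples
#' a <- list(cost_mean = 390.40, qaly_mean = 0.1568)
#' b <- list(cost_mean = 305.06, qaly_mean = 0.1473)
#' incremental_analysis(a, b)
#' @export
incremental_analysis <- function(summary_a, summary_b, wtp = 19410) {
  stopifnot_scalar_number(wtp, "wtp", lower = 0)
  delta_cost <- summary_a$cost_mean - summary_b$cost_mean
  delta_qaly <- summary_a$qaly_mean - summary_b$qaly_mean
  quadrant <- classify_quadrant(delta_cost, delta_qaly)
  if (delta_qaly == 0) {
    icur <- NA_real_
    status <- "UNDEFINED"
  } else {
    icur <- delta_cost / delta_qaly
    status <- if (delta_cost < 0 && delta_qaly > 0) {
      "DOMINANT"
    } else if (delta_cost > 0 && delta_qaly < 0) {
      "DOMINATED"
    } else {
      "RATIO"
    }
  }
  structure(
    list(delta_cost = delta_cost, delta_qaly = delta_qaly,
         icur = icur, status = status, quadrant = quadrant,
         nmb = wtp * delta_qaly - delta_cost, wtp = wtp,
         boundary = delta_cost == 0 || delta_qaly == 0),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("dCost %.2f USD, dQALY %.4f  [quadrant %s]\n",
              x$delta_cost, x$delta_qaly, x$quadrant))
  icur_txt <- switch(x$status,
                     RATIO = sprintf("%.0f USD/QALY", x$icur),
                     DOMINANT = "dominant (cheaper, more effective)",
                     DOMINATED = "dominated (costlier, less effective)",
                     UNDEFINED = "undefined (zero QALY difference)")
  cat("ICUR:", icur_txt, "\n")
  cat(sprintf("NMB at WTP %.0f: %.2f USD\n", x$wtp, x$nmb))
  invisible(x)
}

#' Percentile confidence interval for the ICUR from PSA iterates
#'
#' Per-iterate cost/QALY ratios are computed and the 2.5th and 97.5th
#' percentiles taken by linear interpolation.  Iterates with a zero QALY
#' difference are excluded (their count is reported).  When the sign of the
#' QALY difference varies across iterates, the ratio is not monotone in net
#' benefit and the interval is flagged as hard to interpret in the usual
#' ordering — a negative lower bound can then accompany a clearly
#' cost-effective intervention.
#'
#' @param psa A [run_psa()] result, or a data frame / list with
#'   `delta_cost` and `delta_qaly` vectors.
#' @param probs Percentile pair (default `c(0.025, 0.975)`).
#' @return List with `lower`, `upper`, `n_used`, `n_excluded_zero_dqaly`,
#'   and logical `mixed_sign`.
#' @export
icur_ci_from_psa <- function(psa, probs = c(0.025, 0.975)) {
  it <- if (inherits(psa, "psa_result")) psa$iterates else psa
  dc <- it$delta_cost
  dq <- it$delta_qaly
  if (length(dc) < 100L) {
    stop("need at least 100 PSA iterates for a percentile interval", call. = FALSE)
  }
  zero <- dq == 0
  ratios <- dc[!zero] / dq[!zero]
  q <- stats::quantile(ratios, probs, names = FALSE, type = 7)
  list(lower = q[1L], upper = q[2L],
       n_used = sum(!zero), n_excluded_zero_dqaly = sum(zero),
       mixed_sign = length(unique(sign(dq[!zero]))) > 1L)
}
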