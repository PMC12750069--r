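#' Probabilistic sensitivity analysis configuration
#'
#' Controls the parametric PSA: per iteration each arm's mean total cost is
#' drawn from a gamma distribution and each arm's mean total QALY from a
#' normal distribution, both moment-matched to the arm summary statistics.
#' The dispersion fed to each family is configurable: `"SEM"` uses the
#' standard error of the mean (`sd / sqrt(n)`), `"SD"` the full sample SD.
#' The defaults (costs at SEM, utilities at full SD) are the package's
#' base-case convention; every result object echoes the choice in force.
#'
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed; the PSA restores the caller's RNG state.
#' @param cost_dispersion `"SEM"` (default) or `"SD"`.
#' @param utility_dispersion `"SD"` (default) or `"SEM"`.
#' @param wtp_grid Ascending willingness-to-pay grid for the CEAC.
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_iter = 1000, seed = NULL,
                       cost_dispersion = c("SEM", "SD"),
                       utility_dispersion = c("SD", "SEM"),
                       wtp_grid = seq(0, 40000, by = 500)) {
  stopifnot_scalar_number(n_iter, "n_iter", lower = 1)
  if (is.unsorted(wtp_grid) || length(wtp_grid) < 2L) {
    stop("wtp_grid must be an ascending grid with >= 2 points", call. = FALSE)
  }
  structure(
    list(n_iter = as.integer(n_iter), seed = seed,
         cost_dispersion = match.arg(cost_dispersion),
         utility_dispersion = match.arg(utility_dispersion),
         wtp_grid = wtp_grid),
    class = "psa_config"
  )
}

dispersion_value <- function(sd, n, mode) {
  if (mode == "SEM") sd / sqrt(n) else sd
}

# gamma draw moment-matched to (mean, sd); sd = 0 degenerates to the mean
rgamma_matched <- function(n, mean, sd) {
  if (mean <= 0 && sd > 0) {
    stop("gamma cost parameterization needs a positive mean", call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

rnorm_matched <- function(n, mean, sd) {
  if (sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

#' Run the probabilistic sensitivity analysis
#'
#' @param summary_a Intervention [arm_summary()].
#' @param summary_b Comparator [arm_summary()].
#' @param config A [psa_config()].
#' @return A `psa_result` with `iterates` (data frame: `iter`, `cost_a`,
#'   `cost_b`, `qaly_a`, `qaly_b`, `delta_cost`, `delta_qaly`), the
#'   `config` in force and the input summaries.
#' @examples
#' a <- arm_summary("DTX", 43, 390.40, 193.09, 0.1568, 0.016)
#' b <- arm_summary("CONTROL", 41, 305.06, 220.18, 0.1473, 0.013)
#' psa <- run_psa(a, b, psa_config(n_iter = 500, seed = 1))
#' quadrant_summary(psa, wtp = 19410)
#' @export
run_psa <- function(summary_a, summary_b, config = psa_config()) {
  stopifnot(inherits(config, "psa_config"))
  n <- config$n_iter
  draws <- with_seed(config$seed, {
    ca <- rgamma_matched(n, summary_a$cost_mean,
                         dispersion_value(summary_a$cost_sd, summary_a$n,
                                          config$cost_dispersion))
    cb <- rgamma_matched(n, summary_b$cost_mean,
                         dispersion_value(summary_b$cost_sd, summary_b$n,
                                          config$cost_dispersion))
    qa <- rnorm_matched(n, summary_a$qaly_mean,
                        dispersion_value(summary_a$qaly_sd, summary_a$n,
                                         config$utility_dispersion))
    qb <- rnorm_matched(n, summary_b$qaly_mean,
                        dispersion_value(summary_b$qaly_sd, summary_b$n,
                                         config$utility_dispersion))
    data.frame(iter = seq_len(n), cost_a = ca, cost_b = cb,
               qaly_a = qa, qaly_b = qb,
               delta_cost = ca - cb, delta_qaly = qa - qb)
  })
  structure(
    list(iterates = draws, config = config,
         summary_a = summary_a, summary_b = summary_b),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (cost dispersion %s, utility dispersion %s)\n",
              x$config$n_iter, x$config$cost_dispersion,
              x$config$utility_dispersion))
  print(quadrant_summary(x))
  invisible(x)
}

#' Cost-effectiveness-plane quadrant shares
#'
#' Classifies each PSA iterate by the signs of (delta cost, delta QALY) and
#' reports the share of iterates per quadrant, the share of
#' northeast-quadrant iterates falling below the willingness-to-pay line —
#' both conditional on the NE quadrant and as a fraction of all iterates —
#' and the overall probability of positive net monetary benefit.  Zero
#' deltas (measure-zero under the continuous families) count as positive.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A `quadrant_summary` list: `n`, counts and shares per quadrant
#'   (`ne`, `nw`, `se`, `sw`), `ne_below_wtp_conditional`,
#'   `ne_below_wtp_overall`, `p_cost_effective`.
#' @export
quadrant_summary <- function(psa, wtp = 19410) {
  stopifnot(inherits(psa, "psa_result"))
  stopifnot_scalar_number(wtp, "wtp", lower = 0)
  it <- psa$iterates
  dc <- it$delta_cost
  dq <- it$delta_qaly
  n <- nrow(it)
  ne <- dc >= 0 & dq >= 0
  nw <- dc >= 0 & dq < 0
  se <- dc < 0 & dq >= 0
  sw <- dc < 0 & dq < 0
  ne_below <- ne & (dc < wtp * dq)   # strictly below the WTP line
  nmb <- wtp * dq - dc
  structure(
    list(n = n, wtp = wtp,
         counts = c(NE = sum(ne), NW = sum(nw), SE = sum(se), SW = sum(sw)),
         shares = c(NE = mean(ne), NW = mean(nw), SE = mean(se), SW = mean(sw)),
         ne_below_wtp_conditional = if (any(ne)) sum(ne_below) / sum(ne) else NA_real_,
         ne_below_wtp_overall = mean(ne_below),
         p_cost_effective = mean(nmb > 0)),
    class = "quadrant_summary"
  )
}

#' @export
print.quadrant_summary <- function(x, ...) {
  s <- x$shares * 100
  cat(sprintf("  quadrants: NE %.1f%%  NW %.1f%%  SE %.1f%%  SW %.1f%%\n",
              s["NE"], s["NW"], s["SE"], s["SW"]))
  cat(sprintf("  NE below WTP %.0f: %.1f%% of NE (%.1f%% of all)\n",
              x$wtp, 100 * x$ne_below_wtp_conditional,
              100 * x$ne_below_wtp_overall))
  cat(sprintf("  P(cost-effective at WTP): %.1f%%\n", 100 * x$p_cost_effective))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the share of PSA iterates with positive net
#' monetary benefit; in a two-comparator analysis the comparator's curve is
#' the complement.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Ascending grid; defaults to the grid in the PSA config.
#' @return Data frame with `wtp`, `p_dtx`, `p_control`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  wtp_grid <- wtp_grid %||% psa$config$wtp_grid
  if (is.unsorted(wtp_grid) || length(wtp_grid) < 2L) {
    stop("wtp_grid must be an ascending grid with >= 2 points", call. = FALSE)
  }
  it <- psa$iterates
  p <- vapply(wtp_grid,
              function(w) mean(w * it$delta_qaly - it$delta_cost > 0),
              numeric(1))
  data.frame(wtp = wtp_grid, p_dtx = p, p_control = 1 - p)
}

#' Cost-effectiveness plane / CEAC plots
#'
#' Base-graphics views of a PSA: the scatter of iterates on the
#' cost-effectiveness plane with the WTP line, or the acceptability curves.
#'
#' @param x A `psa_result`.
#' @param which `"plane"` or `"ceac"`.
#' @param wtp Threshold drawn on the plane / marked on the CEAC.
#' @param ... Passed to the underlying plot call.
#' @export
plot.psa_result <- function(x, which = c("plane", "ceac"), wtp = 19410, ...) {
  which <- match.arg(which)
  it <- x$iterates
  if (which == "plane") {
    plot(it$delta_qaly, it$delta_cost, pch = 16, cex = 0.4,
         col = "grey30", xlab = "Incremental QALY",
         ylab = "Incremental cost (USD)", ...)
    abline(h = 0, v = 0, col = "grey70")
    abline(a = 0, b = wtp, lwd = 2)
    points(mean(it$delta_qaly), mean(it$delta_cost), pch = 4, cex = 1.5, lwd = 2)
  } else {
    cc <- ceac(x)
    plot(cc$wtp, cc$p_dtx, type = "l", lwd = 2, ylim = c(0, 1),
         xlab = "Willingness-to-pay (USD/QALY)",
         ylab = "Probability cost-effective", ...)
    lines(cc$wtp, cc$p_control, col = "grey50", lwd = 2)
    abline(v = wtp, lty = 2)
  }
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the ICUR with each parameter set to the low and then the high
#' end of its range while all other parameters stay at base case.  The
#' default parameter set is the four arm-level means (cost and QALY in each
#' arm) varied over their 95% confidence intervals,
#' `mean +- 1.96 * sd / sqrt(n)`.  Additional scenarios — e.g. QALY pairs
#' re-estimated under alternative mapping algorithms — can be appended via
#' `scenarios`.
#'
#' @param summary_a,summary_b [arm_summary()] objects.
#' @param wtp Willingness-to-pay threshold (for reference only; the ICUR is
#'   reported unrounded).
#' @param ranges Optional named list overriding parameter ranges; each
#'   element is `c(low, high)` bracketing the base value, with names among
#'   `cost_a`, `cost_b`, `qaly_a`, `qaly_b`.
#' @param scenarios Optional named list of alternative `(qaly_a, qaly_b)`
#'   pairs, each a list with those two fields; the entry's low/high ICURs
#'   are the min/max over the supplied pairs.
#' @return Data frame of class `tornado` sorted by decreasing range width:
#'   `parameter`, `low`, `high`, `icur_low`, `icur_high`, `width`.
#' @export
one_way_dsa <- function(summary_a, summary_b, wtp = 19410, ranges = NULL,
                        scenarios = NULL) {
  base <- list(cost_a = summary_a$cost_mean, cost_b = summary_b$cost_mean,
               qaly_a = summary_a$qaly_mean, qaly_b = summary_b$qaly_mean)
  ci <- function(mean, sd, n) mean + c(-1, 1) * 1.96 * sd / sqrt(n)
  default_ranges <- list(
    cost_a = ci(summary_a$cost_mean, summary_a$cost_sd, summary_a$n),
    cost_b = ci(summary_b$cost_mean, summary_b$cost_sd, summary_b$n),
    qaly_a = ci(summary_a$qaly_mean, summary_a$qaly_sd, summary_a$n),
    qaly_b = ci(summary_b$qaly_mean, summary_b$qaly_sd, summary_b$n)
  )
  if (!is.null(ranges)) {
    unknown <- setdiff(names(ranges), names(default_ranges))
    if (length(unknown)) {
      stop("unknown DSA parameters: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    default_ranges[names(ranges)] <- ranges
  }
  icur_at <- function(p) (p$cost_a - p$cost_b) / (p$qaly_a - p$qaly_b)
  rows <- lapply(names(default_ranges), function(par) {
    r <- default_ranges[[par]]
    if (r[1L] > r[2L]) stop("range for ", par, " has low > high", call. = FALSE)
    if (base[[par]] < r[1L] || base[[par]] > r[2L]) {
      stop("range for ", par, " does not bracket its base value", call. = FALSE)
    }
    lo <- base; lo[[par]] <- r[1L]
    hi <- base; hi[[par]] <- r[2L]
    data.frame(parameter = par, low = r[1L], high = r[2L],
               icur_low = icur_at(lo), icur_high = icur_at(hi))
  })
  if (!is.null(scenarios)) {
    icurs <- vapply(scenarios, function(s) {
      icur_at(list(cost_a = base$cost_a, cost_b = base$cost_b,
                   qaly_a = s$qaly_a, qaly_b = s$qaly_b))
    }, numeric(1))
    rows <- c(rows, list(data.frame(parameter = "mapping_algorithm",
                                    low = NA_real_, high = NA_real_,
                                    icur_low = min(icurs),
                                    icur_high = max(icurs))))
  }
  out <- do.call(rbind, rows)
  out$width <- abs(out$icur_high - out$icur_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", class(out))
  out
}
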