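#' Value-based price of the DTx usage fee
#'
#' The value-based price (VBP) is the usage fee at which the intervention's
#' incremental cost-utility ratio equals the willingness-to-pay threshold.
#' Writing the DTx arm's total cost as `fee + othercosts_a`, the closed
#' form is
#'
#' `VBP = wtp * (qaly_a - qaly_b) + cost_b - othercosts_a`
#'
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param qaly_a,qaly_b Total QALY means of the DTx and comparator arms.
#' @param cost_b Comparator arm total cost mean (USD).
#' @param othercosts_a DTx arm total cost mean excluding the usage fee (USD).
#' @return A `vbp_result`: `price` (exact), `price_display` (rounded down
#'   to the whole dollar, since any higher integer price would push the
#'   ICUR above the threshold), and `negative` flagging a price below zero
#'   (the intervention is not cost-effective even free of charge).
#' @examples
#' solve_vbp(19410, 0.1568, 0.1473, 305.06, 390.40 - 93.17)  # 192 USD
#' @export
solve_vbp <- function(wtp, qaly_a, qaly_b, cost_b, othercosts_a) {
  stopifnot_scalar_number(wtp, "wtp", lower = 0)
  stopifnot_scalar_number(othercosts_a, "othercosts_a", lower = 0)
  price <- wtp * (qaly_a - qaly_b) + cost_b - othercosts_a
  structure(
    list(price = price, price_display = floor(price), negative = price < 0,
         wtp = wtp),
    class = "vbp_result"
  )
}

#' @export
print.vbp_result <- function(x, ...) {
  cat(sprintf("Value-based price at WTP %.0f USD/QALY: %.2f USD (display %d)\n",
              x$wtp, x$price, as.integer(x$price_display)))
  if (x$negative) {
    cat("  note: negative price - not cost-effective at any non-negative fee\n")
  }
  invisible(x)
}

#' ICUR as a function of the DTx usage fee
#'
#' Sweeps the usage fee over a grid while holding QALYs and all other costs
#' fixed, recomputing the ICUR at each fee.  The ICUR is affine in the fee
#' with slope `1 / (qaly_a - qaly_b)`, so for a positive QALY gain the
#' curve is increasing and crosses the willingness-to-pay threshold exactly
#' at the value-based price.
#'
#' @param fees Ascending numeric grid of candidate fees (USD).
#' @param qaly_a,qaly_b,cost_b,othercosts_a As in [solve_vbp()].
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Data frame with columns `fee`, `icur` (`NA` when the QALY
#'   difference is zero) and logical `cost_effective` (ICUR at or below the
#'   threshold when the QALY gain is positive; otherwise decided by net
#'   monetary benefit).
#' @export
price_sweep <- function(fees, qaly_a, qaly_b, cost_b, othercosts_a,
                        wtp = 19410) {
  if (length(fees) == 0L) stop("empty fee grid", call. = FALSE)
  if (is.unsorted(fees, strictly = FALSE)) {
    stop("fee grid must be ascending", call. = FALSE)
  }
  delta_qaly <- qaly_a - qaly_b
  delta_cost <- othercosts_a + fees - cost_b
  nmb <- wtp * delta_qaly - delta_cost
  if (delta_qaly == 0) {
    icur <- rep(NA_real_, length(fees))
    ce <- nmb > 0
  } else {
    icur <- delta_cost / delta_qaly
    ce <- if (delta_qaly > 0) icur <= wtp else nmb > 0
  }
  data.frame(fee = fees, icur = icur, cost_effective = ce)
}
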