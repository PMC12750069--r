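#' CAT-to-EQ-5D-3L mapping algorithms
#'
#' A mapping algorithm converts the eight COPD Assessment Test (CAT) item
#' scores (each 0--5) into an EQ-5D-3L utility index.  An algorithm is an
#' intercept plus per-item decrements: predicted utility is
#' `intercept - sum(coefficients[i] * item[i])`, optionally minus
#' `total_coefficient * sum(items)` for total-score-based algorithms.
#' Coefficients are stored as positive decrements, matching the published
#' regression convention in which every item score lowers utility.
#'
#' @param name Short label for the algorithm.
#' @param intercept Predicted utility when every referenced item scores 0.
#' @param coefficients Named numeric vector of per-point utility decrements;
#'   names must be a subset of `q1`..`q8`.
#' @param total_coefficient Optional decrement per point of the CAT total
#'   score, for algorithms estimated on the summed score (default 0).
#' @return An object of class `mapping_algorithm`.
#' @examples
#' alg <- cat_eq5d_model3()
#' map_cat_to_utility(rep(0, 8), alg)    # the intercept, 1.0661
#' @export
mapping_algorithm <- function(name, intercept, coefficients = numeric(),
                              total_coefficient = 0) {
  stopifnot_scalar_number(intercept, "intercept")
  stopifnot_scalar_number(total_coefficient, "total_coefficient")
  if (length(coefficients)) {
    items <- names(coefficients)
    if (is.null(items) || !all(items %in% paste0("q", 1:8))) {
      stop("coefficient names must be a subset of q1..q8", call. = FALSE)
    }
    if (anyDuplicated(items)) stop("duplicated item coefficients", call. = FALSE)
    if (!is.numeric(coefficients) || any(!is.finite(coefficients))) {
      stop("coefficients must be finite numbers", call. = FALSE)
    }
  }
  full <- stats::setNames(numeric(8), paste0("q", 1:8))
  full[names(coefficients)] <- as.numeric(coefficients)
  structure(
    list(name = as.character(name), intercept = intercept,
         coefficients = full, total_coefficient = total_coefficient),
    class = "mapping_algorithm"
  )
}

#' @export
print.mapping_algorithm <- function(x, ...) {
  cat("CAT -> EQ-5D-3L mapping algorithm:", x$name, "\n")
  cat("  intercept:", format(x$intercept), "\n")
  used <- x$coefficients[x$coefficients != 0]
  if (length(used)) {
    cat("  item decrements:",
        paste(sprintf("%s=%.4f", names(used), used), collapse = ", "), "\n")
  }
  if (x$total_coefficient != 0) {
    cat("  total-score decrement:", format(x$total_coefficient), "\n")
  }
  invisible(x)
}

#' Default mapping: ordinary least squares on five CAT items
#'
#' The algorithm shipped as the package default, estimated in a Korean
#' tertiary-hospital population of patients with chronic respiratory
#' disease:
#'
#' utility = 1.0661 - 0.0103 Q3 - 0.0120 Q4 - 0.0168 Q5 - 0.0255 Q6 - 0.0125 Q8
#'
#' Items Q1, Q2 and Q7 do not enter the model.  Over the valid item range
#' the prediction lies in \[0.6806, 1.0661\]; note the intercept exceeds 1,
#' see [map_cat_to_utility()] for the capping policy.
#'
#' @return A `mapping_algorithm`.
#' @export
cat_eq5d_model3 <- function() {
  mapping_algorithm(
    name = "cat-eq5d3l-ols-model3",
    intercept = 1.0661,
    coefficients = c(q3 = 0.0103, q4 = 0.0120, q5 = 0.0168,
                     q6 = 0.0255, q8 = 0.0125)
  )
}

validate_cat_items <- function(cat_items) {
  if (length(cat_items) != 8L) {
    stop("a CAT response has exactly 8 items (q1..q8), got ",
         length(cat_items), call. = FALSE)
  }
  if (anyNA(cat_items)) {
    stop("CAT items contain missing values; impute before mapping",
         call. = FALSE)
  }
  if (!is.numeric(cat_items) || any(cat_items < 0 | cat_items > 5)) {
    stop("CAT items must be scores in [0, 5]", call. = FALSE)
  }
  invisible(as.numeric(cat_items))
}

#' Map one CAT response to an EQ-5D-3L utility
#'
#' @param cat_items Numeric vector of the 8 item scores (q1..q8), each in
#'   0--5 and none missing.
#' @param algorithm A [mapping_algorithm()]; defaults to [cat_eq5d_model3()].
#' @param cap_at_one If `TRUE`, predictions above 1 are truncated to 1.
#'   The default is `FALSE`: the shipped algorithm's intercept (1.0661)
#'   exceeds 1 and the trial-level QALY magnitudes are consistent with
#'   uncapped predictions, so capping is opt-in.
#' @return A single utility value (dimensionless).
#' @export
map_cat_to_utility <- function(cat_items, algorithm = cat_eq5d_model3(),
                               cap_at_one = FALSE) {
  stopifnot(inherits(algorithm, "mapping_algorithm"))
  cat_items <- validate_cat_items(cat_items)
  u <- algorithm$intercept -
    sum(algorithm$coefficients * cat_items) -
    algorithm$total_coefficient * sum(cat_items)
  if (cap_at_one) u <- min(u, 1)
  u
}

# vectorised mapping over a visits-shaped data frame with columns q1..q8;
# rows with any missing item map to NA (imputation is done at utility level)
map_cat_frame <- function(visits, algorithm = cat_eq5d_model3(),
                          cap_at_one = FALSE) {
  qcols <- paste0("q", 1:8)
  stopifnot(all(qcols %in% names(visits)))
  m <- as.matrix(visits[qcols])
  ok <- stats::complete.cases(m)
  bad <- ok & (apply(m, 1L, function(r) any(r < 0 | r > 5)))
  if (any(bad)) stop("CAT items outside [0, 5] in visit rows", call. = FALSE)
  u <- rep(NA_real_, nrow(visits))
  if (any(ok)) {
    u[ok] <- algorithm$intercept -
      as.vector(m[ok, , drop = FALSE] %*% algorithm$coefficients) -
      algorithm$total_coefficient * rowSums(m[ok, , drop = FALSE])
  }
  if (cap_at_one) u <- pmin(u, 1)
  u
}

#' Utility trajectory for one patient
#'
#' Maps every visit that carries a complete CAT block and returns the
#' utilities in week order.  Visits with an incomplete or absent CAT block
#' are dropped (impute with [locf_impute_utilities()] afterwards if the
#' analysis needs the full visit grid).
#'
#' @param visits Data frame with columns `week` and `q1`..`q8` for a single
#'   patient.
#' @param algorithm A [mapping_algorithm()].
#' @param cap_at_one See [map_cat_to_utility()].
#' @return Data frame with columns `week` and `utility`, sorted by week.
#' @export
map_visit_series <- function(visits, algorithm = cat_eq5d_model3(),
                             cap_at_one = FALSE) {
  stopifnot(is.data.frame(visits), "week" %in% names(visits))
  if (anyDuplicated(visits$week)) {
    stop("duplicate visit weeks for one patient", call. = FALSE)
  }
  visits <- visits[order(visits$week), , drop = FALSE]
  u <- map_cat_frame(visits, algorithm, cap_at_one)
  out <- data.frame(week = visits$week, utility = u)
  out <- out[!is.na(out$utility), , drop = FALSE]
  if (nrow(out) == 0L) {
    id <- if ("patient_id" %in% names(visits)) unique(visits$patient_id) else "<unknown>"
    stop("no visit with a complete CAT block for patient ", id, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read / write a mapping-algorithm definition file
#'
#' Algorithm files are small YAML documents with fields `name`,
#' `intercept`, an optional `coefficients` map (`q3: 0.0103`, ...) and an
#' optional `total_coefficient`.  This is the interchange format for the
#' alternative published algorithms used in the deterministic sensitivity
#' analysis; no third-party coefficients are bundled with the package.
#'
#' @param path File path.
#' @return `read_mapping_algorithm()` returns a `mapping_algorithm`;
#'   `write_mapping_algorithm()` returns `path` invisibly.
#' @export
read_mapping_algorithm <- function(path) {
  spec <- yaml::read_yaml(path)
  mapping_algorithm(
    name = spec$name %||% basename(path),
    intercept = as.numeric(spec$intercept),
    coefficients = unlist(spec$coefficients %||% list()),
    total_coefficient = as.numeric(spec$total_coefficient %||% 0)
  )
}

#' @rdname read_mapping_algorithm
#' @param algorithm A `mapping_algorithm` to serialise.
#' @export
write_mapping_algorithm <- function(algorithm, path) {
  stopifnot(inherits(algorithm, "mapping_algorithm"))
  used <- algorithm$coefficients[algorithm$coefficients != 0]
  spec <- list(name = algorithm$name, intercept = algorithm$intercept)
  if (length(used)) spec$coefficients <- as.list(used)
  if (algorithm$total_coefficient != 0) {
    spec$total_coefficient <- algorithm$total_coefficient
  }
  yaml::write_yaml(spec, path)
  invisible(path)
}
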