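# Shared fixtures: the study-condition arm summaries and small hand-built
# trial objects used across test files.

ref_dtx <- function() arm_summary("DTX", 43, 390.40, 193.09, 0.1568, 0.016)
ref_control <- function() arm_summary("CONTROL", 41, 305.06, 220.18, 0.1473, 0.013)

# A tiny three-patient trial with hand-checkable values.
toy_trial <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    arm = c("DTX", "DTX", "CONTROL"),
    center = c(1L, 1L, 2L),
    age = c(60, 70, 66),
    sex = c("M", "F", "M"),
    diagnosis = c("COPD", "ILD", "COPD"),
    pps_flag = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  qz <- function(n) matrix(0L, n, 8, dimnames = list(NULL, paste0("q", 1:8)))
  visits <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 3L),
    week = rep(c(0L, 4L, 8L), 3L),
    qz(9L),
    mmrc = rep(c(1L, 2L, 0L), each = 3L),
    stringsAsFactors = FALSE
  )
  costs <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 2L),
    category = rep(c("MEDICAL", "PHARMACEUTICAL"), 3L),
    amount = c(100, 50, 200, 150, 120, 80),
    currency = "USD",
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, visits = visits, costs = costs,
                 config = NULL),
            class = "dtx_trial")
}

default_coefs <- c(q3 = 0.0103, q4 = 0.0120, q5 = 0.0168,
                   q6 = 0.0255, q8 = 0.0125)

# random valid CAT response
random_cat <- function() sample(0:5, 8, replace = TRUE)
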