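# Deterministic trauma scores: TRISS probability of survival and helpers.

#' Age index used by the TRISS equations
#'
#' 0 for age below 55 years, 1 for age 55 or older.
#'
#' @param age Age in years (vectorised), non-negative.
#' @return Integer 0/1 vector.
#' @export
age_index <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be non-negative and finite")
  }
  as.integer(age >= 55)
}

#' TRISS probability of survival
#'
#' Computes `Ps = 1 / (1 + exp(-b))` with the mechanism-specific linear
#' predictor: for blunt trauma
#' `b = -0.4499 + 0.8085 * RTS - 0.0835 * ISS - 1.7430 * AgeIndex`,
#' and for penetrating trauma
#' `b = -2.5355 + 0.9934 * RTS - 0.0651 * ISS - 1.1360 * AgeIndex`.
#'
#' @param rts Revised Trauma Score, in `[0, 7.8408]` (vectorised).
#' @param iss Injury Severity Score, in `[0, 75]`.
#' @param age Age in years.
#' @param mechanism `"blunt"` or `"penetrating"` (vectorised).
#' @return Survival probabilities in (0, 1).
#' @export
triss_ps <- function(rts, iss, age, mechanism) {
  n <- max(length(rts), length(iss), length(age), length(mechanism))
  rts <- rep_len(rts, n); iss <- rep_len(iss, n)
  age <- rep_len(age, n); mechanism <- rep_len(as.character(mechanism), n)
  if (any(!mechanism %in% c("blunt", "penetrating"))) {
    stop("`mechanism` must be \"blunt\" or \"penetrating\"")
  }
  if (any(iss < 0 | iss > 75)) stop("`iss` must be in [0, 75]")
  if (any(rts < 0 | rts > 7.8408 + 1e-9)) stop("`rts` must be in [0, 7.8408]")
  ai <- age_index(age)
  b <- ifelse(mechanism == "blunt",
              -0.4499 + 0.8085 * rts - 0.0835 * iss - 1.7430 * ai,
              -2.5355 + 0.9934 * rts - 0.0651 * iss - 1.1360 * ai)
  stats::plogis(b)
}

#' Weighted Revised Trauma Score from coded components
#'
#' Standard triage-coded RTS, `0.9368 * GCSc + 0.7326 * SBPc + 0.2908 * RRc`,
#' where each component is coded 0--4. Provided as a convenience for
#' simulation inputs; the analysis itself consumes RTS as a recorded number.
#'
#' @param gcs_c,sbp_c,rr_c Coded Glasgow Coma Scale, systolic blood pressure
#'   and respiratory rate components, each an integer 0--4.
#' @return RTS values in `[0, 7.8408]`.
#' @export
rts_score <- function(gcs_c, sbp_c, rr_c) {
  for (v in list(gcs_c, sbp_c, rr_c)) {
    if (any(!v %in% 0:4)) stop("coded components must be integers in 0..4")
  }
  0.9368 * gcs_c + 0.7326 * sbp_c + 0.2908 * rr_c
}
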