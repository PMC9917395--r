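# Raw-table preprocessing: cohort screening, daily-maximum blocking over the
# 50-day horizon, KNN imputation of AIS, and ISS derivation.

#' Apply the cohort inclusion rules to a screening roster
#'
#' Exclusion rules are applied sequentially, each to the patients surviving
#' the previous rule, in the flow order: D-dimer measured on fewer than three
#' distinct days; re-admission after recovery from the primary trauma;
#' trauma-to-hospitalisation interval above 14 days; age 18 or younger;
#' cancer; pregnancy. Audit counts therefore sum, with the included count,
#' to the screened total.
#'
#' @param roster Data frame with columns `patient_id`, `n_ddimer_days`,
#'   `readmission`, `trauma_to_admission_days`, `age`, `cancer`, `pregnant`.
#' @param min_days Minimum number of distinct D-dimer days (default 3).
#' @param max_interval_days Maximum trauma-to-admission interval (default 14).
#' @param min_age Exclusive minimum age (default 18; patients aged `<= 18`
#'   are excluded).
#' @return A list with `included_ids`, a named `audit` vector of per-rule
#'   exclusion counts, `n_screened` and `n_included`.
#' @export
apply_exclusions <- function(roster, min_days = 3, max_interval_days = 14,
                             min_age = 18) {
  need <- c("patient_id", "n_ddimer_days", "readmission",
            "trauma_to_admission_days", "age", "cancer", "pregnant")
  missing_cols <- setdiff(need, names(roster))
  if (length(missing_cols)) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in need[-1]) {
    bad <- is.na(roster[[col]])
    if (any(bad)) {
      stop(sprintf("missing `%s` for patient(s): %s", col,
                   paste(utils::head(roster$patient_id[bad], 5),
                         collapse = ", ")))
    }
  }
  rules <- list(
    few_ddimer_days = function(d) d$n_ddimer_days < min_days,
    readmission = function(d) as.logical(d$readmission),
    late_admission = function(d) d$trauma_to_admission_days > max_interval_days,
    age_le_18 = function(d) d$age <= min_age,
    cancer = function(d) as.logical(d$cancer),
    pregnant = function(d) as.logical(d$pregnant)
  )
  audit <- integer(length(rules))
  names(audit) <- names(rules)
  remaining <- roster
  for (r in names(rules)) {
    hit <- rules[[r]](remaining)
    audit[[r]] <- sum(hit)
    remaining <- remaining[!hit, , drop = FALSE]
  }
  list(included_ids = remaining$patient_id, audit = audit,
       n_screened = nrow(roster), n_included = nrow(remaining))
}

#' Collapse raw D-dimer measurements into daily maxima
#'
#' Measurements are grouped into 1-day blocks (day 0 = day of trauma; the day
#' index is the whole number of days elapsed since the trauma date) and each
#' block keeps its maximum value, emphasising the worst pathological state of
#' the day. Values are clipped to the censoring interval with a censoring
#' flag, and days beyond the horizon are dropped.
#'
#' @param raw Data frame with `patient_id`, a time column, and `value`
#'   (mg/L). The time column may be `day` (numeric days since trauma,
#'   possibly fractional) or `datetime` (`Date`/`POSIXct`), in which case
#'   `trauma_date` is required.
#' @param trauma_date Optional `Date`/`POSIXct` of the trauma, used to
#'   convert timestamps to day indices.
#' @param horizon_days Last retained day (default 50).
#' @param censor_lo,censor_hi Clipping bounds (default 0 and 40 mg/L).
#' @return Data frame with `patient_id`, `day`, `value`, and logical
#'   `censored_low` / `censored_high` flags; one row per patient-day.
#' @export
block_daily_max <- function(raw, trauma_date = NULL, horizon_days = 50,
                            censor_lo = 0, censor_hi = 40) {
  if (!all(c("patient_id", "value") %in% names(raw))) {
    stop("raw table must have `patient_id` and `value` columns")
  }
  if ("day" %in% names(raw)) {
    day <- floor(as.numeric(raw$day))
  } else if ("datetime" %in% names(raw)) {
    if (is.null(trauma_date)) {
      stop("`trauma_date` is required when measurements carry timestamps")
    }
    day <- floor(as.numeric(difftime(as.POSIXct(raw$datetime),
                                     as.POSIXct(trauma_date),
                                     units = "days")))
  } else {
    stop("raw table must have a `day` or `datetime` column")
  }
  if (any(day < 0, na.rm = TRUE)) {
    stop("measurements dated before the trauma day")
  }
  keep <- !is.na(day) & day <= horizon_days & !is.na(raw$value)
  d <- data.frame(patient_id = raw$patient_id[keep], day = day[keep],
                  value = as.numeric(raw$value[keep]))
  if (nrow(d) == 0L) {
    return(data.frame(patient_id = character(0), day = integer(0),
                      value = numeric(0), censored_low = logical(0),
                      censored_high = logical(0)))
  }
  agg <- stats::aggregate(value ~ patient_id + day, data = d, FUN = max)
  agg <- agg[order(agg$patient_id, agg$day), ]
  out <- data.frame(patient_id = agg$patient_id, day = as.integer(agg$day),
                    value = pmin(pmax(agg$value, censor_lo), censor_hi),
                    censored_low = agg$value <= censor_lo,
                    censored_high = agg$value >= censor_hi)
  rownames(out) <- NULL
  out
}

#' Does a blocked series meet the minimum-days inclusion rule?
#'
#' @param series A blocked series for one patient (data frame with `day`),
#'   or a vector of day indices.
#' @param min_days Minimum number of distinct observation days (default 3).
#' @return `TRUE` iff the series covers at least `min_days` distinct days.
#' @export
filter_min_days <- function(series, min_days = 3) {
  days <- if (is.data.frame(series)) series$day else series
  length(unique(days)) >= min_days
}

#' KNN imputation of missing AIS profiles
#'
#' Rows with any missing AIS value are completed from their `k` nearest
#' complete rows, with distance computed as standardised Euclidean over age,
#' BMI, SOFA, ISS (when present for both rows) and a one-hot injury
#' mechanism. Each missing region score is imputed as the rounded median of
#' the neighbours' scores, clamped to 0--6, and the ISS is recomputed from
#' the completed AIS.
#'
#' @param covariates Data frame with the six `ais_*` columns plus `age`,
#'   `bmi`, `sofa`, `mechanism`, and optionally `iss`.
#' @param k Number of donor neighbours (default 5).
#' @return The completed data frame (no missing AIS), with a logical
#'   `ais_imputed` column marking imputed rows.
#' @export
impute_ais_knn <- function(covariates, k = 5) {
  ais_cols <- c("ais_head", "ais_face", "ais_chest", "ais_abdomen",
                "ais_extremities", "ais_external")
  if (!all(ais_cols %in% names(covariates))) {
    stop("covariates must contain the six ais_* columns")
  }
  incomplete <- apply(is.na(covariates[, ais_cols]), 1, any)
  out <- covariates
  out$ais_imputed <- incomplete
  if (!any(incomplete)) return(out)
  donors <- which(!incomplete)
  if (length(donors) < k) {
    stop(sprintf("need at least k = %d complete donor rows, have %d",
                 k, length(donors)))
  }
  feat <- cbind(age = covariates$age, bmi = covariates$bmi,
                sofa = covariates$sofa,
                iss = if ("iss" %in% names(covariates)) covariates$iss else NA,
                blunt = as.numeric(covariates$mechanism == "blunt"))
  mu <- colMeans(feat, na.rm = TRUE)
  sdv <- apply(feat, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(feat, 2, mu), 2, sdv, `/`)
  for (i in which(incomplete)) {
    diff2 <- sweep(Z[donors, , drop = FALSE], 2, Z[i, ])^2
    # average over features observed for both rows
    dist <- sqrt(rowMeans(diff2, na.rm = TRUE))
    dist[!is.finite(dist)] <- Inf
    nn <- donors[order(dist)[seq_len(k)]]
    for (col in ais_cols) {
      if (is.na(out[[col]][i])) {
        v <- round(stats::median(covariates[[col]][nn]))
        out[[col]][i] <- min(max(v, 0), 6)
      }
    }
    out$iss[i] <- iss_from_ais(as.numeric(out[i, ais_cols]))
  }
  out
}

#' Injury Severity Score from six region AIS values
#'
#' ISS is the sum of squares of the three highest region AIS scores; any
#' region scored 6 (unsurvivable) forces ISS = 75.
#'
#' @param ais Numeric vector of six region AIS values, each in 0--6.
#' @return Integer ISS in 0--75.
#' @export
iss_from_ais <- function(ais) {
  ais <- as.numeric(ais)
  if (length(ais) != 6L || anyNA(ais)) {
    stop("`ais` must be six non-missing region scores")
  }
  if (any(ais < 0 | ais > 6 | ais != round(ais))) {
    stop("AIS values must be integers in 0..6")
  }
  if (any(ais == 6)) return(75L)
  as.integer(sum(sort(ais, decreasing = TRUE)[1:3]^2))
}
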