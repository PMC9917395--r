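# Synthetic trauma-cohort generator with latent trajectory classes, plus the
# small fixed fixtures that encode published screening and outcome counts.

#' Default simulator configuration
#'
#' The default cohort mimics, qualitatively, the four D-dimer trajectory
#' phenotypes reported for abdominal trauma: a large "stable low" class
#' around 1.4 mg/L, a "moderate-decline" class starting near 12 mg/L, a
#' small "high-rapid decline" class (very high day 0, steep drop over the
#' first five days, slight later rise; quartic), and a small "high-gradual
#' decline" class (high early peak, decline towards day 25; quartic).
#' Mixing proportions default to (0.576, 0.282, 0.084, 0.058).
#'
#' @param n_patients Cohort size.
#' @param group_props Mixing proportions; must sum to 1 within 1e-9.
#' @param group_polys List of per-group polynomial coefficient vectors in
#'   mg/L per day^k (time in days, increasing powers).
#' @param sigma Residual SD in mg/L.
#' @param censor_lo,censor_hi Assay detection bounds in mg/L; simulated
#'   values are clipped to this interval.
#' @param horizon_days Last day that can carry an observation (day 0 is the
#'   trauma day).
#' @param obs_prob Per-day probability that a scheduled D-dimer test is
#'   actually recorded.
#' @param followup_mean Per-group mean number of follow-up days beyond the
#'   guaranteed first three; follow-up length is `3 + NegBinomial`, emulating
#'   test stopping once patients stabilise (informative stopping: classes
#'   that resolve quickly stop earlier, including the "high-rapid decline"
#'   class whose D-dimer normalises within about a week).
#' @param followup_size Dispersion (size) of the negative-binomial follow-up
#'   draw; larger values concentrate stays around the group mean.
#' @param mortality_logit Per-group intercepts of the death probability on
#'   the logit scale.
#' @param miss_ais_prob Probability that a patient's AIS profile is recorded
#'   as missing (to exercise KNN imputation).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   seed and configuration.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 400,
                       group_props = c(0.576, 0.282, 0.084, 0.058),
                       group_polys = default_group_polys(),
                       sigma = 1.8,
                       censor_lo = 0, censor_hi = 40,
                       horizon_days = 50,
                       obs_prob = 0.85,
                       followup_mean = c(8, 13, 9, 23),
                       followup_size = 8,
                       mortality_logit = stats::qlogis(c(0.0449, 0.0920,
                                                         0.0769, 0.2778)),
                       miss_ais_prob = 0.0874,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, group_props = group_props,
              group_polys = group_polys, sigma = sigma,
              censor_lo = censor_lo, censor_hi = censor_hi,
              horizon_days = horizon_days, obs_prob = obs_prob,
              followup_mean = followup_mean, followup_size = followup_size,
              mortality_logit = mortality_logit,
              miss_ais_prob = miss_ais_prob, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_group_polys <- function() {
  list(
    c(1.4, 0, 0),                                               # stable low
    c(12, -0.55, 0.0068),                                       # moderate-decline
    c(22.0763, -3.13198, 0.221346, -0.00588574, 5.17087e-05),   # high-rapid decline
    c(16.5726, 0.534613, -0.0888776, 0.00262747, -2.34106e-05)  # high-gradual decline
  )
}

validate_sim_config <- function(cfg) {
  G <- length(cfg$group_props)
  if (any(cfg$group_props < 0)) stop("group proportions must be non-negative")
  if (abs(sum(cfg$group_props) - 1) > 1e-9) {
    stop("group proportions must sum to 1 (within 1e-9)")
  }
  if (length(cfg$group_polys) != G) {
    stop("`group_polys` must have one coefficient vector per group")
  }
  if (!(cfg$sigma >= 0)) stop("`sigma` must be non-negative")
  if (!(cfg$censor_lo < cfg$censor_hi)) {
    stop("`censor_lo` must be below `censor_hi`")
  }
  if (!.is_count(cfg$horizon_days) || cfg$horizon_days < 1) {
    stop("`horizon_days` must be a positive integer")
  }
  if (length(cfg$followup_mean) != G || length(cfg$mortality_logit) != G) {
    stop("`followup_mean` and `mortality_logit` must have one entry per group")
  }
  invisible(cfg)
}

#' Generate a synthetic trauma cohort
#'
#' Draws latent group labels from the mixing proportions, simulates each
#' patient's daily-maximum D-dimer series as a group-specific polynomial in
#' day plus Normal(0, sigma^2) noise clipped to the censoring interval,
#' applies irregular sampling with group-dependent informative stopping
#' (every patient keeps at least three observed days, matching the cohort
#' inclusion rule), and draws covariates and in-hospital death from
#' group-linked models.
#'
#' @param config A [sim_config()].
#' @return A list of class `"cohort_bundle"` with `measurements` (long table:
#'   `patient_id`, `day`, `value`), `covariates` (one row per patient,
#'   including the death flag), `true_labels`, and the `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  G <- length(config$group_props)
  labels <- sample.int(G, n, replace = TRUE, prob = config$group_props)

  meas <- vector("list", n)
  for (i in seq_len(n)) {
    g <- labels[i]
    extra <- stats::rnbinom(1, size = config$followup_size,
                            mu = config$followup_mean[g])
    last_day <- min(2 + extra, config$horizon_days)
    days <- 0:last_day
    obs <- stats::runif(length(days)) < config$obs_prob
    obs[1] <- TRUE                       # admission day always tested
    if (sum(obs) < 3L) obs[seq_len(min(3L, length(days)))] <- TRUE
    days <- days[obs]
    mu <- .polyval(config$group_polys[[g]], days)
    val <- mu + stats::rnorm(length(days), 0, config$sigma)
    val <- pmin(pmax(val, config$censor_lo), config$censor_hi)
    meas[[i]] <- data.frame(patient_id = i, day = days,
                            value = round(val, 2))
  }
  measurements <- do.call(rbind, meas)

  sev <- c(0, 0.4, 1.2, 1.6)[pmin(labels, 4)]  # latent severity by class
  age <- round(pmin(pmax(stats::rnorm(n, 44, 13), 19), 90))
  male <- stats::rbinom(n, 1, 0.81)
  bmi <- round(stats::rnorm(n, 22.3, 2.6), 1)
  sofa <- pmin(stats::rpois(n, lambda = 3.5 + 1.5 * sev), 20)
  mech <- ifelse(stats::runif(n) < 0.85, "blunt", "penetrating")

  ais_abd <- pmin(pmax(round(stats::rnorm(n, 3.3 + 0.2 * sev, 0.8)), 1), 5)
  ais_head <- ifelse(stats::runif(n) < 0.28, sample(1:4, n, replace = TRUE), 0)
  ais_face <- ifelse(stats::runif(n) < 0.03, sample(1:2, n, replace = TRUE), 0)
  ais_chest <- ifelse(stats::runif(n) < 0.63, sample(1:4, n, replace = TRUE), 0)
  ais_extr <- ifelse(stats::runif(n) < 0.35, sample(1:4, n, replace = TRUE), 0)
  ais_ext <- ifelse(stats::runif(n) < 0.28, sample(1:2, n, replace = TRUE), 0)
  ais <- cbind(head = ais_head, face = ais_face, chest = ais_chest,
               abdomen = ais_abd, extremities = ais_extr, external = ais_ext)
  iss <- apply(ais, 1, iss_from_ais)

  rts <- round(pmin(pmax(7.84 - 0.55 * sev - 0.05 * sofa +
                           stats::rnorm(n, 0, 0.6), 0), 7.8408), 4)
  death <- stats::rbinom(n, 1, stats::plogis(config$mortality_logit[labels]))

  lmwh <- stats::rbinom(n, 1, stats::plogis(-1.2 + 0.8 * sev))
  ufh <- stats::rbinom(n, 1, 0.91)
  transfusion <- stats::rbinom(n, 1, stats::plogis(0.05 + 0.7 * sev))
  plasma <- stats::rbinom(n, 1, stats::plogis(0.0 + 0.6 * sev))
  cryo <- stats::rbinom(n, 1, 0.18)
  surgery <- stats::rbinom(n, 1, 0.65)
  renal <- stats::rbinom(n, 1, stats::plogis(-1.5 + 1.1 * sev))
  sepsis <- stats::rbinom(n, 1, stats::plogis(-1.3 + 0.5 * sev))
  vte <- stats::rbinom(n, 1, 0.08)

  covariates <- data.frame(
    patient_id = seq_len(n), age = age, male = male, bmi = bmi, sofa = sofa,
    ais_head = ais[, "head"], ais_face = ais[, "face"],
    ais_chest = ais[, "chest"], ais_abdomen = ais[, "abdomen"],
    ais_extremities = ais[, "extremities"], ais_external = ais[, "external"],
    iss = iss, rts = rts, mechanism = mech,
    ufh = ufh, lmwh = lmwh, transfusion = transfusion, plasma = plasma,
    cryoprecipitate = cryo, surgery = surgery,
    renal_dysfunction = renal, sepsis = sepsis, vte = vte,
    death = death
  )

  if (config$miss_ais_prob > 0) {
    miss <- stats::runif(n) < config$miss_ais_prob
    ais_cols <- c("ais_head", "ais_face", "ais_chest", "ais_abdomen",
                  "ais_extremities", "ais_external")
    covariates[miss, ais_cols] <- NA_integer_
    covariates$iss[miss] <- NA_real_
  }

  structure(list(measurements = measurements, covariates = covariates,
                 true_labels = labels, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d measurements, %d latent groups\n",
              nrow(x$covariates), nrow(x$measurements),
              length(x$config$group_props)))
  cat("  label counts:", paste(tabulate(x$true_labels,
                                        length(x$config$group_props)),
                               collapse = " / "), "\n")
  invisible(x)
}

#' Write a cohort bundle to CSV files
#'
#' Writes `measurements.csv`, `covariates.csv`, `outcomes.csv` and
#' `labels.csv`, plus the generating configuration as `config.yaml`.
#'
#' @param bundle A `"cohort_bundle"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("measurements.csv", "covariates.csv",
                            "outcomes.csv", "labels.csv", "config.yaml"))
  utils::write.csv(bundle$measurements, paths[1], row.names = FALSE)
  utils::write.csv(bundle$covariates, paths[2], row.names = FALSE)
  utils::write.csv(bundle$covariates[, c("patient_id", "death")], paths[3],
                   row.names = FALSE)
  utils::write.csv(data.frame(patient_id = bundle$covariates$patient_id,
                              true_group = bundle$true_labels), paths[4],
                   row.names = FALSE)
  cfg <- bundle$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths[5])
  invisible(paths)
}

#' Screening roster fixture reproducing the published patient flow
#'
#' Builds a deterministic roster of 913 screening records tagged so that the
#' sequential exclusion rules remove, in order: 227 patients with D-dimer
#' measured on fewer than three days, 197 re-admissions, 136 patients with a
#' trauma-to-hospitalisation interval above 14 days, 41 patients aged 18 or
#' younger, 2 cancer patients and 1 pregnant patient, leaving 309 eligible.
#' Tags are mutually exclusive, mirroring a sequential screening flow.
#'
#' @return A data frame with one row per screened patient and the fields
#'   consumed by [apply_exclusions()].
#' @export
make_flowchart_fixture <- function() {
  n <- 913
  counts <- c(few_days = 227, readmit = 197, late = 136, minor = 41,
              cancer = 2, pregnant = 1)
  tag <- rep(c(names(counts), "eligible"), c(counts, n - sum(counts)))
  data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    n_ddimer_days = ifelse(tag == "few_days", 2L, 5L),
    readmission = tag == "readmit",
    trauma_to_admission_days = ifelse(tag == "late", 21, 2),
    age = ifelse(tag == "minor", 17, 45),
    cancer = tag == "cancer",
    pregnant = tag == "pregnant"
  )
}

#' Group-by-outcome mortality fixture from the published Table 1 counts
#'
#' In-hospital deaths and totals per trajectory group:
#' 8/178, 8/87, 2/26 and 5/18 (23 deaths among 309 patients overall).
#'
#' @return A data frame with columns `group`, `deaths`, `total`, `survivors`.
#' @export
make_mortality_fixture <- function() {
  out <- data.frame(group = 1:4,
                    deaths = c(8L, 8L, 2L, 5L),
                    total = c(178L, 87L, 26L, 18L))
  out$survivors <- out$total - out$deaths
  out
}
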