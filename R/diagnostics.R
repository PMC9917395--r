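# Model-adequacy diagnostics for trajectory fits.

#' Bayesian information criterion (Nagin convention)
#'
#' `BIC = loglik - (k/2) * ln(n)`, with `n` the number of subjects. Under
#' this sign convention larger values indicate better models, so model
#' selection maximises it (equivalent to minimising the classical
#' `-2 loglik + k ln n`).
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free parameters: one coefficient per polynomial term
#'   per group, `G - 1` mixing proportions, and the residual SD.
#' @param n_subjects Number of subjects (not observations).
#' @return A single number.
#' @export
gbtm_bic <- function(loglik, k, n_subjects) {
  if (!.is_count(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be a positive integer")
  }
  loglik - (k / 2) * log(n_subjects)
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - [-sum_i sum_g p_ig ln p_ig] / (n ln G)`, with `0 ln 0 := 0`.
#' 1 means perfectly crisp assignment, 0 means uniformly uncertain.
#' A single-group model is degenerate and returns 1 by convention.
#'
#' @param posterior An `n x G` posterior-probability matrix.
#' @return A number in `[0, 1]`.
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G == 1L) return(1)
  p <- pmin(pmax(posterior, 0), 1)
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 - (-sum(plogp)) / (nrow(p) * log(G))
}

#' Average posterior probability of assignment (APPA)
#'
#' For each group, the mean posterior membership probability among the
#' patients assigned to that group. Values near 1 indicate that modal
#' assignment is a faithful summary of the posterior. An empty group yields
#' `NA` with a warning.
#'
#' @param posterior An `n x G` posterior matrix.
#' @param labels Modal assignments, as from [assign_groups()].
#' @return Numeric vector of length `G`.
#' @export
appa <- function(posterior, labels) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (length(labels) != nrow(posterior)) {
    stop("`labels` length must match posterior rows")
  }
  out <- vapply(seq_len(G), function(g) {
    in_g <- labels == g
    if (!any(in_g)) return(NA_real_)
    mean(posterior[in_g, g])
  }, numeric(1))
  if (anyNA(out)) warning("APPA undefined for empty group(s)")
  out
}

#' Fitted mean trajectory curves with observed-data bands
#'
#' Evaluates each group's latent polynomial mean on a day grid, clipped to
#' the censoring interval for display, and summarises the observed values of
#' the patients assigned to each group (per-day mean with a normal-theory
#' 95% CI).
#'
#' @param fit A `"gbtm_fit"` object.
#' @param days Integer day grid (default 0--50).
#' @return A data frame with one row per group x day: `group`, `day`,
#'   `mean_latent` (clipped), `clipped` flag, and where observed data exist
#'   `obs_mean`, `obs_lo`, `obs_hi`, `n_obs`.
#' @export
predict_mean_curves <- function(fit, days = 0:50) {
  stopifnot(inherits(fit, "gbtm_fit"))
  spec <- fit$spec
  s <- days / spec$time_scale
  out <- do.call(rbind, lapply(seq_len(spec$n_groups), function(g) {
    mu <- .polyval(fit$params$beta[[g]], s)
    clipped <- mu < spec$censor_lo | mu > spec$censor_hi
    data.frame(group = g, day = days,
               mean_latent = pmin(pmax(mu, spec$censor_lo), spec$censor_hi),
               clipped = clipped)
  }))
  out$obs_mean <- NA_real_; out$obs_lo <- NA_real_; out$obs_hi <- NA_real_
  out$n_obs <- 0L
  m <- fit$measurements
  lab <- fit$assignment[match(m$patient_id, fit$patient_ids)]
  key <- paste(lab, m$day)
  agg <- tapply(m$value, key, function(v) {
    se <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    c(mean(v), length(v), se)
  })
  hit <- match(paste(out$group, out$day), names(agg))
  ok <- !is.na(hit)
  if (any(ok)) {
    vals <- do.call(rbind, agg[hit[ok]])
    out$obs_mean[ok] <- vals[, 1]
    out$n_obs[ok] <- as.integer(vals[, 2])
    out$obs_lo[ok] <- vals[, 1] - 1.96 * vals[, 3]
    out$obs_hi[ok] <- vals[, 1] + 1.96 * vals[, 3]
  }
  out
}
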