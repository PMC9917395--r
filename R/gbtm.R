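# Censored-normal group-based trajectory model: likelihood and EM estimation.

#' Specify a censored-normal trajectory model
#'
#' A trajectory specification fixes the number of latent groups, the
#' polynomial order of each group's mean curve, the censoring interval of the
#' assay, and the time rescaling used inside the polynomials.
#'
#' @param n_groups Number of latent trajectory groups (1--6).
#' @param poly_orders Integer vector of per-group polynomial orders, each in
#'   2--4 (quadratic, cubic, quartic). Recycled to `n_groups` if scalar.
#' @param censor_lo,censor_hi Detection bounds of the assay in mg/L.
#'   Observations at a bound contribute censored-normal probability mass
#'   rather than density (Tobit treatment). Defaults 0 and 40 mg/L.
#' @param time_scale Days are divided by this constant before entering the
#'   polynomial basis, which keeps the design well conditioned over a 50-day
#'   horizon. Coefficients are reported on the scaled axis; see
#'   [coef_natural_scale()].
#'
#' @return An object of class `"trajectory_spec"`.
#' @seealso [fit_gbtm()], [mixture_loglik()]
#' @export
trajectory_spec <- function(n_groups, poly_orders = 2, censor_lo = 0,
                            censor_hi = 40, time_scale = 10) {
  if (!.is_count(n_groups) || n_groups < 1 || n_groups > 6) {
    stop("`n_groups` must be an integer between 1 and 6")
  }
  if (length(poly_orders) == 1L) poly_orders <- rep(poly_orders, n_groups)
  if (length(poly_orders) != n_groups) {
    stop("`poly_orders` must have length 1 or `n_groups`")
  }
  if (!all(poly_orders %in% 2:4)) {
    stop("polynomial orders must be 2, 3 or 4")
  }
  if (!(censor_lo < censor_hi)) stop("`censor_lo` must be below `censor_hi`")
  structure(
    list(n_groups = as.integer(n_groups),
         poly_orders = as.integer(poly_orders),
         censor_lo = censor_lo, censor_hi = censor_hi,
         time_scale = time_scale),
    class = "trajectory_spec"
  )
}

#' Log-density of the censored normal (Tobit) observation model
#'
#' Interior values contribute a normal log-density; values at the lower or
#' upper detection bound contribute the log of the corresponding tail
#' probability mass. All returns are finite (log-space evaluation with a
#' floor), so downstream mixture arithmetic never sees `-Inf`.
#'
#' @param y Observed values in `[lo, hi]` (vectorised).
#' @param mu Latent means (vectorised, recycled against `y`).
#' @param sigma Residual standard deviation, > 0.
#' @param lo,hi Censoring bounds.
#'
#' @return Numeric vector of log-densities / log-masses.
#' @export
censored_normal_logdensity <- function(y, mu, sigma, lo = 0, hi = 40) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  if (!(lo < hi)) stop("`lo` must be below `hi`")
  if (any(y < lo - 1e-9 | y > hi + 1e-9)) {
    stop("observed values must lie within [lo, hi]")
  }
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  lower <- y <= lo + 1e-9
  upper <- y >= hi - 1e-9
  .cens_ll(y, mu, sigma, lo, hi, lower, upper)
}

# Vectorised workhorse used by the fitter: censor status precomputed.
.cens_ll <- function(y, mu, sigma, lo, hi, lower, upper) {
  ll <- numeric(length(y))
  interior <- !(lower | upper)
  if (any(interior)) {
    ll[interior] <- stats::dnorm(y[interior], mu[interior], sigma, log = TRUE)
  }
  if (any(lower)) {
    ll[lower] <- stats::pnorm((lo - mu[lower]) / sigma, log.p = TRUE)
  }
  if (any(upper)) {
    ll[upper] <- stats::pnorm((hi - mu[upper]) / sigma,
                              lower.tail = FALSE, log.p = TRUE)
  }
  pmax(ll, -1e10)
}

# Bundle a long measurement table into the internal fitting structure:
# stacked observation vectors plus a patient index and a polynomial basis on
# the scaled time axis.
.gbtm_data <- function(measurements, spec) {
  need <- c("patient_id", "day", "value")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(measurements) == 0L) stop("measurement table is empty")
  pid <- factor(measurements$patient_id,
                levels = unique(measurements$patient_id))
  y <- as.numeric(measurements$value)
  if (any(!is.finite(y))) stop("non-finite measurement values")
  y <- pmin(pmax(y, spec$censor_lo), spec$censor_hi)
  s <- as.numeric(measurements$day) / spec$time_scale
  maxord <- max(spec$poly_orders)
  S <- outer(s, 0:maxord, `^`)
  lower <- y <= spec$censor_lo + 1e-9
  upper <- y >= spec$censor_hi - 1e-9
  list(y = y, idx = as.integer(pid), ids = levels(pid), n = nlevels(pid),
       N = length(y), S = S, lower = lower, upper = upper, day = measurements$day)
}

# n x G matrix of per-patient conditional log-likelihoods.
.component_loglik <- function(dat, spec, beta, sigma) {
  G <- length(beta)
  L <- matrix(0, dat$n, G)
  for (g in seq_len(G)) {
    Xg <- dat$S[, seq_len(spec$poly_orders[g] + 1L), drop = FALSE]
    mu <- drop(Xg %*% beta[[g]])
    ll <- .cens_ll(dat$y, mu, sigma, spec$censor_lo, spec$censor_hi,
                   dat$lower, dat$upper)
    L[, g] <- rowsum(ll, dat$idx)
  }
  L
}

.check_params <- function(params, spec) {
  if (!all(c("beta", "sigma", "pi") %in% names(params))) {
    stop("params must contain `beta`, `sigma` and `pi`")
  }
  if (length(params$beta) != spec$n_groups ||
      length(params$pi) != spec$n_groups) {
    stop("params dimensions do not match the trajectory spec")
  }
  lens <- vapply(params$beta, length, integer(1))
  if (!all(lens == spec$poly_orders + 1L)) {
    stop("beta lengths must equal poly_orders + 1")
  }
  if (params$sigma <= 0) stop("sigma must be positive")
  if (any(params$pi < -1e-12) || abs(sum(params$pi) - 1) > 1e-6) {
    stop("pi must be non-negative and sum to 1")
  }
  invisible(TRUE)
}

#' Total mixture log-likelihood of a trajectory model
#'
#' Computes the observed-data log-likelihood
#' \eqn{\sum_i \log \sum_g \pi_g \prod_t f(y_{it} \mid \beta_g, \sigma)}
#' of a censored-normal trajectory mixture, with the inner product over a
#' patient's occasions evaluated in log space (conditional independence given
#' group membership) and the outer sum by log-sum-exp.
#'
#' @param measurements Long table with columns `patient_id`, `day`, `value`.
#' @param spec A [trajectory_spec()].
#' @param params List with `beta` (list of per-group coefficient vectors on
#'   the scaled time axis), `sigma` (shared residual SD), `pi` (mixing
#'   proportions).
#'
#' @return A single number, the total log-likelihood.
#' @export
mixture_loglik <- function(measurements, spec, params) {
  .check_params(params, spec)
  dat <- .gbtm_data(measurements, spec)
  L <- .component_loglik(dat, spec, params$beta, params$sigma)
  A <- sweep(L, 2, log(pmax(params$pi, 1e-300)), `+`)
  sum(.row_logsumexp(A))
}

#' Posterior probabilities of group membership (PPGM)
#'
#' @inheritParams mixture_loglik
#' @return An `n x G` matrix whose rows sum to one;
#'   \eqn{p_{ig} = \pi_g L_{ig} / \sum_h \pi_h L_{ih}} computed in log space.
#' @export
posterior_probabilities <- function(measurements, spec, params) {
  .check_params(params, spec)
  dat <- .gbtm_data(measurements, spec)
  A <- sweep(.component_loglik(dat, spec, params$beta, params$sigma),
             2, log(pmax(params$pi, 1e-300)), `+`)
  W <- exp(A - .row_logsumexp(A))
  rownames(W) <- dat$ids
  W
}

#' Assign patients to their modal trajectory group
#'
#' Each patient is assigned to the group with the highest posterior
#' probability of membership; exact ties go to the lowest group index.
#'
#' @param posterior An `n x G` posterior matrix (rows sum to one).
#' @return Integer vector of group labels in `1..G`.
#' @export
assign_groups <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    stop("posterior rows must sum to 1")
  }
  max.col(posterior, ties.method = "first")
}

# ---- EM fitting ------------------------------------------------------------

# Weighted least-squares M-step update for one group's coefficients.
.wls_beta <- function(X, ystar, w) {
  fit <- stats::lm.wfit(X, ystar, pmax(w, 1e-12))
  b <- unname(fit$coefficients)
  b[is.na(b)] <- 0
  b
}

# One exact EM iteration. The complete data are (group label, latent
# uncensored value); censored observations enter the M-step through their
# conditional first and second moments under the current parameters.
.em_step <- function(dat, spec, beta, sigma, pi) {
  G <- length(beta)
  L <- .component_loglik(dat, spec, beta, sigma)
  A <- sweep(L, 2, log(pmax(pi, 1e-300)), `+`)
  lse <- .row_logsumexp(A)
  W <- exp(A - lse)
  loglik <- sum(lse)

  pi_new <- colMeans(W)
  beta_new <- vector("list", G)
  ss <- 0
  for (g in seq_len(G)) {
    Xg <- dat$S[, seq_len(spec$poly_orders[g] + 1L), drop = FALSE]
    mu <- drop(Xg %*% beta[[g]])
    ystar <- dat$y
    vadd <- numeric(dat$N)
    if (any(dat$lower)) {
      z <- (spec$censor_lo - mu[dat$lower]) / sigma
      lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
      ystar[dat$lower] <- mu[dat$lower] - sigma * lam
      vadd[dat$lower] <- pmax(sigma^2 * (1 - z * lam - lam^2), 0)
    }
    if (any(dat$upper)) {
      z <- (spec$censor_hi - mu[dat$upper]) / sigma
      h <- exp(stats::dnorm(z, log = TRUE) -
                 stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
      ystar[dat$upper] <- mu[dat$upper] + sigma * h
      vadd[dat$upper] <- pmax(sigma^2 * (1 + z * h - h^2), 0)
    }
    wg <- W[dat$idx, g]
    bg <- .wls_beta(Xg, ystar, wg)
    mu_new <- drop(Xg %*% bg)
    ss <- ss + sum(wg * ((ystar - mu_new)^2 + vadd))
    beta_new[[g]] <- bg
  }
  sigma_new <- max(sqrt(ss / dat$N), 1e-4)
  list(beta = beta_new, sigma = sigma_new, pi = pi_new,
       loglik = loglik, posterior = W)
}

# Initial parameters from a hard labelling of patients.
.init_from_labels <- function(dat, spec, labels) {
  G <- spec$n_groups
  beta <- vector("list", G)
  ss <- 0; nobs <- 0
  for (g in seq_len(G)) {
    Xg <- dat$S[, seq_len(spec$poly_orders[g] + 1L), drop = FALSE]
    wg <- as.numeric(labels[dat$idx] == g)
    if (sum(wg) < ncol(Xg)) wg <- wg + 1e-3  # tiny ridge toward pooled fit
    bg <- .wls_beta(Xg, dat$y, wg)
    beta[[g]] <- bg
    r <- dat$y - drop(Xg %*% bg)
    ss <- ss + sum(wg * r^2); nobs <- nobs + sum(wg)
  }
  pi <- tabulate(labels, G) / length(labels)
  pi <- pmax(pi, 1 / (2 * length(labels)))
  pi <- pi / sum(pi)
  list(beta = beta, sigma = max(sqrt(ss / nobs), 0.1), pi = pi)
}

# Per-patient summary features for k-means initialization: overall level,
# peak, and early slope.
.patient_features <- function(dat) {
  mn <- rowsum(dat$y, dat$idx) / tabulate(dat$idx, dat$n)
  mx <- vapply(split(dat$y, dat$idx), max, numeric(1))
  early <- dat$day <= 7
  slope <- numeric(dat$n)
  if (any(early)) {
    d <- split(dat$day[early], dat$idx[early])
    v <- split(dat$y[early], dat$idx[early])
    ids <- as.integer(names(d))
    slope[ids] <- mapply(function(dd, vv) {
      if (length(dd) < 2L || stats::var(dd) == 0) return(0)
      stats::cov(dd, vv) / stats::var(dd)
    }, d, v)
  }
  cbind(mn, mx, slope)
}

.kmeans_labels <- function(dat, G) {
  if (G == 1L) return(rep(1L, dat$n))
  f <- scale(.patient_features(dat))
  f[!is.finite(f)] <- 0
  km <- tryCatch(stats::kmeans(f, centers = G, nstart = 25, iter.max = 50),
                 error = function(e) NULL)
  if (is.null(km)) return(sample.int(G, dat$n, replace = TRUE))
  # order clusters by mean level so starts are reproducible across platforms
  ord <- order(km$centers[, 1])
  match(km$cluster, ord)
}

# Relabel groups in ascending order of mean fitted level over days 0-10,
# so that "group 1 = lowest trajectory" is stable across seeds.
.relabel_ascending <- function(spec, beta, pi, W) {
  s <- (0:10) / spec$time_scale
  lev <- vapply(seq_along(beta), function(g) {
    mu <- .polyval(beta[[g]], s)
    mean(pmin(pmax(mu, spec$censor_lo), spec$censor_hi))
  }, numeric(1))
  ord <- order(lev)
  list(beta = beta[ord], pi = pi[ord], posterior = W[, ord, drop = FALSE],
       order = ord)
}

#' Fit a censored-normal group-based trajectory model by EM
#'
#' Maximum-likelihood estimation of a finite mixture of polynomial mean
#' trajectories with a shared residual SD and censored-normal (Tobit)
#' observation model. The E-step computes posterior group memberships and the
#' conditional moments of censored observations; the M-step updates mixing
#' proportions, polynomial coefficients (weighted least squares on imputed
#' latent values) and the residual SD in closed form, so the observed-data
#' log-likelihood is non-decreasing across iterations. Several starts are
#' run for a few burn-in iterations (the first from k-means on per-patient
#' summary features, the rest perturbed or random) and the best is iterated
#' to convergence.
#'
#' After convergence the groups are relabelled in ascending order of mean
#' fitted level over days 0--10, so group 1 is always the lowest trajectory.
#'
#' @inheritParams mixture_loglik
#' @param n_starts Number of random starts (default 20).
#' @param max_iter Maximum EM iterations for the best start (default 500).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param seed Optional integer seed controlling the random starts.
#' @param burn_iter EM iterations used to triage starts before the best one
#'   is run to convergence.
#'
#' @return An object of class `"gbtm_fit"`: fitted `params` (`beta`, `sigma`,
#'   `pi`), `loglik`, the posterior matrix, modal `assignment`, `bic` (Nagin
#'   convention, larger is better), relative `entropy`, per-group `appa` and
#'   `group_props`, the parameter count `n_params`, a `converged` flag, the
#'   iteration `trace` of log-likelihoods, and the data/spec used.
#' @export
fit_gbtm <- function(measurements, spec, n_starts = 20, max_iter = 500,
                     tol = 1e-6, seed = NULL, burn_iter = 15) {
  stopifnot(inherits(spec, "trajectory_spec"))
  dat <- .gbtm_data(measurements, spec)
  if (dat$n < spec$n_groups) {
    stop("need at least as many patients as groups")
  }
  if (!is.null(seed)) set.seed(seed)
  G <- spec$n_groups

  km <- .kmeans_labels(dat, G)
  starts <- vector("list", max(1L, n_starts))
  starts[[1L]] <- km
  if (n_starts > 1L) {
    for (s in 2:n_starts) {
      if (s %% 2 == 0) {
        lab <- km
        flip <- sample.int(dat$n, max(1L, round(0.3 * dat$n)))
        lab[flip] <- sample.int(G, length(flip), replace = TRUE)
      } else {
        lab <- sample.int(G, dat$n, replace = TRUE)
      }
      starts[[s]] <- lab
    }
  }

  run_em <- function(par, iters, tol, trace = FALSE) {
    tr <- numeric(0)
    conv <- FALSE
    prev <- -Inf
    for (it in seq_len(iters)) {
      stp <- .em_step(dat, spec, par$beta, par$sigma, par$pi)
      par$beta <- stp$beta; par$sigma <- stp$sigma; par$pi <- stp$pi
      if (trace) tr <- c(tr, stp$loglik)
      if (is.finite(prev) &&
          abs(stp$loglik - prev) < tol * (abs(prev) + 1e-8)) {
        conv <- TRUE
        prev <- stp$loglik
        break
      }
      prev <- stp$loglik
    }
    list(par = par, loglik = prev, converged = conv, trace = tr)
  }

  burns <- lapply(starts, function(lab) {
    run_em(.init_from_labels(dat, spec, lab), burn_iter, tol)
  })
  # run the two most promising starts to convergence: the burn-in ranking
  # occasionally misorders basins of attraction
  top <- order(vapply(burns, `[[`, numeric(1), "loglik"),
               decreasing = TRUE)[seq_len(min(2L, length(burns)))]
  finals <- lapply(burns[top], function(b) {
    run_em(b$par, max_iter, tol, trace = TRUE)
  })
  final <- finals[[which.max(vapply(finals, `[[`, numeric(1), "loglik"))]]
  if (!final$converged) {
    warning("EM did not converge within max_iter; returning best iterate")
  }

  par <- final$par
  # prune components that have collapsed below one expected member
  keep <- par$pi >= 1 / dat$n
  if (!all(keep)) {
    warning(sprintf("pruned %d degenerate component(s) with pi < 1/n",
                    sum(!keep)))
    spec <- trajectory_spec(sum(keep), spec$poly_orders[keep],
                            spec$censor_lo, spec$censor_hi, spec$time_scale)
    par$beta <- par$beta[keep]
    par$pi <- par$pi[keep] / sum(par$pi[keep])
    final <- run_em(par, max_iter, tol, trace = TRUE)
    par <- final$par
    G <- spec$n_groups
  }

  stp <- .em_step(dat, spec, par$beta, par$sigma, par$pi)
  rel <- .relabel_ascending(spec, par$beta, par$pi, stp$posterior)
  spec$poly_orders <- spec$poly_orders[rel$order]
  W <- rel$posterior
  rownames(W) <- dat$ids
  labels <- assign_groups(W)
  k <- sum(spec$poly_orders + 1L) + (G - 1L) + 1L

  structure(list(
    params = list(beta = rel$beta, sigma = par$sigma, pi = rel$pi),
    spec = spec,
    loglik = stp$loglik,
    posterior = W,
    assignment = labels,
    patient_ids = dat$ids,
    bic = gbtm_bic(stp$loglik, k, dat$n),
    entropy = relative_entropy(W),
    appa = appa(W, labels),
    group_props = tabulate(labels, G) / dat$n,
    n_params = k,
    converged = final$converged,
    n_starts = n_starts,
    seed = seed,
    trace = final$trace,
    n_patients = dat$n,
    n_obs = dat$N,
    measurements = measurements
  ), class = "gbtm_fit")
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf("Censored-normal GBTM: %d group(s), orders (%s), n = %d patients, %d observations\n",
              x$spec$n_groups, paste(x$spec$poly_orders, collapse = ","),
              x$n_patients, x$n_obs))
  cat(sprintf("  loglik %.3f | BIC %.3f | entropy %.3f | sigma %.3f mg/L%s\n",
              x$loglik, x$bic, x$entropy, x$params$sigma,
              if (x$converged) "" else " | NOT CONVERGED"))
  tab <- data.frame(group = seq_len(x$spec$n_groups),
                    pi = round(x$params$pi, 4),
                    assigned = round(x$group_props, 4),
                    appa = round(x$appa, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Convert fitted coefficients from the scaled to the natural day axis
#'
#' Internally polynomials are evaluated on `day / time_scale`; this helper
#' reports coefficients in units of mg/L per day^k.
#'
#' @param fit A `"gbtm_fit"` object.
#' @return List of per-group coefficient vectors on the natural day scale.
#' @export
coef_natural_scale <- function(fit) {
  lapply(fit$params$beta, function(b) {
    b / fit$spec$time_scale^(seq_along(b) - 1L)
  })
}
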