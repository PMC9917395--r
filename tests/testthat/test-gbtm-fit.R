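test_that("a single uncensored group reproduces polynomial least squares", {
  set.seed(7)
  n <- 80
  days <- 0:9
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = i, day = days,
               value = 15 + 1.2 * days - 0.08 * days^2 + rnorm(10, 0, 1))
  }))
  stopifnot(all(panel$value > 0 & panel$value < 40))
  fit <- fit_gbtm(panel, trajectory_spec(1, 2), n_starts = 1, seed = 1)
  ols <- lm(value ~ I(day / 10) + I((day / 10)^2), data = panel)
  expect_equal(fit$params$beta[[1]], unname(coef(ols)), tolerance = 1e-4)
  sig_mle <- sqrt(mean(residuals(ols)^2))
  expect_equal(fit$params$sigma, sig_mle, tolerance = 1e-4)
})

test_that("a censored single-group fit matches an independent Tobit oracle", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 60
  days <- 0:7
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = i, day = days,
               value = 36 + 0.6 * days - 0.12 * days^2 + rnorm(8, 0, 3))
  }))
  panel$value <- pmin(panel$value, 40)
  expect_gt(sum(panel$value == 40), 10)
  expect_true(all(panel$value > 5))
  spec <- trajectory_spec(1, 2, censor_lo = -1000, censor_hi = 40)
  fit <- fit_gbtm(panel, spec, n_starts = 1, seed = 1, tol = 1e-9)
  s <- panel$day / 10
  tob <- survival::survreg(
    survival::Surv(value, value < 40, type = "right") ~ s + I(s^2),
    data = panel, dist = "gaussian")
  expect_equal(fit$loglik, as.numeric(logLik(tob)), tolerance = 1e-4)
  expect_equal(fit$params$beta[[1]], unname(coef(tob)), tolerance = 1e-3)
  expect_equal(fit$params$sigma, tob$scale, tolerance = 1e-3)
})

test_that("well-separated groups are recovered with crisp assignment", {
  b <- generate_cohort(two_group_config(n = 300, seed = 42))
  fit <- fit_gbtm(b$measurements, trajectory_spec(2, 2), n_starts = 5,
                  seed = 1)
  truth <- tabulate(b$true_labels, 2) / 300
  expect_lt(max(abs(fit$params$pi - truth)), 0.05)
  acc <- mean(fit$assignment[match(b$covariates$patient_id,
                                   fit$patient_ids)] == b$true_labels)
  expect_gte(acc, 0.95)
  expect_equal(fit$params$sigma, 1.5, tolerance = 0.15)
})

test_that("near-zero noise yields an essentially crisp posterior", {
  cfg <- two_group_config(n = 80, sigma = 0.1, seed = 13)
  b <- generate_cohort(cfg)
  fit <- fit_gbtm(b$measurements, trajectory_spec(2, 2), n_starts = 3,
                  seed = 2)
  expect_gte(fit$entropy, 0.99)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  b <- generate_cohort(sim_config(n_patients = 150, seed = 23))
  fit <- fit_gbtm(b$measurements, trajectory_spec(4, c(2, 2, 4, 4)),
                  n_starts = 3, seed = 3)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_true(fit$converged)
})

test_that("groups are relabelled in ascending order of early level", {
  b <- generate_cohort(two_group_config(n = 150, seed = 31))
  fit <- fit_gbtm(b$measurements, trajectory_spec(2, 2), n_starts = 3,
                  seed = 5)
  expect_lt(fit$params$beta[[1]][1], fit$params$beta[[2]][1])
})

test_that("hitting the iteration cap flags non-convergence with a warning", {
  b <- generate_cohort(sim_config(n_patients = 100, seed = 17))
  expect_warning(
    fit <- fit_gbtm(b$measurements, trajectory_spec(3, 2), n_starts = 1,
                    max_iter = 1, burn_iter = 1, seed = 4),
    "converge")
  expect_false(fit$converged)
})

test_that("overfitting a one-group cohort still yields a coherent mixture", {
  cfg <- sim_config(n_patients = 60, group_props = 1,
                    group_polys = list(c(8, 0, 0)), sigma = 1,
                    followup_mean = 8, mortality_logit = -2,
                    miss_ais_prob = 0, seed = 17)
  b <- generate_cohort(cfg)
  fit <- suppressWarnings(fit_gbtm(b$measurements, trajectory_spec(3, 2),
                                   n_starts = 2, seed = 4))
  expect_lte(fit$spec$n_groups, 3)
  expect_equal(rowSums(fit$posterior), rep(1, 60), ignore_attr = TRUE,
               tolerance = 1e-8)
  # all surviving components describe essentially the same flat curve
  lv <- vapply(fit$params$beta, function(b) b[1], numeric(1))
  expect_lt(max(lv) - min(lv), 1.5)
})

test_that("fitted curves report a clipped 51-point day grid", {
  b <- generate_cohort(two_group_config(n = 60, seed = 19))
  fit <- fit_gbtm(b$measurements, trajectory_spec(2, 2), n_starts = 2,
                  seed = 6)
  curves <- predict_mean_curves(fit)
  expect_equal(nrow(curves), 2 * 51)
  expect_true(all(curves$mean_latent >= 0 & curves$mean_latent <= 40))
  # observed-band summaries exist where the group has data
  expect_true(any(is.finite(curves$obs_mean)))
})
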