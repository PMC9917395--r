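test_that("censored-normal log-density matches closed forms and the CDF oracle", {
  # mass at the upper bound with mu at the bound: half the distribution
  expect_equal(censored_normal_logdensity(40, 40, 1), log(0.5),
               tolerance = 1e-12)
  # interior mode of the standard normal
  expect_equal(censored_normal_logdensity(5, 5, 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # mass at the lower bound equals the normal CDF there
  expect_equal(censored_normal_logdensity(0, 2, 1),
               pnorm(0, 2, 1, log.p = TRUE), tolerance = 1e-12)
  expect_error(censored_normal_logdensity(1, 0, 0), "sigma")
  expect_error(censored_normal_logdensity(45, 0, 1), "within")
  # finite even in extreme tails
  expect_true(is.finite(censored_normal_logdensity(0, 39, 0.5)))
})

test_that("mixture log-likelihood matches a brute-force nested-loop oracle", {
  panel <- tiny_panel()
  spec <- trajectory_spec(2, 2)
  params <- tiny_params()
  expect_equal(mixture_loglik(panel, spec, params),
               brute_force_loglik(panel, spec, params), tolerance = 1e-10)
})

test_that("single-group and duplicated-group mixtures reduce correctly", {
  panel <- tiny_panel()
  spec1 <- trajectory_spec(1, 2)
  p1 <- list(beta = list(c(4, -0.5, 0.1)), sigma = 1.5, pi = 1)
  ll1 <- mixture_loglik(panel, spec1, p1)
  # direct sum of per-observation censored log-densities
  s <- panel$day / 10
  mu <- 4 - 0.5 * s + 0.1 * s^2
  expect_equal(ll1, sum(censored_normal_logdensity(panel$value, mu, 1.5)),
               tolerance = 1e-12)
  # duplicating the component with split weights changes nothing
  spec2 <- trajectory_spec(2, 2)
  p2 <- list(beta = list(c(4, -0.5, 0.1), c(4, -0.5, 0.1)), sigma = 1.5,
             pi = c(0.5, 0.5))
  expect_equal(mixture_loglik(panel, spec2, p2), ll1, tolerance = 1e-10)
})

test_that("log-likelihood is invariant under group relabelling", {
  panel <- tiny_panel()
  spec <- trajectory_spec(2, 2)
  params <- tiny_params()
  flipped <- list(beta = params$beta[2:1], sigma = params$sigma,
                  pi = params$pi[2:1])
  expect_equal(mixture_loglik(panel, spec, params),
               mixture_loglik(panel, spec, flipped), tolerance = 1e-12)
})

test_that("with remote bounds the censored likelihood equals the plain normal one", {
  set.seed(4)
  panel <- data.frame(patient_id = rep(1:5, each = 4),
                      day = rep(0:3, 5),
                      value = rnorm(20, 10, 2))
  spec <- trajectory_spec(2, 2, censor_lo = -1e6, censor_hi = 1e6)
  params <- tiny_params()
  s <- panel$day / 10
  dens <- vapply(1:2, function(g) {
    mu <- params$beta[[g]][1] + params$beta[[g]][2] * s +
      params$beta[[g]][3] * s^2
    tapply(dnorm(panel$value, mu, params$sigma, log = TRUE),
           panel$patient_id, sum)
  }, numeric(5))
  plain <- sum(log(exp(dens) %*% params$pi))
  expect_equal(mixture_loglik(panel, spec, params), plain, tolerance = 1e-8)
})

test_that("posterior probabilities normalise and collapse correctly", {
  panel <- tiny_panel()
  spec <- trajectory_spec(2, 2)
  params <- tiny_params()
  W <- posterior_probabilities(panel, spec, params)
  expect_equal(rowSums(W), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-8)

  # identical components: every row equals the mixing proportions
  same <- list(beta = list(c(4, 0, 0), c(4, 0, 0)), sigma = 1,
               pi = c(0.3, 0.7))
  Ws <- posterior_probabilities(panel, spec, same)
  expect_equal(unname(Ws), matrix(c(0.3, 0.7), 3, 2, byrow = TRUE),
               tolerance = 1e-10)

  # one group: all ones
  W1 <- posterior_probabilities(panel, trajectory_spec(1, 2),
                                list(beta = list(c(4, 0, 0)), sigma = 1,
                                     pi = 1))
  expect_equal(unname(W1), matrix(1, 3, 1))

  # hand log-space oracle on a two-patient panel
  two <- panel[panel$patient_id %in% c("a", "b"), ]
  W2 <- posterior_probabilities(two, spec, params)
  for (id in c("a", "b")) {
    rows <- two[two$patient_id == id, ]
    lg <- vapply(1:2, function(g) {
      s <- rows$day / 10
      mu <- params$beta[[g]][1] + params$beta[[g]][2] * s +
        params$beta[[g]][3] * s^2
      sum(censored_normal_logdensity(rows$value, mu, params$sigma)) +
        log(params$pi[g])
    }, numeric(1))
    expect_equal(W2[id, ], exp(lg - max(lg)) / sum(exp(lg - max(lg))),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("modal assignment breaks ties toward the lowest group", {
  expect_equal(assign_groups(rbind(c(0.1, 0.9), c(0.5, 0.5))), c(2L, 1L))
  expect_error(assign_groups(rbind(c(0.4, 0.4))), "sum to 1")
})
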