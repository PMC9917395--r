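# Shared fixtures built in code: small cohorts with known latent structure.

# two flat, well-separated trajectory classes
two_group_config <- function(n = 300, means = c(2, 12), sigma = 1.5,
                             props = c(0.5, 0.5), seed = 42) {
  sim_config(n_patients = n, group_props = props,
             group_polys = list(c(means[1], 0, 0), c(means[2], 0, 0)),
             sigma = sigma, followup_mean = c(10, 10),
             mortality_logit = c(-2.5, -1.5), miss_ais_prob = 0, seed = seed)
}

# pronounced quartic shapes for groups 3-4: used by shape-recovery tests
strong_shape_config <- function(n = 300, seed = 1) {
  sim_config(n_patients = n, group_props = c(0.4, 0.3, 0.15, 0.15),
             group_polys = list(
               c(1.4, 0, 0),
               c(12, -0.55, 0.0068),
               c(32, -7.22016, 0.610568, -0.0181692, 0.000172439),
               c(20, 3.03031, -0.444371, 0.0161361, -0.000171936)),
             sigma = 1.5, followup_mean = c(12, 14, 18, 22),
             mortality_logit = rep(-2, 4), miss_ais_prob = 0, seed = seed)
}

# tiny deterministic panel for likelihood oracles
tiny_panel <- function() {
  data.frame(
    patient_id = rep(c("a", "b", "c"), times = c(4, 3, 4)),
    day = c(0, 1, 2, 3, 0, 2, 4, 0, 1, 3, 5),
    value = c(1.2, 0.0, 3.5, 40.0, 12.1, 9.8, 7.7, 0.4, 2.2, 40.0, 5.0)
  )
}

tiny_params <- function() {
  list(beta = list(c(2, -0.5, 0.1), c(10, -1, 0.05)),
       sigma = 2, pi = c(0.6, 0.4))
}

# independent nested-loop evaluation of the mixture log-likelihood
brute_force_loglik <- function(measurements, spec, params) {
  total <- 0
  for (id in unique(measurements$patient_id)) {
    rows <- measurements[measurements$patient_id == id, ]
    li <- 0
    for (g in seq_along(params$beta)) {
      lg <- 1
      for (r in seq_len(nrow(rows))) {
        s <- rows$day[r] / spec$time_scale
        mu <- sum(params$beta[[g]] * s^(seq_along(params$beta[[g]]) - 1))
        y <- rows$value[r]
        f <- if (y <= spec$censor_lo) {
          pnorm(spec$censor_lo, mu, params$sigma)
        } else if (y >= spec$censor_hi) {
          pnorm(spec$censor_hi, mu, params$sigma, lower.tail = FALSE)
        } else {
          dnorm(y, mu, params$sigma)
        }
        lg <- lg * f
      }
      li <- li + params$pi[g] * lg
    }
    total <- total + log(li)
  }
  total
}
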