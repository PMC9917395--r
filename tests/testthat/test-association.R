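# expand a group-by-outcome count table into per-patient vectors
expand_fixture <- function(fx = make_mortality_fixture()) {
  list(group = rep(fx$group, fx$total),
       death = unlist(lapply(seq_len(nrow(fx)), function(i) {
         rep(c(1, 0), c(fx$deaths[i], fx$survivors[i]))
       })))
}

test_that("2x2 odds ratios reproduce the published univariate associations", {
  fx <- make_mortality_fixture()
  ref <- fx[fx$group == 1, ]
  g4 <- odds_ratio_2x2(fx$deaths[4], fx$survivors[4], ref$deaths,
                       ref$survivors)
  expect_equal(g4$or, 8.17, tolerance = 0.005)
  expect_equal(g4$ci, c(2.34, 28.57), tolerance = 0.005)
  g2 <- odds_ratio_2x2(fx$deaths[2], fx$survivors[2], ref$deaths,
                       ref$survivors)
  expect_equal(g2$or, 2.15, tolerance = 0.005)
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or, 1)
})

test_that("odds ratios are reciprocal under exposure swap and guard degenerate tables", {
  a <- odds_ratio_2x2(5, 13, 8, 170)
  b <- odds_ratio_2x2(8, 170, 5, 13)
  expect_equal(a$or * b$or, 1, tolerance = 1e-12)
  expect_true(odds_ratio_2x2(0, 10, 5, 5)$corrected)
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "margin")
})

test_that("univariate screening keeps real signals and has near-nominal size", {
  set.seed(101)
  # a covariate identical to the outcome is retained with p ~ 0
  y <- rbinom(400, 1, 0.3)
  scr <- univariate_screen(data.frame(dup = y), y)
  expect_true(scr$keep[1])
  expect_lt(scr$p[1], 1e-10)

  # null covariates are excluded at roughly the screening level
  kept <- vapply(1:80, function(i) {
    x <- rnorm(500)
    univariate_screen(data.frame(x = x), rbinom(500, 1, 0.15))$keep
  }, logical(1))
  expect_gte(mean(!kept), 0.8)
  expect_lte(mean(!kept), 0.98)

  expect_warning(out <- univariate_screen(data.frame(k = rep(1, 10)),
                                          rep(0:1, 5)), "constant")
  expect_false(out$keep)
})

test_that("collinearity screening drops duplicates and keeps orthogonal designs", {
  set.seed(7)
  x <- rnorm(200)
  dup <- data.frame(a = x, b = x, c = rnorm(200))
  res <- collinearity_screen(dup, univariate_p = c(a = 0.01, b = 0.05,
                                                   c = 0.2))
  expect_false("b" %in% res$retained)   # larger univariate p loses
  expect_true(all(c("a", "c") %in% res$retained))

  ortho <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  res2 <- collinearity_screen(ortho)
  expect_equal(sort(res2$retained), c("a", "b", "c"))
  expect_true(all(res2$vif < 10))
})

test_that("internal VIFs agree with the car oracle", {
  skip_if_not_installed("car")
  set.seed(12)
  X <- data.frame(a = rnorm(150), b = rnorm(150))
  X$c <- 0.7 * X$a + rnorm(150, 0, 0.5)
  y <- rnorm(150)
  ours <- ddtraj:::.vif(as.matrix(X))
  theirs <- unname(car::vif(lm(y ~ a + b + c, data = X)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("an adjuster-free multivariable model reproduces contingency odds ratios", {
  d <- expand_fixture()
  mv <- fit_multivariable(d$death, d$group)
  fx <- make_mortality_fixture()
  for (g in 2:4) {
    ct <- odds_ratio_2x2(fx$deaths[g], fx$survivors[g], fx$deaths[1],
                         fx$survivors[1])
    expect_equal(mv$table$or[g - 1], ct$or, tolerance = 1e-6)
  }
})

test_that("an irrelevant adjuster barely moves the group odds ratios", {
  set.seed(33)
  d <- expand_fixture()
  noise <- data.frame(z = rnorm(length(d$death)))
  mv0 <- fit_multivariable(d$death, d$group)
  mv1 <- fit_multivariable(d$death, d$group, noise)
  ors1 <- mv1$table$or[startsWith(mv1$table$term, "group")]
  expect_equal(ors1, mv0$table$or, tolerance = 0.15)
  expect_error(fit_multivariable(rep(0, 100), rep(1:2, 50)), "single-class")
})

test_that("the AIS-to-ISS sensitivity swap refits with the exchanged covariate", {
  set.seed(44)
  n <- 300
  grp <- sample(1:2, n, TRUE)
  adj <- data.frame(ais_abdomen = sample(1:5, n, TRUE), bmi = rnorm(n, 22))
  y <- rbinom(n, 1, plogis(-2 + 0.5 * (grp == 2)))
  # swapping in a duplicate of the removed column leaves the fit unchanged
  same <- sensitivity_swap(y, grp, adj, "ais_abdomen",
                           data.frame(iss = adj$ais_abdomen))
  expect_equal(sort(same$primary$table$or), sort(same$sensitivity$table$or),
               tolerance = 1e-8)
  grp_terms <- startsWith(same$primary$table$term, "group")
  expect_equal(same$primary$table$or[grp_terms],
               same$sensitivity$table$or[grp_terms], tolerance = 1e-8)
  expect_error(sensitivity_swap(y, grp, adj, "iss",
                                data.frame(iss = rnorm(n))), "not among")
})

test_that("rank AUC matches exhaustive pair counting and is monotone-invariant", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_auc(scores, labels), 0.75)

  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(5)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, 0.05), 30, TRUE)  # coarse grid forces ties
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(qlogis(pmin(pmax(s, 0.01), 0.99)), y),
                 roc_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), rep(0:1, 3)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "non-event")
})

test_that("rank AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(120)
  y <- rbinom(120, 1, plogis(s))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("group comparison reproduces fixture mortality percentages with BH pairwise", {
  d <- expand_fixture()
  out <- group_comparison_table(data.frame(death = d$death), d$group)
  row <- out$table[out$table$variable == "death", ]
  expect_equal(unname(unlist(row[paste0("group_", 1:4)])),
               c("8 (4.49)", "8 (9.20)", "2 (7.69)", "5 (27.78)"))
  expect_lt(row$p, 0.05)
  pw <- out$pairwise$death
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
})

test_that("BH adjustment is monotone and never below the raw p-values", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:10) {
    p <- runif(12)
    adj <- p.adjust(p, method = "BH")
    expect_true(all(adj >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
})

test_that("continuous variables are compared by Kruskal-Wallis with null-uniform p", {
  set.seed(55)
  ps <- vapply(1:60, function(i) {
    x <- rnorm(120)
    g <- rep(1:3, each = 40)
    group_comparison_table(data.frame(x = x), g)$table$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
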