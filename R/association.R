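# Trajectory-group / mortality association: univariate screening,
# collinearity diagnostics, logistic models, contingency odds ratios, AUC,
# and group-comparison tables.

.is_continuous <- function(x) {
  is.numeric(x) && length(unique(x[!is.na(x)])) > 5L
}

# chi-square unless any expected cell is below 5, then Fisher.
.cat_test <- function(tab) {
  suppressWarnings({
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_cells < 5)) {
      list(p = stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                                  B = 1e4)$p.value, test = "fisher")
    } else {
      list(p = stats::chisq.test(tab, correct = FALSE)$p.value, test = "chisq")
    }
  })
}

#' Univariate screening of baseline covariates against a binary outcome
#'
#' Continuous covariates are tested by single-predictor logistic regression
#' (Wald p-value); categorical covariates by chi-square, or Fisher's exact
#' test when any expected cell count is below 5. Covariates with p below
#' `alpha` are retained as candidates for the multivariable model; constant
#' covariates are excluded with a warning.
#'
#' @param covariates Data frame of candidate covariates.
#' @param outcome Binary 0/1 vector.
#' @param alpha Screening level (default 0.1).
#' @return Data frame with `variable`, `type`, `test`, `p`, `keep`.
#' @export
univariate_screen <- function(covariates, outcome, alpha = 0.1) {
  stopifnot(is.data.frame(covariates), length(outcome) == nrow(covariates))
  outcome <- as.integer(outcome)
  if (!all(outcome %in% 0:1)) stop("`outcome` must be binary 0/1")
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning(sprintf("covariate `%s` is constant; excluded", v))
      return(data.frame(variable = v, type = "constant", test = NA_character_,
                        p = NA_real_, keep = FALSE))
    }
    if (.is_continuous(x)) {
      fit <- stats::glm(outcome ~ x, family = stats::binomial())
      p <- summary(fit)$coefficients[2, 4]
      data.frame(variable = v, type = "continuous", test = "logistic_wald",
                 p = p, keep = p < alpha)
    } else {
      tt <- .cat_test(table(x, outcome))
      data.frame(variable = v, type = "categorical", test = tt$test,
                 p = tt$p, keep = tt$p < alpha)
    }
  })
  do.call(rbind, rows)
}

# Variance inflation factors from the R^2 of each column on the others.
.vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((X[, j] - mean(X[, j]))^2), 1e-300)
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
}

#' Collinearity screening of candidate covariates
#'
#' Computes variance inflation factors on the candidate design and pairwise
#' Spearman rank correlations. Pairs with |r| > `r_max` and correlation-test
#' p < 0.05, and variables with VIF at or above `vif_max`, are flagged; from
#' each flagged pair the variable with the larger univariate p-value is
#' dropped (the drop is logged in the report), iterating until the design is
#' clean.
#'
#' @param candidates Data frame of numeric candidate covariates.
#' @param univariate_p Optional named vector of univariate p-values used to
#'   break pairs (smaller p wins); defaults to keeping the earlier column.
#' @param vif_max VIF threshold (default 10).
#' @param r_max Absolute correlation threshold (default 0.5).
#' @return List with `retained` (column names), `dropped` (data frame of
#'   drops with reasons), `vif` (final VIFs) and `correlations` (flagged
#'   pairs at entry).
#' @export
collinearity_screen <- function(candidates, univariate_p = NULL,
                                vif_max = 10, r_max = 0.5) {
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 1)
  X <- as.data.frame(lapply(seq_along(candidates), function(j) {
    x <- candidates[[j]]
    if (is.numeric(x)) x else as.numeric(as.factor(x))
  }))
  names(X) <- names(candidates)
  pv <- function(v) {
    if (!is.null(univariate_p) && v %in% names(univariate_p)) {
      univariate_p[[v]]
    } else {
      match(v, names(candidates)) / 1e6  # stable fallback: earlier wins
    }
  }
  dropped <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  flagged_pairs <- NULL
  repeat {
    if (ncol(X) < 2L) break
    cors <- suppressWarnings(stats::cor(X, method = "spearman",
                                        use = "pairwise.complete.obs"))
    n <- nrow(X)
    worst <- NULL
    for (a in seq_len(ncol(X) - 1L)) {
      for (b in (a + 1L):ncol(X)) {
        r <- cors[a, b]
        if (!is.finite(r) || abs(r) <= r_max) next
        ct <- suppressWarnings(
          stats::cor.test(X[[a]], X[[b]], method = "spearman", exact = FALSE))
        if (ct$p.value < 0.05) {
          if (is.null(flagged_pairs)) {
            flagged_pairs <- data.frame(var1 = character(0),
                                        var2 = character(0), r = numeric(0))
          }
          flagged_pairs <- rbind(flagged_pairs,
                                 data.frame(var1 = names(X)[a],
                                            var2 = names(X)[b], r = r))
          if (is.null(worst) || abs(r) > abs(worst$r)) {
            worst <- list(a = names(X)[a], b = names(X)[b], r = r)
          }
        }
      }
    }
    vifs <- .vif(X)
    names(vifs) <- names(X)
    if (is.null(worst) && all(vifs < vif_max)) break
    if (!is.null(worst)) {
      drop <- if (pv(worst$a) > pv(worst$b)) worst$a else worst$b
      reason <- sprintf("|r| = %.3f with %s", abs(worst$r),
                        setdiff(c(worst$a, worst$b), drop))
    } else {
      drop <- names(which.max(vifs))
      reason <- sprintf("VIF = %.1f", max(vifs))
    }
    dropped <- rbind(dropped, data.frame(variable = drop, reason = reason))
    X <- X[, setdiff(names(X), drop), drop = FALSE]
  }
  final_vif <- if (ncol(X) >= 2L) {
    v <- .vif(X); names(v) <- names(X); v
  } else {
    stats::setNames(rep(1, ncol(X)), names(X))
  }
  list(retained = names(X), dropped = dropped, vif = final_vif,
       correlations = flagged_pairs)
}

#' Odds ratio from a 2x2 contingency table with a Wald interval
#'
#' `OR = (a d) / (b c)`; 95% CI on the log scale with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`; p-value from the Wald z statistic. A zero
#' cell triggers the 0.5 continuity correction (flagged).
#'
#' @param a,b Events and non-events among the exposed.
#' @param c,d Events and non-events among the reference.
#' @return List with `or`, `ci` (length 2), `p`, `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("a margin of the 2x2 table is empty")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  list(or = unname(or),
       ci = unname(exp(log(or) + c(-1, 1) * 1.96 * se)),
       p = unname(2 * stats::pnorm(-abs(z))),
       corrected = corrected)
}

#' Multivariable logistic model of death on trajectory group
#'
#' Fits `outcome ~ group + adjusters` by maximum likelihood with group 1 as
#' the reference level, returning Wald odds ratios, 95% CIs and p-values per
#' non-reference group and per adjuster. Quasi-separation (any |coef| > 10
#' on the logit scale or non-convergence) is flagged: the CIs are then
#' unreliable.
#'
#' @param outcome Binary 0/1 vector.
#' @param group Group labels (coerced to factor; level 1 = reference).
#' @param adjusters Optional data frame of adjustment covariates.
#' @return List with `table` (term, or, ci_lo, ci_hi, p), the fitted `model`,
#'   and `separation` flag.
#' @export
fit_multivariable <- function(outcome, group, adjusters = NULL) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% 0:1)) stop("`outcome` must be binary 0/1")
  if (length(unique(outcome)) < 2L) {
    stop("outcome is single-class; logistic model is degenerate")
  }
  df <- data.frame(.y = outcome, .group = factor(group))
  if (!is.null(adjusters)) {
    stopifnot(nrow(adjusters) == length(outcome))
    df <- cbind(df, adjusters)
  }
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  cf <- summary(fit)$coefficients
  terms <- rownames(cf)[-1]
  sep <- !fit$converged || any(abs(cf[-1, 1]) > 10)
  if (sep) warning("possible separation: Wald CIs unreliable")
  tab <- data.frame(
    term = sub("^\\.group", "group ", terms),
    or = exp(cf[-1, 1]),
    ci_lo = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
    ci_hi = exp(cf[-1, 1] + 1.96 * cf[-1, 2]),
    p = cf[-1, 4], row.names = NULL)
  list(table = tab, model = fit, separation = sep)
}

#' Sensitivity analysis: swap one adjuster for another and refit
#'
#' Refits the multivariable model with `swap_out` replaced by `swap_in`
#' (typically abdominal AIS swapped for ISS) and reports both models side by
#' side.
#'
#' @inheritParams fit_multivariable
#' @param adjusters Data frame containing `swap_out`.
#' @param swap_out,swap_in Column name to remove and data frame (or named
#'   list) with the single column to add.
#' @return List with `primary` and `sensitivity` model results.
#' @export
sensitivity_swap <- function(outcome, group, adjusters, swap_out, swap_in) {
  if (!swap_out %in% names(adjusters)) {
    stop(sprintf("`%s` is not among the adjusters", swap_out))
  }
  swap_in <- as.data.frame(swap_in)
  if (ncol(swap_in) != 1L) stop("`swap_in` must supply exactly one column")
  primary <- fit_multivariable(outcome, group, adjusters)
  alt <- adjusters[, setdiff(names(adjusters), swap_out), drop = FALSE]
  alt <- cbind(alt, swap_in)
  sensitivity <- fit_multivariable(outcome, group, alt)
  list(primary = primary, sensitivity = sensitivity)
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes the AUC as the Mann-Whitney probability that a random event
#' outranks a random non-event, with ties receiving half credit; this equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric predictions (higher = more likely event).
#' @param outcome Binary 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one event and one non-event")
  r <- rank(scores)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group-comparison summary table with omnibus and pairwise tests
#'
#' Continuous variables are summarised as median (IQR) per group and
#' compared by Kruskal-Wallis (normality is assessed by Shapiro-Wilk and
#' reported); categorical variables as n (%) with chi-square, or Fisher's
#' exact test when any expected cell is below 5. For variables with a
#' significant omnibus test (p < 0.05), pairwise comparisons (Wilcoxon for
#' continuous, 2x2 chi-square/Fisher for categorical) are adjusted by the
#' Benjamini-Hochberg method.
#'
#' @param covariates Data frame of variables to compare.
#' @param labels Group labels.
#' @return List with `table` (one row per variable: per-group summaries,
#'   omnibus p, test used, Shapiro p where applicable) and `pairwise`
#'   (BH-adjusted pairwise p-values for significant variables).
#' @export
group_comparison_table <- function(covariates, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  empty <- table(labels) == 0
  if (any(empty)) {
    warning("empty group level(s) dropped: ",
            paste(names(which(empty)), collapse = ", "))
    labels <- droplevels(labels)
  }
  groups <- levels(labels)
  rows <- list(); pairwise <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    if (.is_continuous(x)) {
      summ <- vapply(groups, function(g) {
        q <- stats::quantile(x[labels == g], c(0.5, 0.25, 0.75), na.rm = TRUE)
        sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3])
      }, character(1))
      kw <- stats::kruskal.test(x, labels)
      sw <- tryCatch(stats::shapiro.test(
        x[!is.na(x)][seq_len(min(5000, sum(!is.na(x))))])$p.value,
        error = function(e) NA_real_)
      p <- kw$p.value; test <- "kruskal-wallis"
      if (!is.na(p) && p < 0.05) {
        pw <- utils::combn(groups, 2, function(pr) {
          stats::wilcox.test(x[labels == pr[1]], x[labels == pr[2]],
                             exact = FALSE)$p.value
        })
        pairwise[[v]] <- data.frame(
          t(utils::combn(groups, 2)),
          p_adj = stats::p.adjust(pw, method = "BH"))
        names(pairwise[[v]])[1:2] <- c("group_a", "group_b")
      }
    } else {
      tab <- table(factor(x), labels)
      summ <- vapply(groups, function(g) {
        n_g <- sum(labels == g)
        pos <- if (nrow(tab) == 2L) tab[2, g] else NA
        if (is.na(pos)) sprintf("n = %d", n_g)
        else sprintf("%d (%.2f)", pos, 100 * pos / n_g)
      }, character(1))
      tt <- .cat_test(tab)
      p <- tt$p; test <- tt$test; sw <- NA_real_
      if (!is.na(p) && p < 0.05) {
        pw <- utils::combn(groups, 2, function(pr) {
          .cat_test(table(factor(x[labels %in% pr]),
                          droplevels(labels[labels %in% pr])))$p
        })
        pairwise[[v]] <- data.frame(
          t(utils::combn(groups, 2)),
          p_adj = stats::p.adjust(pw, method = "BH"))
        names(pairwise[[v]])[1:2] <- c("group_a", "group_b")
      }
    }
    row <- data.frame(variable = v, t(summ), p = p, test = test,
                      shapiro_p = sw, row.names = NULL)
    names(row)[2:(1 + length(groups))] <- paste0("group_", groups)
    rows[[v]] <- row
  }
  list(table = do.call(rbind, rows), pairwise = pairwise)
}
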