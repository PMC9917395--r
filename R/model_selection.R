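# Two-stage trajectory model selection: number of groups first (all
# quadratic), then per-group polynomial orders under adequacy constraints.

.fit_diag_row <- function(fit) {
  data.frame(loglik = fit$loglik, bic = fit$bic, entropy = fit$entropy,
             min_prop = min(fit$group_props),
             min_appa = suppressWarnings(min(fit$appa)),
             converged = fit$converged)
}

#' Adequacy criteria for a trajectory fit
#'
#' Checks the three classification-adequacy criteria used alongside BIC:
#' relative entropy at least `entropy_min`, every assigned group holding at
#' least `prop_min` of patients, and every group's APPA at least `appa_min`.
#'
#' @param fit A `"gbtm_fit"`.
#' @param entropy_min,prop_min,appa_min Thresholds (defaults 0.9, 0.05, 0.7).
#' @return Named logical vector `entropy_ok`, `proportion_ok`, `appa_ok`,
#'   `all_ok`.
#' @export
adequacy_check <- function(fit, entropy_min = 0.9, prop_min = 0.05,
                           appa_min = 0.7) {
  stopifnot(inherits(fit, "gbtm_fit"))
  appa_vals <- suppressWarnings(fit$appa)
  out <- c(entropy_ok = fit$entropy >= entropy_min,
           proportion_ok = min(fit$group_props) >= prop_min,
           appa_ok = !anyNA(appa_vals) && min(appa_vals) >= appa_min)
  c(out, all_ok = all(out))
}

#' Stage 1: choose the number of trajectory groups
#'
#' Fits all-quadratic models with 1 to `max_groups` groups and selects the
#' number of groups by BIC (Nagin convention, maximised), with a parsimony
#' margin: the smallest number of groups whose BIC is within
#' `parsimony_margin` of the maximum is preferred. Non-converged fits are
#' retried once with double the starts.
#'
#' @inheritParams fit_gbtm
#' @param max_groups Largest number of groups to consider (default 6).
#' @param parsimony_margin BIC margin within which a smaller model is
#'   preferred (default 2).
#' @param censor_lo,censor_hi,time_scale Passed to [trajectory_spec()].
#' @return List with `best_G`, the diagnostics `table` (one row per G),
#'   and `fits` (the fitted models).
#' @export
stage1_select_groups <- function(measurements, max_groups = 6, n_starts = 5,
                                 parsimony_margin = 2, seed = NULL,
                                 censor_lo = 0, censor_hi = 40,
                                 time_scale = 10, max_iter = 500,
                                 tol = 1e-6) {
  fits <- vector("list", max_groups)
  rows <- vector("list", max_groups)
  for (G in seq_len(max_groups)) {
    sp <- trajectory_spec(G, 2, censor_lo, censor_hi, time_scale)
    sd_g <- if (is.null(seed)) NULL else seed + G
    fit <- fit_gbtm(measurements, sp, n_starts = n_starts,
                    max_iter = max_iter, tol = tol, seed = sd_g)
    if (!fit$converged) {
      fit <- fit_gbtm(measurements, sp, n_starts = 2 * n_starts,
                      max_iter = 2 * max_iter, tol = tol,
                      seed = if (is.null(sd_g)) NULL else sd_g + 1000)
    }
    fits[[G]] <- fit
    rows[[G]] <- cbind(data.frame(G = G), .fit_diag_row(fit))
  }
  tab <- do.call(rbind, rows)
  best_bic <- max(tab$bic)
  best_G <- min(tab$G[tab$bic >= best_bic - parsimony_margin])
  list(best_G = best_G, table = tab, fits = fits)
}

#' Stage 2: choose the polynomial order of each group
#'
#' Enumerates the order combinations in `{2,3,4}^G`. Combinations that are
#' permutations of one another describe the same model up to group
#' relabelling (and fitted groups are always relabelled by level), so one
#' representative per order multiset is fitted and its diagnostics shared
#' across the permuted rows. Among combinations passing all three adequacy
#' criteria the best-BIC one is selected; if none passes, the best-BIC
#' combination overall is returned with a warning.
#'
#' @inheritParams stage1_select_groups
#' @param G Number of groups, usually from [stage1_select_groups()].
#' @param mode `"exhaustive"` (default) or `"greedy"`, which starts from the
#'   all-quadratic model and upgrades one group's order at a time while BIC
#'   improves.
#' @param entropy_min,prop_min,appa_min Adequacy thresholds.
#' @return List with `best_spec`, `best_fit`, the per-combination `table`,
#'   and `adequate` (whether the selected combination passed all criteria).
#' @export
stage2_select_shapes <- function(measurements, G, n_starts = 5,
                                 mode = c("exhaustive", "greedy"),
                                 entropy_min = 0.9, prop_min = 0.05,
                                 appa_min = 0.7, seed = NULL,
                                 censor_lo = 0, censor_hi = 40,
                                 time_scale = 10, max_iter = 500,
                                 tol = 1e-6) {
  mode <- match.arg(mode)
  fit_orders <- function(orders, sd_off) {
    sp <- trajectory_spec(G, orders, censor_lo, censor_hi, time_scale)
    fit_gbtm(measurements, sp, n_starts = n_starts, max_iter = max_iter,
             tol = tol, seed = if (is.null(seed)) NULL else seed + sd_off)
  }
  key_of <- function(orders) paste(sort(orders), collapse = "")

  if (mode == "exhaustive") {
    combos <- as.matrix(expand.grid(rep(list(2:4), G)))
    colnames(combos) <- paste0("order_g", seq_len(G))
    keys <- apply(combos, 1, key_of)
    fits <- list()
    for (k in unique(keys)) {
      orders <- as.integer(strsplit(k, "")[[1]])
      fits[[k]] <- fit_orders(orders, sd_off = sum(orders) * 7 +
                                as.integer(k) %% 997)
    }
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      f <- fits[[keys[i]]]
      ok <- adequacy_check(f, entropy_min, prop_min, appa_min)
      cbind(as.data.frame(t(combos[i, ])), .fit_diag_row(f),
            data.frame(entropy_ok = ok[["entropy_ok"]],
                       proportion_ok = ok[["proportion_ok"]],
                       appa_ok = ok[["appa_ok"]], all_ok = ok[["all_ok"]]))
    })
    tab <- do.call(rbind, rows)
    uniq <- !duplicated(keys)
    cand <- tab[uniq, ]
    cand_fits <- fits[keys[uniq]]
  } else {
    orders <- rep(2L, G)
    cur <- fit_orders(orders, 0)
    tried <- list()
    tried[[key_of(orders)]] <- cur
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (g in seq_len(G)) {
        for (o in setdiff(2:4, orders[g])) {
          cand_orders <- orders
          cand_orders[g] <- o
          k <- key_of(cand_orders)
          if (is.null(tried[[k]])) {
            tried[[k]] <- fit_orders(cand_orders, sum(cand_orders) * 7)
          }
          if (tried[[k]]$bic > cur$bic + 1e-9) {
            cur <- tried[[k]]
            orders <- cand_orders
            improved <- TRUE
          }
        }
      }
    }
    rows <- lapply(names(tried), function(k) {
      f <- tried[[k]]
      ok <- adequacy_check(f, entropy_min, prop_min, appa_min)
      orders_k <- as.integer(strsplit(k, "")[[1]])
      row <- as.data.frame(t(orders_k))
      names(row) <- paste0("order_g", seq_len(G))
      cbind(row, .fit_diag_row(f),
            data.frame(entropy_ok = ok[["entropy_ok"]],
                       proportion_ok = ok[["proportion_ok"]],
                       appa_ok = ok[["appa_ok"]], all_ok = ok[["all_ok"]]))
    })
    tab <- do.call(rbind, rows)
    cand <- tab
    cand_fits <- tried
  }

  pass <- which(cand$all_ok)
  if (length(pass)) {
    pick <- pass[which.max(cand$bic[pass])]
    adequate <- TRUE
  } else {
    warning("no order combination passed all adequacy criteria; ",
            "returning the best-BIC combination")
    pick <- which.max(cand$bic)
    adequate <- FALSE
  }
  best_fit <- cand_fits[[pick]]
  list(best_spec = best_fit$spec, best_fit = best_fit, table = tab,
       adequate = adequate)
}

#' Two-stage trajectory model selection
#'
#' Runs [stage1_select_groups()] to pick the number of groups, then
#' [stage2_select_shapes()] to pick per-group polynomial orders.
#'
#' @inheritParams stage1_select_groups
#' @param ... Passed to [stage2_select_shapes()] (e.g. `mode`, thresholds).
#' @return A list of class `"gbtm_selection"` with `stage1`, `stage2`,
#'   `best_G`, `best_spec` and `best_fit`.
#' @export
select_trajectory_model <- function(measurements, max_groups = 6,
                                    n_starts = 5, seed = NULL, ...) {
  s1 <- stage1_select_groups(measurements, max_groups = max_groups,
                             n_starts = n_starts, seed = seed)
  s2 <- stage2_select_shapes(measurements, G = s1$best_G,
                             n_starts = n_starts,
                             seed = if (is.null(seed)) NULL else seed + 100,
                             ...)
  structure(list(stage1 = s1, stage2 = s2, best_G = s1$best_G,
                 best_spec = s2$best_spec, best_fit = s2$best_fit),
            class = "gbtm_selection")
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat("Two-stage trajectory model selection\n")
  cat(sprintf("  stage 1: G = %d (BIC over G = 1..%d)\n", x$best_G,
              max(x$stage1$table$G)))
  cat(sprintf("  stage 2: orders (%s)%s\n",
              paste(x$best_spec$poly_orders, collapse = ","),
              if (x$stage2$adequate) "" else " [adequacy criteria NOT met]"))
  print(x$best_fit)
  invisible(x)
}
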