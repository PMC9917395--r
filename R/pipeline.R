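# End-to-end pipeline driver and tabular IO:
# simulate -> preprocess -> score -> select -> fit -> associate.

#' Read a long-format measurement table
#'
#' Expects a CSV with header `patient_id`, `day` (or `datetime`) and
#' `value`. Malformed rows (non-numeric or missing values, negative days)
#' are collected into an error report attached as the `"errors"` attribute
#' rather than silently dropped.
#'
#' @param path CSV file path.
#' @return Data frame of well-formed rows; `attr(, "errors")` holds the
#'   rejected rows with a `reason` column.
#' @export
read_long_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  time_col <- intersect(c("day", "datetime"), names(raw))[1]
  need <- c("patient_id", time_col, "value")
  missing_cols <- setdiff(c("patient_id", "value"), names(raw))
  if (is.na(time_col)) missing_cols <- c(missing_cols, "day")
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("measurement file is empty")
    out <- data.frame(patient_id = character(0), day = numeric(0),
                      value = numeric(0))
    attr(out, "errors") <- data.frame()
    return(out)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  if (time_col == "day") {
    tval <- suppressWarnings(as.numeric(raw[[time_col]]))
    bad_time <- is.na(tval) | tval < 0
  } else {
    tval <- raw[[time_col]]
    bad_time <- is.na(tval) | tval == ""
  }
  reason <- ifelse(is.na(value), "non-numeric value",
                   ifelse(bad_time, "bad time", NA))
  bad <- !is.na(reason)
  errors <- cbind(raw[bad, , drop = FALSE],
                  reason = reason[bad])
  out <- data.frame(patient_id = raw$patient_id[!bad],
                    value = value[!bad], stringsAsFactors = FALSE)
  out[[time_col]] <- if (time_col == "day") tval[!bad] else tval[!bad]
  out <- out[, c("patient_id", time_col, "value")]
  attr(out, "errors") <- errors
  if (nrow(errors)) {
    warning(sprintf("%d malformed row(s) routed to the error report",
                    nrow(errors)))
  }
  out
}

#' Default pipeline configuration
#'
#' Collects every stage's defaults into one list: the simulator
#' configuration, preprocessing bounds, KNN `k`, model-selection settings,
#' the association covariate list, and the master seed from which each stage
#' draws its own sub-seed.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed.
#' @param sim A [sim_config()] (its own seed is overridden by the stage
#'   sub-seed).
#' @param max_groups,n_starts,stage2_mode Model-selection settings.
#' @param screen_alpha Univariate screening level.
#' @return A list of class `"run_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            max_groups = 6, n_starts = 5,
                            stage2_mode = "exhaustive", screen_alpha = 0.1) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 censor_lo = sim$censor_lo, censor_hi = sim$censor_hi,
                 horizon_days = sim$horizon_days, knn_k = 5,
                 max_groups = max_groups, n_starts = n_starts,
                 stage2_mode = stage2_mode, screen_alpha = screen_alpha),
            class = "run_config")
}

#' Run the full trajectory analysis pipeline
#'
#' Executes, in order: cohort simulation, preprocessing (daily-max blocking,
#' minimum-days filter, KNN completion of AIS), TRISS scoring, two-stage
#' model selection, the final trajectory fit, and the mortality association
#' (screening, collinearity, multivariable logistic, AUC comparison against
#' TRISS). Every artifact is written under `config$out_dir` and linked from
#' a JSON manifest carrying the per-stage seeds and the config hash; reruns
#' with the same config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  cfg_plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest <- list(config = cfg_path,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = list())
  stage <- function(name, artifacts) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, artifacts = artifacts)
  }

  # 1. simulate
  sim <- config$sim
  sim$seed <- .stage_seed(config$seed, 1L)
  bundle <- generate_cohort(sim)
  paths <- write_cohort(bundle, config$out_dir)
  stage("simulate", basename(paths))

  # 2. preprocess
  blocked <- block_daily_max(bundle$measurements,
                             horizon_days = config$horizon_days,
                             censor_lo = config$censor_lo,
                             censor_hi = config$censor_hi)
  keep_ids <- names(which(tapply(blocked$day, blocked$patient_id,
                                 function(d) length(unique(d)) >= 3)))
  blocked <- blocked[blocked$patient_id %in% keep_ids, ]
  covs <- impute_ais_knn(
    bundle$covariates[bundle$covariates$patient_id %in% keep_ids, ],
    k = config$knn_k)
  p1 <- file.path(config$out_dir, "blocked_series.csv")
  p2 <- file.path(config$out_dir, "completed_covariates.csv")
  utils::write.csv(blocked, p1, row.names = FALSE)
  utils::write.csv(covs, p2, row.names = FALSE)
  stage("preprocess", basename(c(p1, p2)))

  # 3. score
  covs$triss_ps <- triss_ps(covs$rts, covs$iss, covs$age, covs$mechanism)
  p3 <- file.path(config$out_dir, "triss.csv")
  utils::write.csv(covs[, c("patient_id", "triss_ps")], p3, row.names = FALSE)
  stage("score", basename(p3))

  # 4. select
  sel <- select_trajectory_model(blocked, max_groups = config$max_groups,
                                 n_starts = config$n_starts,
                                 seed = .stage_seed(config$seed, 4L),
                                 mode = config$stage2_mode)
  p4 <- file.path(config$out_dir, "selection_report.json")
  jsonlite::write_json(list(best_G = sel$best_G,
                            best_orders = sel$best_spec$poly_orders,
                            stage1 = sel$stage1$table,
                            stage2 = sel$stage2$table),
                       p4, auto_unbox = TRUE, digits = 10)
  stage("select", basename(p4))

  # 5. fit (final model at the selected spec, more starts)
  fit <- fit_gbtm(blocked, sel$best_spec,
                  n_starts = max(config$n_starts, 10),
                  seed = .stage_seed(config$seed, 5L))
  p5a <- file.path(config$out_dir, "fit.json")
  p5b <- file.path(config$out_dir, "posterior.csv")
  jsonlite::write_json(list(
    beta_scaled = fit$params$beta,
    beta_per_day = coef_natural_scale(fit),
    sigma = fit$params$sigma, pi = fit$params$pi,
    loglik = fit$loglik, bic = fit$bic, entropy = fit$entropy,
    appa = fit$appa, group_props = fit$group_props,
    converged = fit$converged, seed = fit$seed),
    p5a, auto_unbox = TRUE, digits = 10)
  post <- data.frame(patient_id = fit$patient_ids,
                     round(fit$posterior, 6),
                     assigned = fit$assignment)
  names(post)[2:(1 + fit$spec$n_groups)] <-
    paste0("p_group", seq_len(fit$spec$n_groups))
  utils::write.csv(post, p5b, row.names = FALSE)
  stage("fit", basename(c(p5a, p5b)))

  # 6. associate
  lab <- fit$assignment[match(covs$patient_id, fit$patient_ids)]
  screen_covs <- covs[, intersect(
    c("age", "male", "bmi", "sofa", "ais_abdomen", "iss", "mechanism",
      "ufh", "lmwh", "transfusion", "plasma", "surgery"), names(covs))]
  scr <- suppressWarnings(univariate_screen(screen_covs, covs$death,
                                            alpha = config$screen_alpha))
  cand_names <- scr$variable[scr$keep]
  adj <- NULL
  if (length(cand_names) >= 2L) {
    pv <- stats::setNames(scr$p, scr$variable)
    col <- collinearity_screen(screen_covs[, cand_names, drop = FALSE],
                               univariate_p = pv)
    adj <- screen_covs[, col$retained, drop = FALSE]
  } else if (length(cand_names) == 1L) {
    adj <- screen_covs[, cand_names, drop = FALSE]
  }
  mv <- fit_multivariable(covs$death, lab, adj)
  uni <- fit_multivariable(covs$death, lab, NULL)
  auc_traj <- roc_auc(stats::fitted(mv$model), covs$death)
  auc_triss <- roc_auc(1 - covs$triss_ps, covs$death)
  p6 <- file.path(config$out_dir, "association.json")
  jsonlite::write_json(list(screen = scr, univariate = uni$table,
                            multivariable = mv$table,
                            auc_trajectory = auc_traj,
                            auc_triss = auc_triss),
                       p6, auto_unbox = TRUE, digits = 10)
  stage("associate", basename(p6))

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = 10)
  invisible(manifest)
}
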