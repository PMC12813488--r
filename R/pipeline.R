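#' Pipeline configuration
#'
#' Collects thresholds, model options, cohort sizes, and the master seed
#' for [run_pipeline()]. Thresholds must be positive; the configuration is
#' validated before any compute.
#'
#' @param out_dir output directory for stage artifacts
#' @param seed master seed; each stage derives its own child seed
#' @param n_train training-cohort size (default 300)
#' @param n_longitudinal longitudinal-cohort size (default 150)
#' @param n_deprivation deprivation-cohort pairs (default 60)
#' @param n_parcels parcels for all synthetic cohorts (default 30)
#' @param n_sites sites for the training cohort (default 4)
#' @param n_runs,volumes_per_run,tr_seconds acquisition layout per subject
#' @param fd_mm censoring threshold (default 0.5 mm)
#' @param min_minutes minimum retained run duration (default 4)
#' @param highpass_hz high-pass cutoff (default 0.008)
#' @param inner_folds inner CV folds (default 5)
#' @param grid component grid; NULL for the default
#' @param K_contrast components for the contrast signature (default 21,
#'   clamped to the data rank)
#' @param B permutations for significance tests (default 200)
#' @param delta_sleep_sd SD of longitudinal latent sleep change (default 1)
#' @param deprivation_shift planted deprivation amplitude (default 1)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_train = 300, n_longitudinal = 150,
                            n_deprivation = 60,
                            n_parcels = 30, n_sites = 4,
                            n_runs = 4, volumes_per_run = 375,
                            tr_seconds = 0.8,
                            fd_mm = 0.5, min_minutes = 4,
                            highpass_hz = 0.008,
                            inner_folds = 5, grid = NULL,
                            K_contrast = 21, B = 200,
                            delta_sleep_sd = 1, deprivation_shift = 1) {
  cfg <- as.list(environment())
  for (f in c("fd_mm", "min_minutes", "highpass_hz", "B", "K_contrast",
              "n_train", "n_longitudinal", "n_deprivation", "n_parcels",
              "n_sites", "inner_folds", "tr_seconds")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("configuration error: '", f, "' must be positive")
    }
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

.stage_train <- function(config) {
  set.seed(config$seed)
  sim <- simulate_cross_sectional(sim_config(
    n_subjects = config$n_train, n_parcels = config$n_parcels,
    n_sites = config$n_sites, n_runs = config$n_runs,
    volumes_per_run = config$volumes_per_run,
    tr_seconds = config$tr_seconds, seed = config$seed))
  co <- sim$cohort
  fm <- fit_factor(co[, c("parent_duration", "child_duration", "device_duration")])
  y <- factor_scores(fm, co[, c("parent_duration", "child_duration",
                                "device_duration")], orientation = "reduced")
  covars <- standard_covariates(co)
  cv <- loso_cv(sim$X, y, co$site_id, covars, grid = config$grid,
                inner_folds = config$inner_folds)
  K <- round_half_up(mean(cv$K_per_fold, na.rm = TRUE))
  sig <- build_signature(sim$X, y, covars, K, sim$networks)
  blocks <- exchangeability_blocks(co$site_id, co$family_id, co$twin_pair_id)
  fl <- freedman_lane_null(y, covars, blocks, B = config$B,
                           statistic = insample_r_statistic(sim$X, covars, K))
  list(sim = sim, factor_model = fm, y = y, covariates = covars,
       cv = cv, K = K, signature = sig, permutation = fl)
}

.stage_longitudinal <- function(config, signature) {
  long <- simulate_longitudinal(sim_config(
    n_subjects = config$n_longitudinal, n_parcels = config$n_parcels,
    n_sites = max(3, config$n_sites), n_runs = config$n_runs,
    volumes_per_run = config$volumes_per_run,
    tr_seconds = config$tr_seconds, seed = config$seed + 1L),
    delta_sleep_sd = config$delta_sleep_sd)
  co <- long$cohort
  e1 <- express(signature, long$X_t1)
  e2 <- express(signature, long$X_t2)
  covs <- longitudinal_covariates(co$age_t2 - co$age_t1,
                                  co$mean_fd_t1, co$mean_fd_t2, co$sex)
  fit <- longitudinal_change_model(e1, e2, co$sleep_t1, co$sleep_t2,
                                   co$site_id, covs)
  list(sim = long, expr_t1 = e1, expr_t2 = e2, model = fit)
}

.stage_deprivation <- function(config, signature) {
  dep <- simulate_deprivation(sim_config(
    n_subjects = config$n_deprivation, n_parcels = config$n_parcels,
    n_sites = 1, n_runs = config$n_runs,
    volumes_per_run = config$volumes_per_run,
    tr_seconds = config$tr_seconds, seed = config$seed + 2L),
    deprivation_shift = config$deprivation_shift)
  co <- dep$cohort
  et <- express(signature, dep$X_typical)
  ed <- express(signature, dep$X_deprived)
  ct <- deprivation_contrast(et, ed, sex = co$sex, age_group = co$age_group,
                             motion_typical = co$mean_fd_typical,
                             motion_deprived = co$mean_fd_deprived)
  list(sim = dep, expr_typical = et, expr_deprived = ed, contrast = ct)
}

.stage_correspond <- function(config, train, dep) {
  co <- dep$sim$cohort
  covs_t <- cbind(sex = co$sex, age_group = co$age_group,
                  motion = co$mean_fd_typical)
  covs_d <- cbind(sex = co$sex, age_group = co$age_group,
                  motion = co$mean_fd_deprived)
  K <- max(1, min(config$K_contrast, nrow(co) - 4))
  set.seed(config$seed + 3L)
  dual_permutation_null(
    X = train$sim$X, y = train$y, covariates = train$covariates,
    K_x = min(config$K_contrast, nrow(train$sim$X) - 2),
    typical = dep$sim$X_typical, deprived = dep$sim$X_deprived,
    cov_typical = covs_t, cov_deprived = covs_d,
    K_c = K, networks = train$sim$networks, B = config$B)
}

#' Run the synthetic end-to-end workflow
#'
#' Reproduces the four analysis stages on synthetic cohorts: (1) train the
#' reduced-sleep neurosignature (latent factor, LOSO-CV PCR, Freedman-Lane
#' permutation p), (2) longitudinal expression change mixed model, (3)
#' within-subject deprivation contrast, (4) dual-permutation spatial
#' correspondence. Stage artifacts (signature table, per-site CV, model
#' summaries) are written as TSV/JSON under `config$out_dir`; everything is
#' deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @param stage one of "all", "train", "longitudinal", "deprivation",
#'   "correspond"; stages after "train" require its outputs, so "all" is
#'   the common entry point
#' @return named list of stage results, invisibly
#' @export
run_pipeline <- function(config, stage = c("all", "train", "longitudinal",
                                           "deprivation", "correspond")) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  train <- .stage_train(config)
  out <- list(train = train)
  write_connectome_table(train$signature,
                         file.path(config$out_dir, "signature.tsv"))
  utils::write.table(
    data.frame(site = names(train$cv$per_site),
               r = sprintf("%.10g", train$cv$per_site),
               K = train$cv$K_per_fold),
    file.path(config$out_dir, "cv_per_site.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = config$seed,
    r_cv = train$cv$mean_r,
    r_cv_perm_p = train$permutation$p,
    n_components = train$K,
    factor_loadings = train$factor_model$loadings)

  if (stage %in% c("all", "longitudinal")) {
    long <- .stage_longitudinal(config, train$signature)
    out$longitudinal <- long
    summary$longitudinal_beta <- long$model$beta
    summary$longitudinal_p <- long$model$p
    utils::write.table(
      data.frame(subject = long$sim$cohort$subject_id,
                 expr_t1 = sprintf("%.10g", long$expr_t1),
                 expr_t2 = sprintf("%.10g", long$expr_t2)),
      file.path(config$out_dir, "longitudinal_expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage %in% c("all", "deprivation", "correspond")) {
    dep <- .stage_deprivation(config, train$signature)
    out$deprivation <- dep
    summary$deprivation_mean_diff <- dep$contrast$mean_diff
    summary$deprivation_t <- dep$contrast$t
    summary$deprivation_p <- dep$contrast$p
    utils::write.table(
      data.frame(subject = dep$sim$cohort$subject_id,
                 expr_typical = sprintf("%.10g", dep$expr_typical),
                 expr_deprived = sprintf("%.10g", dep$expr_deprived)),
      file.path(config$out_dir, "deprivation_expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage %in% c("all", "correspond")) {
    corr <- .stage_correspond(config, train, dep)
    out$correspondence <- corr
    summary$spatial_r <- corr$observed
    summary$spatial_p <- corr$p
    utils::write.table(
      data.frame(null_r = sprintf("%.10g", corr$null)),
      file.path(config$out_dir, "correspondence_null.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_sidecar(summary, file.path(config$out_dir, "run_summary.json"))
  invisible(out)
}
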