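#' Default network labels for a synthetic parcellation
#'
#' Splits parcels as evenly as possible across six canonical networks,
#' always including the somatomotor (SMN) and visual (VIS) blocks the
#' planted effect targets.
#'
#' @param n_parcels parcel count
#' @return character vector of length `n_parcels`
#' @export
default_network_labels <- function(n_parcels) {
  nets <- c("SMN", "VIS", "DMN", "FPN", "DAN", "CO")
  sort(rep_len(nets, n_parcels))
}

#' Configuration of the synthetic multisite cohort
#'
#' Defines the statistical structure all generators share: a one-factor
#' latent sleep-duration construct with three noisy indicators; community
#' (network-block) structured connectomes; a planted sleep effect confined
#' to within-SMN (positive for reduced sleep) and within-VIS (negative)
#' edges, expressed in Fisher-z units per SD of the latent; site and family
#' nesting with a twin fraction; and an FD-correlated motion confound that
#' inflates global signal variance.
#'
#' @param n_subjects subjects to simulate
#' @param n_parcels parcels (default 60)
#' @param network_labels per-parcel networks; must include "SMN" and "VIS"
#' @param n_sites acquisition sites (default 6)
#' @param twin_fraction fraction of subjects who are one of a twin pair
#' @param n_runs resting-state runs per subject (default 4)
#' @param volumes_per_run volumes per run (default 375, i.e. 5 min at
#'   TR = 0.8 s)
#' @param tr_seconds repetition time (default 0.8)
#' @param effect_size_smn planted within-SMN z shift per SD of *reduced*
#'   sleep (default 0.10)
#' @param effect_size_vis planted within-VIS shift, negative (default
#'   -0.08)
#' @param indicator_loadings standardized loadings of the three sleep
#'   indicators (default 0.8, 0.6, 0.5)
#' @param motion_confound_strength scaling of the FD-driven global variance
#'   inflation (default 0.2)
#' @param base_within_r,base_between_r baseline within-/between-network
#'   correlations (defaults 0.35 / 0.08)
#' @param edge_noise_sd SD of stable subject-specific edge perturbations in
#'   z units (default 0.06)
#' @param site_edge_sd SD of site-specific edge offsets (default 0.02)
#' @param seed master seed; every sub-generator derives child seeds from it
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_subjects,
                       n_parcels = 60,
                       network_labels = default_network_labels(n_parcels),
                       n_sites = 6,
                       twin_fraction = 0.2,
                       n_runs = 4,
                       volumes_per_run = 375,
                       tr_seconds = 0.8,
                       effect_size_smn = 0.10,
                       effect_size_vis = -0.08,
                       indicator_loadings = c(0.8, 0.6, 0.5),
                       motion_confound_strength = 0.2,
                       base_within_r = 0.35,
                       base_between_r = 0.08,
                       edge_noise_sd = 0.06,
                       site_edge_sd = 0.02,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_parcels = as.integer(n_parcels),
              network_labels = as.character(network_labels),
              n_sites = as.integer(n_sites), twin_fraction = twin_fraction,
              n_runs = as.integer(n_runs),
              volumes_per_run = as.integer(volumes_per_run),
              tr_seconds = tr_seconds,
              effect_size_smn = effect_size_smn, effect_size_vis = effect_size_vis,
              indicator_loadings = indicator_loadings,
              motion_confound_strength = motion_confound_strength,
              base_within_r = base_within_r, base_between_r = base_between_r,
              edge_noise_sd = edge_noise_sd, site_edge_sd = site_edge_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects >= 1, n_parcels >= 2, n_sites >= 1, n_runs >= 1,
              volumes_per_run >= 8, tr_seconds > 0,
              twin_fraction >= 0, twin_fraction <= 1,
              length(indicator_loadings) == 3,
              all(indicator_loadings > 0), all(indicator_loadings < 1))
  })
  if (length(cfg$network_labels) != cfg$n_parcels) {
    stop("configuration error: network_labels must cover all parcels")
  }
  if (!all(c("SMN", "VIS") %in% cfg$network_labels)) {
    stop("configuration error: network labels must include SMN and VIS blocks")
  }
  structure(cfg, class = "sim_config")
}

#' Planted effect map of a configuration
#'
#' The ground-truth edge map of the sleep effect: `effect_size_smn` on
#' within-SMN edges, `effect_size_vis` on within-VIS edges, zero
#' elsewhere, in Fisher-z units per SD of reduced sleep.
#'
#' @param config a [sim_config()]
#' @return numeric edge vector
#' @export
planted_map <- function(config) {
  e <- numeric(n_edges(config$n_parcels))
  e[within_network_edges(config$network_labels, "SMN")] <- config$effect_size_smn
  e[within_network_edges(config$network_labels, "VIS")] <- config$effect_size_vis
  e
}

# deterministic child seed from the master seed (kept below 2^31)
.child_seed <- function(seed, k) (seed * 97L + k * 101L) %% 2000000011L

# site/family/twin assignment satisfying the strict nesting tree
.assign_structure <- function(n, n_sites, twin_fraction) {
  site <- sort(rep_len(seq_len(n_sites), n))
  family <- character(n)
  twin <- rep(NA_character_, n)
  fam_counter <- 0L
  for (s in seq_len(n_sites)) {
    idx <- which(site == s)
    ns <- length(idx)
    n_pairs <- floor(twin_fraction * ns / 2)
    pos <- 1L
    while (pos <= ns) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("fam%05d", fam_counter)
      if (n_pairs > 0 && pos + 1L <= ns) {
        family[idx[pos + 0:1]] <- fid
        twin[idx[pos + 0:1]] <- paste0(fid, "_tw")
        n_pairs <- n_pairs - 1L
        pos <- pos + 2L
      } else {
        family[idx[pos]] <- fid
        pos <- pos + 1L
      }
    }
  }
  data.frame(site_id = paste0("site", sprintf("%02d", site)),
             family_id = family, twin_pair_id = twin,
             stringsAsFactors = FALSE)
}

# nearest-PD projection for a correlation matrix (eigenvalue clipping)
.fix_pd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > 1e-8) return(R)
  v <- pmax(e$values, 1e-6)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 / tcrossprod(d)
}

# simulate one subject's runs from a parcel correlation matrix, pushing the
# motion confound and censorable spike artifacts into the time series
.simulate_runs <- function(R, n_runs, n_vol, tr, fd_mean, motion_strength) {
  L <- chol(.fix_pd(R))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fd <- fd_mean * stats::rgamma(n_vol, shape = 4, rate = 4)
    spike <- stats::runif(n_vol) < 0.02
    fd[spike] <- fd[spike] + stats::runif(sum(spike), 0.3, 1.2)
    Y <- matrix(stats::rnorm(n_vol * ncol(R)), n_vol) %*% L
    Y <- Y * (1 + motion_strength * fd)          # global variance inflation
    bad <- fd > 0.5
    if (any(bad)) {
      Y[bad, ] <- Y[bad, ] + matrix(stats::rnorm(sum(bad) * ncol(R), 0, 3),
                                    sum(bad))
    }
    nuis <- cbind(fd + stats::rnorm(n_vol, 0, 0.02),
                  c(0, diff(fd)) + stats::rnorm(n_vol, 0, 0.02),
                  fd^2 + stats::rnorm(n_vol, 0, 0.02),
                  matrix(stats::rnorm(n_vol * 3), n_vol))
    runs[[r]] <- run_timeseries(Y, tr, fd, nuis)
  }
  runs
}

# subject-specific z-level connectivity matrix: base blocks + site offset +
# stable subject jitter + planted sleep effect
.subject_zmat <- function(config, z_sleep, site_offset, subj_jitter) {
  p <- config$n_parcels
  nets <- config$network_labels
  base_r <- matrix(config$base_between_r, p, p)
  same <- outer(nets, nets, "==")
  base_r[same] <- config$base_within_r
  diag(base_r) <- 0
  Z <- atanh(base_r)
  zvec <- vec_upper(Z) + site_offset + subj_jitter +
    planted_map(config) * (-z_sleep)
  unvec_upper(zvec, diag = 0)
}

.indicator_names <- c("parent_duration", "child_duration", "device_duration")

#' Simulate a cross-sectional multisite cohort
#'
#' Generates phenotypes and connectomes with the structure the downstream
#' analysis assumes. Parcel time series are sampled per run from a
#' network-block correlation matrix (so the connectome construction code
#' path is exercised end-to-end), with an FD-correlated global variance
#' confound and occasional high-motion spike volumes; connectomes are then
#' built through [subject_connectome()]. The latent sleep variable is
#' retained in the output for oracle-only recovery tests — pipeline stages
#' must never consume it.
#'
#' @param config a [sim_config()]
#' @param return_timeseries also return the raw per-subject runs (memory
#'   heavy; default FALSE)
#' @param imaging generate time series and connectomes (default TRUE);
#'   FALSE yields phenotypes only (`X` is NULL), for tests of the
#'   measurement model at large n
#' @return list of class `synthetic_cohort`: `cohort` (data.frame with
#'   subject, site, family, twin pair, sex, age, mean FD, the three sleep
#'   indicators in hours, and the oracle-only `latent_sleep`), `X`
#'   (subjects x edges Fisher-z matrix), `networks`, `truth` (planted map
#'   and generator parameters), `config`; plus `runs` when requested
#' @export
simulate_cross_sectional <- function(config, return_timeseries = FALSE,
                                     imaging = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 1L))
  n <- config$n_subjects
  p <- config$n_parcels

  struct <- .assign_structure(n, config$n_sites, config$twin_fraction)
  # latent sleep: family-shared component (twins/siblings correlate) + unique
  fam <- struct$family_id
  fam_eff <- stats::setNames(stats::rnorm(length(unique(fam)), 0, sqrt(0.3)),
                             unique(fam))
  latent <- fam_eff[fam] + stats::rnorm(n, 0, sqrt(0.7))
  latent <- as.numeric(scale(latent))

  lam <- config$indicator_loadings
  ind_std <- sapply(lam, function(l) l * latent + stats::rnorm(n, 0, sqrt(1 - l^2)))
  indicators <- 9.2 + 0.8 * ind_std          # hour-like scale
  colnames(indicators) <- .indicator_names

  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::runif(n, 11, 13)
  # motion confound: shorter sleepers move more
  fd_mean <- exp(stats::rnorm(n, log(0.15), 0.35)) * (1 - 0.1 * latent)
  fd_mean <- pmax(fd_mean, 0.02)

  site_ids <- unique(struct$site_id)
  E <- n_edges(p)
  site_offsets <- matrix(stats::rnorm(length(site_ids) * E, 0, config$site_edge_sd),
                         nrow = length(site_ids),
                         dimnames = list(site_ids, NULL))

  X <- matrix(NA_real_, n, E)
  mean_fd_obs <- fd_mean
  runs_used <- rep(1L, n)
  all_runs <- if (return_timeseries) vector("list", n) else NULL
  for (i in if (imaging) seq_len(n) else integer(0)) {
    Zm <- .subject_zmat(config, latent[i], site_offsets[struct$site_id[i], ],
                        stats::rnorm(E, 0, config$edge_noise_sd))
    runs <- .simulate_runs(tanh(Zm), config$n_runs, config$volumes_per_run,
                           config$tr_seconds, fd_mean[i],
                           config$motion_confound_strength)
    sc <- subject_connectome(runs, config$network_labels)
    if (sc$n_runs_used == 0) {
      message("subject ", i, " has no eligible run; connectome set to NA")
    } else {
      X[i, ] <- sc$connectome$values
    }
    runs_used[i] <- sc$n_runs_used
    mean_fd_obs[i] <- mean(unlist(lapply(runs, `[[`, "fd_mm")))
    if (return_timeseries) all_runs[[i]] <- runs
  }

  cohort <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
                       struct,
                       sex = sex, age_years = age, mean_fd_mm = mean_fd_obs,
                       indicators,
                       n_runs_used = runs_used,
                       latent_sleep = latent,   # oracle-only
                       stringsAsFactors = FALSE)
  keep <- runs_used > 0
  if (!all(keep)) {
    message(sum(!keep), " subject(s) excluded: no eligible run after censoring")
  }
  out <- list(cohort = cohort[keep, , drop = FALSE],
              X = X[keep, , drop = FALSE],
              networks = config$network_labels,
              truth = list(planted_map = planted_map(config),
                           latent_sleep = latent[keep]),
              n_excluded = sum(!keep),
              config = config)
  if (return_timeseries) out$runs <- all_runs[keep]
  class(out) <- "synthetic_cohort"
  out
}

#' Simulate a two-timepoint longitudinal cohort
#'
#' Each subject is generated at two timepoints two years apart. The latent
#' sleep variable changes by a N(0, delta_sleep_sd) increment; connectivity
#' at each timepoint carries the planted pattern scaled by that timepoint's
#' latent value, on top of a stable subject-specific connectome. Only the
#' parent-reported duration indicator is observed at both timepoints
#' (mirroring what a baseline wave typically offers). Ground-truth latent
#' columns are retained for oracle-only tests.
#'
#' @param config a [sim_config()]
#' @param delta_sleep_sd SD of the within-subject latent sleep change
#'   (>= 0)
#' @return list of class `synthetic_longitudinal`: `cohort` (one row per
#'   subject with sleep at both timepoints and oracle latents), `X_t1`,
#'   `X_t2` (subjects x edges), `networks`, `truth`, `config`
#' @export
simulate_longitudinal <- function(config, delta_sleep_sd) {
  stopifnot(inherits(config, "sim_config"))
  if (delta_sleep_sd < 0) stop("delta_sleep_sd must be non-negative")
  set.seed(.child_seed(config$seed, 2L))
  n <- config$n_subjects
  p <- config$n_parcels
  E <- n_edges(p)

  struct <- .assign_structure(n, config$n_sites, config$twin_fraction)
  z1 <- stats::rnorm(n)
  dz <- stats::rnorm(n, 0, delta_sleep_sd)
  z2 <- z1 + dz

  lam1 <- config$indicator_loadings[1]
  sleep_t1 <- 9.2 + 0.8 * (lam1 * z1 + stats::rnorm(n, 0, sqrt(1 - lam1^2)))
  sleep_t2 <- 9.2 + 0.8 * (lam1 * z2 + stats::rnorm(n, 0, sqrt(1 - lam1^2)))

  sex <- stats::rbinom(n, 1, 0.5)
  age_t1 <- stats::runif(n, 9, 10)
  age_t2 <- age_t1 + stats::rnorm(n, 2.08, 0.15)
  fd_t1 <- pmax(exp(stats::rnorm(n, log(0.16), 0.35)), 0.02)
  fd_t2 <- pmax(fd_t1 * exp(stats::rnorm(n, 0, 0.15)), 0.02)

  site_ids <- unique(struct$site_id)
  site_offsets <- matrix(stats::rnorm(length(site_ids) * E, 0, config$site_edge_sd),
                         nrow = length(site_ids),
                         dimnames = list(site_ids, NULL))

  X1 <- matrix(NA_real_, n, E)
  X2 <- matrix(NA_real_, n, E)
  fd_obs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    stable <- stats::rnorm(E, 0, config$edge_noise_sd)
    soff <- site_offsets[struct$site_id[i], ]
    for (tp in 1:2) {
      zlat <- if (tp == 1) z1[i] else z2[i]
      Zm <- .subject_zmat(config, zlat, soff,
                          stable + stats::rnorm(E, 0, config$edge_noise_sd / 3))
      runs <- .simulate_runs(tanh(Zm), config$n_runs, config$volumes_per_run,
                             config$tr_seconds,
                             if (tp == 1) fd_t1[i] else fd_t2[i],
                             config$motion_confound_strength)
      sc <- subject_connectome(runs, config$network_labels)
      if (sc$n_runs_used > 0) {
        if (tp == 1) X1[i, ] <- sc$connectome$values else X2[i, ] <- sc$connectome$values
      }
      fd_obs[i, tp] <- mean(unlist(lapply(runs, `[[`, "fd_mm")))
    }
  }

  cohort <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)), struct,
                       sex = sex,
                       age_t1 = age_t1, age_t2 = age_t2,
                       mean_fd_t1 = fd_obs[, 1], mean_fd_t2 = fd_obs[, 2],
                       sleep_t1 = sleep_t1, sleep_t2 = sleep_t2,
                       latent_t1 = z1, latent_t2 = z2,      # oracle-only
                       delta_latent = dz,                    # oracle-only
                       stringsAsFactors = FALSE)
  keep <- stats::complete.cases(X1) & stats::complete.cases(X2)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) excluded: missing timepoint after censoring")
  }
  structure(list(cohort = cohort[keep, , drop = FALSE],
                 X_t1 = X1[keep, , drop = FALSE],
                 X_t2 = X2[keep, , drop = FALSE],
                 networks = config$network_labels,
                 truth = list(planted_map = planted_map(config),
                              delta_sleep_sd = delta_sleep_sd,
                              delta_latent = dz[keep]),
                 n_excluded = sum(!keep),
                 config = config),
            class = "synthetic_longitudinal")
}

#' Simulate a paired sleep-deprivation cohort
#'
#' A two-session within-subject design: the deprived-session connectivity
#' equals the typical-session connectivity plus `deprivation_shift` times
#' the planted pattern plus independent session noise. Covariates (sex,
#' young/old age group, per-session motion) are generated for the contrast
#' model.
#'
#' @param config a [sim_config()]
#' @param deprivation_shift amplitude of the planted pattern added to the
#'   deprived session, in SD-of-latent units (default 1)
#' @return list of class `synthetic_deprivation`: `cohort`, `X_typical`,
#'   `X_deprived`, `networks`, `truth`, `config`
#' @export
simulate_deprivation <- function(config, deprivation_shift = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 3L))
  n <- config$n_subjects
  E <- n_edges(config$n_parcels)

  sex <- stats::rbinom(n, 1, 0.5)
  age_group <- stats::rbinom(n, 1, 0.5)          # 0 young, 1 old
  fd_typ <- pmax(exp(stats::rnorm(n, log(0.14), 0.3)), 0.02)
  fd_dep <- pmax(fd_typ * exp(stats::rnorm(n, 0.1, 0.15)), 0.02)

  Xt <- matrix(NA_real_, n, E)
  Xd <- matrix(NA_real_, n, E)
  fd_obs <- matrix(0, n, 2)
  pat <- planted_map(config)
  for (i in seq_len(n)) {
    stable <- stats::rnorm(E, 0, config$edge_noise_sd)
    for (sess in 1:2) {
      shift <- if (sess == 2) deprivation_shift else 0
      zvec <- vec_upper(.subject_zmat(config, 0, numeric(E), stable)) +
        shift * pat + stats::rnorm(E, 0, config$edge_noise_sd / 3)
      runs <- .simulate_runs(tanh(unvec_upper(zvec)),
                             config$n_runs, config$volumes_per_run,
                             config$tr_seconds,
                             if (sess == 1) fd_typ[i] else fd_dep[i],
                             config$motion_confound_strength)
      sc <- subject_connectome(runs, config$network_labels)
      if (sc$n_runs_used > 0) {
        if (sess == 1) Xt[i, ] <- sc$connectome$values else Xd[i, ] <- sc$connectome$values
      }
      fd_obs[i, sess] <- mean(unlist(lapply(runs, `[[`, "fd_mm")))
    }
  }
  cohort <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
                       sex = sex, age_group = age_group,
                       mean_fd_typical = fd_obs[, 1],
                       mean_fd_deprived = fd_obs[, 2],
                       stringsAsFactors = FALSE)
  keep <- stats::complete.cases(Xt) & stats::complete.cases(Xd)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) excluded: missing session after censoring")
  }
  structure(list(cohort = cohort[keep, , drop = FALSE],
                 X_typical = Xt[keep, , drop = FALSE],
                 X_deprived = Xd[keep, , drop = FALSE],
                 networks = config$network_labels,
                 truth = list(planted_map = pat,
                              deprivation_shift = deprivation_shift),
                 n_excluded = sum(!keep),
                 config = config),
            class = "synthetic_deprivation")
}

#' Simulate expression-score changes with a planted standardized coupling
#'
#' Score-level generator for validating the longitudinal mixed model: the
#' standardized change in expression is built as
#' coupling * z(change in sleep) + site effect + residual, with the
#' residual variance chosen so the outcome has unit variance — the true
#' standardized regression coefficient therefore equals `coupling`
#' exactly (stored in `truth`). Covariates are pure-noise columns so the
#' adjusted model remains correctly specified.
#'
#' @param n subjects
#' @param coupling true standardized coefficient (|coupling| < 1); negative
#'   values encode "less sleep, more reduced-sleep expression"
#' @param n_sites number of sites (default 10)
#' @param site_sd SD of the site random intercept on the outcome scale
#'   (default 0.2)
#' @param seed RNG seed
#' @return data.frame with `expr_t1`, `expr_t2`, `sleep_t1`, `sleep_t2`,
#'   `site`, noise covariates, and attribute `truth`
#' @export
simulate_expression_change <- function(n, coupling, n_sites = 10,
                                       site_sd = 0.2, seed = 1L) {
  stopifnot(abs(coupling) < 1, site_sd^2 + coupling^2 < 1)
  set.seed(.child_seed(as.integer(seed), 4L))
  site <- paste0("site", sort(rep_len(seq_len(n_sites), n)))
  site_eff <- stats::setNames(stats::rnorm(n_sites, 0, site_sd),
                              unique(site))
  d_sleep <- stats::rnorm(n)
  resid_sd <- sqrt(1 - coupling^2 - site_sd^2)
  d_expr <- coupling * d_sleep + site_eff[site] + stats::rnorm(n, 0, resid_sd)

  sleep_t1 <- stats::rnorm(n, 9.2, 0.8)
  expr_t1 <- stats::rnorm(n)
  out <- data.frame(
    expr_t1 = expr_t1, expr_t2 = expr_t1 + d_expr,
    sleep_t1 = sleep_t1, sleep_t2 = sleep_t1 + d_sleep,
    site = site,
    age_diff = stats::rnorm(n, 2.08, 0.15),
    fd_t1 = pmax(stats::rnorm(n, 0.15, 0.05), 0.02),
    fd_t2 = pmax(stats::rnorm(n, 0.15, 0.05), 0.02),
    sex = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(coupling = coupling, site_sd = site_sd)
  out
}

#' Longitudinal covariate matrix (age/motion/sex) from a change table
#'
#' Builds the standard covariate set of the longitudinal model: age
#' difference (linear, quadratic), mean motion at each timepoint (linear,
#' quadratic), and sex.
#'
#' @param age_diff per-subject age difference in years
#' @param fd_t1,fd_t2 mean FD at each timepoint
#' @param sex binary sex code
#' @return numeric covariate matrix
#' @export
longitudinal_covariates <- function(age_diff, fd_t1, fd_t2, sex) {
  cbind(age_diff = age_diff, age_diff2 = age_diff^2,
        fd_t1 = fd_t1, fd_t1_2 = fd_t1^2,
        fd_t2 = fd_t2, fd_t2_2 = fd_t2^2,
        sex = as.numeric(sex))
}
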