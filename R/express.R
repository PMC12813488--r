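#' Neurosignature expression score
#'
#' Projects a signature onto one or many connectomes by a vector dot
#' product: value = sum_e weight_e * z_e. The score is linear in the
#' connectome and only comparable across connectomes sharing the signature's
#' edge ordering, which is checked via the parcel/network metadata — an
#' ordering mismatch is an error, never a silent reorder.
#'
#' @param signature a `neurosignature` or `contrast_signature` (anything
#'   with `weights` and `networks`), or a bare numeric weight vector
#' @param connectome an [edge_vector()], or a subjects x edges matrix
#' @param map which map to project: `"weights"` (default) or `"haufe"`
#' @return scalar (single connectome) or numeric vector (matrix input)
#' @export
express <- function(signature, connectome, map = c("weights", "haufe")) {
  map <- match.arg(map)
  if (is.numeric(signature) && !is.list(signature)) {
    w <- signature
    nets <- NULL
  } else {
    w <- if (map == "haufe") signature$haufe else signature$weights
    nets <- signature$networks
  }
  if (inherits(connectome, "edge_vector")) {
    if (!is.null(nets) && !same_edge_order(signature, connectome)) {
      stop("edge ordering mismatch between signature and connectome")
    }
    v <- connectome$values
    if (length(v) != length(w)) stop("edge count mismatch")
    return(sum(w * v))
  }
  M <- as.matrix(connectome)
  if (ncol(M) != length(w)) stop("edge count mismatch")
  as.numeric(M %*% w)
}

#' Longitudinal change model for signature expression
#'
#' Regresses the within-subject change in expression on the within-subject
#' change in sleep duration with a random intercept per site, controlling
#' for the supplied covariates (age difference linear and quadratic, mean
#' motion at each timepoint linear and quadratic, sex). Outcome and
#' predictor are z-scored on the analysis sample before fitting, so the
#' reported fixed effect is a standardized beta. A singular random-effect
#' fit falls back to OLS with cluster-robust (by site) standard errors,
#' flagged in the output.
#'
#' @param expr_t1,expr_t2 expression scores at the two timepoints
#' @param sleep_t1,sleep_t2 sleep duration at the two timepoints
#' @param site per-subject site labels (>= 3 sites)
#' @param covariates optional numeric covariate matrix
#' @return list: `beta` (standardized), `se`, `p`, `method`
#'   ("mixed" or "ols_cluster_robust"), `n`, `model`
#' @export
longitudinal_change_model <- function(expr_t1, expr_t2, sleep_t1, sleep_t2,
                                      site, covariates = NULL) {
  stopifnot(length(expr_t1) == length(expr_t2),
            length(sleep_t1) == length(sleep_t2),
            length(expr_t1) == length(sleep_t1))
  site <- as.character(site)
  if (length(unique(site)) < 3) stop("need at least 3 sites")
  d_expr <- as.numeric(scale(expr_t2 - expr_t1))
  d_sleep <- as.numeric(scale(sleep_t2 - sleep_t1))
  df <- data.frame(d_expr = d_expr, d_sleep = d_sleep, site = site)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- paste0("c", seq_len(ncol(covariates)))
    colnames(covariates) <- cn
    df <- cbind(df, as.data.frame(covariates))
    cov_terms <- cn
  }
  fml <- stats::reformulate(c("d_sleep", cov_terms, "(1 | site)"),
                            response = "d_expr")
  fit <- lmerTest::lmer(fml, data = df)
  if (lme4::isSingular(fit, tol = 1e-5)) {
    fml0 <- stats::reformulate(c("d_sleep", cov_terms), response = "d_expr")
    ols <- stats::lm(fml0, data = df)
    ct <- lmtest::coeftest(ols, vcov. = sandwich::vcovCL(ols, cluster = df$site))
    return(list(beta = unname(ct["d_sleep", "Estimate"]),
                se = unname(ct["d_sleep", "Std. Error"]),
                p = unname(ct["d_sleep", "Pr(>|t|)"]),
                method = "ols_cluster_robust", n = nrow(df), model = ols))
  }
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["d_sleep", "Estimate"]),
       se = unname(sm["d_sleep", "Std. Error"]),
       p = unname(sm["d_sleep", "Pr(>|t|)"]),
       method = "mixed", n = nrow(df), model = fit)
}

#' Within-subject sleep-deprivation expression contrast
#'
#' Computes the per-subject expression difference (deprived minus typical)
#' and tests its adjusted mean against zero: the difference is regressed on
#' an intercept plus mean-centered covariates (sex, age group, motion on
#' each scan), and the intercept — the covariate-adjusted mean difference —
#' is reported with its t statistic.
#'
#' @param expr_typical,expr_deprived paired expression scores
#' @param sex,age_group optional per-subject covariates
#' @param motion_typical,motion_deprived optional per-scan motion summaries
#' @return list: `mean_diff` (adjusted), `t`, `p`, `n`,
#'   `mean_typical`, `se_typical`, `mean_deprived`, `se_deprived`
#' @export
deprivation_contrast <- function(expr_typical, expr_deprived, sex = NULL,
                                 age_group = NULL, motion_typical = NULL,
                                 motion_deprived = NULL) {
  stopifnot(length(expr_typical) == length(expr_deprived))
  n <- length(expr_typical)
  d <- expr_deprived - expr_typical
  covs <- list(sex = sex, age_group = age_group,
               motion_typical = motion_typical,
               motion_deprived = motion_deprived)
  covs <- covs[!vapply(covs, is.null, TRUE)]
  C <- if (length(covs)) scale(do.call(cbind, lapply(covs, as.numeric)),
                               scale = FALSE) else NULL
  if (n < length(covs) + 2) stop("too few pairs for the covariate model")
  fit <- if (is.null(C)) stats::lm(d ~ 1) else stats::lm(d ~ C)
  sm <- summary(fit)$coefficients
  list(mean_diff = unname(sm["(Intercept)", "Estimate"]),
       t = unname(sm["(Intercept)", "t value"]),
       p = unname(sm["(Intercept)", "Pr(>|t|)"]),
       n = n,
       mean_typical = mean(expr_typical),
       se_typical = stats::sd(expr_typical) / sqrt(n),
       mean_deprived = mean(expr_deprived),
       se_deprived = stats::sd(expr_deprived) / sqrt(n))
}
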