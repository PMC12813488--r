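#' Standard covariate design for sleep neurosignature models
#'
#' Expands a phenotype table into the covariate matrix used throughout the
#' pipeline: sex, age, age squared, mean FD, mean FD squared, plus any
#' extra columns passed through as-is.
#'
#' @param pheno data.frame with columns `sex`, `age_years`, `mean_fd_mm`
#' @param extra optional numeric matrix/data.frame of additional covariates
#' @return numeric matrix, one column per covariate
#' @export
standard_covariates <- function(pheno, extra = NULL) {
  m <- cbind(sex      = as.numeric(pheno$sex),
             age      = pheno$age_years,
             age2     = pheno$age_years^2,
             mean_fd  = pheno$mean_fd_mm,
             mean_fd2 = pheno$mean_fd_mm^2)
  if (!is.null(extra)) m <- cbind(m, as.matrix(extra))
  m
}

#' Residualize an outcome or feature matrix against covariates
#'
#' Fits (or re-applies) an OLS regression of each column on an intercept
#' plus the covariates. When `fit` is supplied, the training coefficients
#' are applied to new rows — the held-out residualization the
#' cross-validation loop requires; fitting on train+test jointly would leak
#' test covariate means into training.
#'
#' @param m numeric vector or matrix (rows = subjects)
#' @param covariates numeric matrix of covariates (no intercept column), or
#'   NULL for intercept-only (mean centering)
#' @param fit optional fit returned in the `fit` attribute of a previous
#'   call, to apply training coefficients to new data
#' @return residual vector/matrix with attribute `fit`
#' @export
residualize <- function(m, covariates = NULL, fit = NULL) {
  vec <- is.null(dim(m))
  M <- as.matrix(m)
  X <- cbind(intercept = rep(1, nrow(M)),
             if (!is.null(covariates)) as.matrix(covariates))
  if (is.null(fit)) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("covariate design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    fit <- list(coef = qr.coef(qrX, M))
  }
  res <- M - X %*% fit$coef
  if (vec) res <- as.numeric(res)
  attr(res, "fit") <- fit
  res
}

.default_grid <- function(n) {
  cap <- max(1, min(floor(n / 10), 250))
  g <- c(1, 2, 4, 8, 16, 21, 32, 64, 128, 250)
  sort(unique(g[g <= cap]))
}

#' Principal-component regression fit
#'
#' PCA on the centered (not per-edge scaled: all edges share the Fisher-z
#' scale) training feature matrix, followed by OLS of the target on the
#' first K component scores. Because the scores are orthogonal, the
#' component betas are independent of K.
#'
#' @param X training feature matrix (subjects x edges)
#' @param y training target
#' @param K number of components (<= rank of centered X)
#' @return object of class `pcr_fit`: `center`, `rotation` (edges x K),
#'   `beta` (K), `intercept`, `weights` (edges; rotation %*% beta)
#' @export
fit_pcr <- function(X, y, K) {
  stopifnot(nrow(X) == length(y), K >= 1)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (K > rank) stop("K = ", K, " exceeds the rank (", rank, ") of the training data")
  V <- sv$v[, seq_len(K), drop = FALSE]
  S <- Xc %*% V
  beta <- as.numeric(crossprod(S, y - mean(y)) / colSums(S^2))
  structure(list(center = ctr, rotation = V, beta = beta,
                 intercept = mean(y),
                 weights = as.numeric(V %*% beta), K = K),
            class = "pcr_fit")
}

#' @param object a `pcr_fit`
#' @param newX feature matrix to predict for
#' @param ... unused
#' @rdname fit_pcr
#' @export
predict.pcr_fit <- function(object, newX, ...) {
  as.numeric(sweep(as.matrix(newX), 2, object$center) %*% object$weights) +
    object$intercept
}

#' One-standard-error component selection by inner cross-validation
#'
#' Over a grid of component counts, computes inner-CV mean squared
#' prediction error with its standard error across folds, then returns the
#' smallest K whose mean error is within one standard error of the minimum
#' (the SE taken at the argmin).
#'
#' @param X training features (already residualized as desired)
#' @param y training target
#' @param grid candidate component counts; default powers-of-2 style up to
#'   min(n/10, 250), always including 21
#' @param inner_folds number of inner folds (default 5)
#' @param fold_ids optional per-row fold assignment (e.g. grouped by site);
#'   when NULL, folds are assigned at random
#' @return list with `K` (selected), `grid`, `mse_mean`, `mse_se`
#' @export
select_components <- function(X, y, grid = NULL, inner_folds = 5,
                              fold_ids = NULL) {
  n <- nrow(X)
  if (is.null(grid)) grid <- .default_grid(n)
  if (is.null(fold_ids)) {
    fold_ids <- sample(rep_len(seq_len(inner_folds), n))
  }
  folds <- unique(fold_ids)
  kmax_fold <- min(vapply(folds, function(f) sum(fold_ids != f), 0L)) - 1L
  grid <- grid[grid <= min(kmax_fold, ncol(X))]
  if (length(grid) == 0) stop("component grid is empty after clamping to the data rank")

  Kmax <- max(grid)
  errs <- matrix(NA_real_, length(folds), length(grid))
  for (fi in seq_along(folds)) {
    te <- fold_ids == folds[fi]
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    ctr <- colMeans(Xtr)
    Xtrc <- sweep(Xtr, 2, ctr)
    sv <- svd(Xtrc, nu = 0, nv = Kmax)
    V <- sv$v
    Str <- Xtrc %*% V
    beta <- as.numeric(crossprod(Str, ytr - mean(ytr)) / colSums(Str^2))
    Ste <- sweep(X[te, , drop = FALSE], 2, ctr) %*% V
    # cumulative contribution of each component to the test prediction
    contrib <- sweep(Ste, 2, beta, "*")
    cum <- t(apply(contrib, 1, cumsum))
    if (sum(te) == 1) cum <- matrix(cumsum(contrib[1, ]), 1)
    for (gi in seq_along(grid)) {
      pred <- mean(ytr) + cum[, grid[gi]]
      errs[fi, gi] <- mean((y[te] - pred)^2)
    }
  }
  mse_mean <- colMeans(errs)
  mse_se <- apply(errs, 2, stats::sd) / sqrt(nrow(errs))
  list(K = one_se_rule(grid, mse_mean, mse_se),
       grid = grid, mse_mean = mse_mean, mse_se = mse_se)
}

#' The one-standard-error selection rule
#'
#' Given a grid of model sizes with cross-validated error means and
#' standard errors, returns the smallest size whose mean error is not more
#' than one standard error (taken at the argmin) above the minimum.
#'
#' @param grid candidate sizes (increasing)
#' @param mean_err,se_err mean CV error and its SE per grid value
#' @return selected grid value
#' @export
one_se_rule <- function(grid, mean_err, se_err) {
  stopifnot(length(grid) > 0, length(grid) == length(mean_err),
            length(grid) == length(se_err))
  if (!any(is.finite(mean_err))) {
    stop("cross-validated errors are all non-finite (degenerate features?)")
  }
  amin <- which.min(mean_err)
  grid[which(mean_err <= mean_err[amin] + se_err[amin])[1]]
}

.fold_ids_by_site <- function(site, inner_folds) {
  sites <- unique(site)
  if (length(sites) >= inner_folds) {
    # spread sites across folds, largest first, to balance fold sizes
    sizes <- sort(table(site), decreasing = TRUE)
    fold_of_site <- stats::setNames(integer(length(sizes)), names(sizes))
    load <- numeric(inner_folds)
    for (s in names(sizes)) {
      k <- which.min(load)
      fold_of_site[s] <- k
      load[k] <- load[k] + sizes[s]
    }
    unname(fold_of_site[as.character(site)])
  } else {
    sample(rep_len(seq_len(inner_folds), length(site)))
  }
}

#' Leave-one-site-out cross-validation of the PCR model
#'
#' For each held-out site: residualize target (and optionally features)
#' with coefficients fitted on the training sites only, select the number
#' of components by nested inner CV with the 1-SE rule, fit PCR on the
#' training sites, and correlate held-out predictions with the held-out
#' residualized target. Accuracy is the mean of the per-site r values.
#'
#' @param X features (subjects x edges)
#' @param y target (e.g. reduced-sleep factor score)
#' @param site per-subject site labels (>= 3 sites)
#' @param covariates covariate matrix (see [standard_covariates()]) or NULL
#' @param grid component grid (default [select_components()]'s default)
#' @param inner_folds inner fold count (default 5, grouped by site when the
#'   training sites allow)
#' @param residualize_X also residualize the features (default TRUE)
#' @return object of class `cv_result`: `per_site` (named r values),
#'   `mean_r`, `K_per_fold`, `n`
#' @export
loso_cv <- function(X, y, site, covariates = NULL, grid = NULL,
                    inner_folds = 5, residualize_X = TRUE) {
  site <- as.character(site)
  sites <- unique(site)
  if (length(sites) < 3) stop("leave-one-site-out needs at least 3 sites")
  r <- stats::setNames(rep(NA_real_, length(sites)), sites)
  Ks <- stats::setNames(rep(NA_integer_, length(sites)), sites)
  for (s in sites) {
    te <- site == s
    if (sum(te) < 2) {
      warning("site ", s, " has fewer than 2 subjects; excluded from held-out correlation")
      next
    }
    ctr_cov <- if (is.null(covariates)) NULL else covariates[!te, , drop = FALSE]
    ytr <- residualize(y[!te], ctr_cov)
    yte <- residualize(y[te],
                       if (is.null(covariates)) NULL else covariates[te, , drop = FALSE],
                       fit = attr(ytr, "fit"))
    if (residualize_X) {
      Xtr <- residualize(X[!te, , drop = FALSE], ctr_cov)
      Xte <- residualize(X[te, , drop = FALSE],
                         if (is.null(covariates)) NULL else covariates[te, , drop = FALSE],
                         fit = attr(Xtr, "fit"))
    } else {
      Xtr <- X[!te, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
    }
    fid <- .fold_ids_by_site(site[!te], inner_folds)
    fold_fit <- tryCatch({
      sel <- select_components(Xtr, ytr, grid = grid,
                               inner_folds = inner_folds, fold_ids = fid)
      list(K = sel$K, pred = predict(fit_pcr(Xtr, ytr, sel$K), Xte))
    }, error = function(e) e)
    if (inherits(fold_fit, "error")) {
      warning("degenerate fold for site ", s, " (", conditionMessage(fold_fit),
              "); r set to NA")
      next
    }
    pred <- fold_fit$pred
    if (stats::sd(pred) == 0 || stats::sd(yte) == 0 ||
        !all(is.finite(pred))) {
      warning("degenerate held-out predictions for site ", s, "; r set to NA")
    } else {
      r[s] <- stats::cor(pred, yte)
    }
    Ks[s] <- fold_fit$K
  }
  structure(list(per_site = r, mean_r = mean(r, na.rm = TRUE),
                 K_per_fold = Ks, n = length(y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> mean r_cv =", signif(x$mean_r, 3),
      "over", length(x$per_site), "held-out sites\n")
  cat("  K per fold:", paste(x$K_per_fold, collapse = ", "), "\n")
  invisible(x)
}

#' Round half up (ties upward)
#' @param x numeric
#' @return nearest integer, .5 rounded up
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Haufe activation-pattern transform
#'
#' Converts prediction weights (a backward/decoding model) into an
#' interpretable activation pattern: the covariance of each feature with
#' the predicted score, rescaled by the prediction variance —
#' pattern = Cov(X) w / Var(X w).
#'
#' @param X training feature matrix (residualized, subjects x edges)
#' @param weights prediction weight vector (length = edges)
#' @return numeric pattern vector, same length as `weights`
#' @export
haufe_transform <- function(X, weights) {
  Xc <- sweep(X, 2, colMeans(X))
  yhat <- as.numeric(Xc %*% weights)
  v <- stats::var(yhat)
  if (v <= 0) stop("predicted scores have zero variance; Haufe pattern undefined")
  as.numeric(crossprod(Xc, yhat - mean(yhat)) / (nrow(X) - 1)) / v
}

#' Build the full-sample neurosignature
#'
#' Residualizes target (and optionally features) on the whole sample, fits
#' PCR with the given component count (typically the rounded mean of the
#' per-fold counts from [loso_cv()]), and collapses the component basis and
#' betas into a single edge-weight map whose dot product with a centered
#' connectome yields the predicted score. The Haufe pattern is attached for
#' interpretation.
#'
#' @param X features (subjects x edges)
#' @param y target
#' @param covariates covariate matrix or NULL
#' @param K component count
#' @param networks per-parcel network labels carried as edge metadata
#' @param residualize_X also residualize features (default TRUE)
#' @return object of class `neurosignature`: `weights`, `haufe`,
#'   `n_components`, `center`, `intercept`, `networks`, `covariate_names`,
#'   `n`
#' @export
build_signature <- function(X, y, covariates = NULL, K, networks,
                            residualize_X = TRUE) {
  stopifnot(length(networks) * (length(networks) - 1) / 2 == ncol(X))
  yr <- residualize(y, covariates)
  Xr <- if (residualize_X) residualize(X, covariates) else X
  fit <- fit_pcr(Xr, yr, K)
  structure(list(
    weights = fit$weights,
    haufe = haufe_transform(Xr, fit$weights),
    n_components = K,
    center = fit$center,
    intercept = fit$intercept,
    networks = as.character(networks),
    covariate_names = colnames(covariates),
    n = nrow(X)
  ), class = "neurosignature")
}

#' @export
print.neurosignature <- function(x, ...) {
  cat("<neurosignature> ", length(x$weights), " edges, ",
      x$n_components, " components, trained on n = ", x$n, "\n", sep = "")
  invisible(x)
}
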