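#' Contrast signature from a paired two-session design
#'
#' Builds an edge-weight map of a within-subject manipulation (e.g. sleep
#' deprivation) in a way that parallels the PCR signature: covariates are
#' regressed out of every connectome, a PCA is run on the stacked
#' (both-session) residuals, per-subject differences in component scores
#' (deprived minus typical) are averaged across subjects, and the mean
#' difference vector is multiplied back through the first K component
#' loadings to give a single spatial map.
#'
#' @param typical,deprived subjects x edges matrices, row-paired
#' @param cov_typical,cov_deprived per-session covariate matrices with
#'   identical columns (e.g. sex, age group, per-scan motion); NULL to skip
#'   residualization
#' @param K number of components (default 21); must not exceed the rank of
#'   the stacked residuals
#' @param networks per-parcel network labels
#' @return object of class `contrast_signature`: `weights`,
#'   `n_components`, `networks`, `mean_dscore` (length K)
#' @export
contrast_signature <- function(typical, deprived, cov_typical = NULL,
                               cov_deprived = NULL, K = 21, networks) {
  stopifnot(nrow(typical) == nrow(deprived), ncol(typical) == ncol(deprived))
  n <- nrow(typical)
  stacked <- rbind(typical, deprived)
  covs <- if (!is.null(cov_typical)) rbind(as.matrix(cov_typical),
                                           as.matrix(cov_deprived)) else NULL
  res <- residualize(stacked, covs)
  ctr <- colMeans(res)
  Xc <- sweep(res, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (K > rank) stop("K = ", K, " exceeds the rank (", rank, ") of the stacked residuals")
  V <- sv$v[, seq_len(K), drop = FALSE]
  S <- Xc %*% V
  dscore <- S[n + seq_len(n), , drop = FALSE] - S[seq_len(n), , drop = FALSE]
  md <- colMeans(dscore)
  structure(list(weights = as.numeric(V %*% md),
                 n_components = K,
                 networks = as.character(networks),
                 mean_dscore = md,
                 rotation = V,
                 dscore = dscore),
            class = "contrast_signature")
}

#' @export
print.contrast_signature <- function(x, ...) {
  cat("<contrast_signature> ", length(x$weights), " edges, ",
      x$n_components, " components\n", sep = "")
  invisible(x)
}

.map_values <- function(x, map = "weights") {
  if (is.numeric(x) && is.null(dim(x))) return(as.numeric(x))
  v <- if (map == "haufe" && !is.null(x$haufe)) x$haufe
       else if (!is.null(x$weights)) x$weights
       else x$values
  as.numeric(v)
}

#' Spatial correlation between two edge maps
#'
#' Pearson correlation across the edge dimension. When both maps carry
#' network metadata the edge ordering is checked first.
#'
#' @param sig_a,sig_b signatures, edge vectors, or numeric vectors
#' @param map_a,map_b which map to use per side (`"weights"` or `"haufe"`)
#' @return correlation across edges
#' @export
spatial_correlation <- function(sig_a, sig_b, map_a = "weights",
                                map_b = "weights") {
  if (is.list(sig_a) && is.list(sig_b) &&
      !is.null(sig_a$networks) && !is.null(sig_b$networks) &&
      !same_edge_order(sig_a, sig_b)) {
    stop("edge ordering mismatch between the two maps")
  }
  a <- .map_values(sig_a, map_a)
  b <- .map_values(sig_b, map_b)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance map")
  stats::cor(a, b)
}

#' Dual-permutation null for spatial correspondence
#'
#' Tests whether two independently derived signatures correspond spatially
#' beyond chance. Per iteration, (a) the cross-sectional signature is
#' rebuilt with target scores shuffled across subjects (feature PCA held
#' fixed; component betas refit), and (b) the paired-contrast signature is
#' rebuilt with each subject's session labels flipped by a fair coin
#' (which negates that subject's component-score difference). The spatial
#' correlation of the two permuted maps forms the null distribution; the
#' p-value uses (b + 1)/(B + 1) counting and is one-sided (greater) by
#' default.
#'
#' @param X,y,covariates cross-sectional features, target, covariates
#' @param K_x components for the cross-sectional signature
#' @param typical,deprived,cov_typical,cov_deprived paired-design inputs as
#'   in [contrast_signature()]
#' @param K_c components for the contrast signature (default = K_x)
#' @param networks per-parcel network labels (shared edge ordering)
#' @param B permutations (>= 100; the study-scale run uses 10,000)
#' @param use_haufe correlate the cross-sectional Haufe pattern (default
#'   TRUE) rather than the raw prediction weights
#' @param residualize_X residualize cross-sectional features (default TRUE)
#' @param sided `"greater"` (default) or `"two.sided"`
#' @return list: `observed` (spatial r), `null`, `p`, `sig_x`, `sig_c`
#' @export
dual_permutation_null <- function(X, y, covariates = NULL, K_x,
                                  typical, deprived,
                                  cov_typical = NULL, cov_deprived = NULL,
                                  K_c = K_x, networks, B = 10000,
                                  use_haufe = TRUE, residualize_X = TRUE,
                                  sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(B >= 100)
  n <- nrow(X)

  # cross-sectional side: PCA fixed, betas refit per permuted target
  yr <- residualize(y, covariates)
  Xr <- if (residualize_X) residualize(X, covariates) else X
  Xc <- sweep(Xr, 2, colMeans(Xr))
  sv <- svd(Xc, nu = 0, nv = K_x)
  V <- sv$v
  S <- Xc %*% V
  ss <- colSums(S^2)
  d2 <- sv$d[seq_len(K_x)]^2 / (n - 1)   # cov(X, score_k) = V_k * d2_k

  map_x <- function(yp) {
    beta <- as.numeric(crossprod(S, yp - mean(yp)) / ss)
    if (use_haufe) {
      vy <- sum(beta^2 * d2) * (n - 1) / (n - 1)
      if (vy <= 0) return(NULL)
      as.numeric(V %*% (beta * d2)) / vy
    } else {
      as.numeric(V %*% beta)
    }
  }

  # paired side: stacked PCA is invariant to session-label flips
  sig_c <- contrast_signature(typical, deprived, cov_typical, cov_deprived,
                              K = K_c, networks = networks)
  map_c <- function(flip) {
    as.numeric(sig_c$rotation %*% colMeans(sig_c$dscore * flip))
  }

  obs_x <- map_x(yr)
  obs_c <- sig_c$weights
  observed <- stats::cor(obs_x, obs_c)

  null <- numeric(B)
  b <- 1L
  redraws <- 0L
  while (b <= B) {
    mx <- map_x(yr[sample.int(n)])
    mc <- map_c(sample(c(-1, 1), nrow(typical), replace = TRUE))
    if (is.null(mx) || stats::sd(mx) == 0 || stats::sd(mc) == 0) {
      redraws <- redraws + 1L
      if (redraws > B) stop("too many degenerate null maps")
      next
    }
    null[b] <- stats::cor(mx, mc)
    b <- b + 1L
  }
  p <- if (sided == "greater") (1 + sum(null >= observed)) / (B + 1)
       else (1 + sum(abs(null) >= abs(observed))) / (B + 1)
  list(observed = observed, null = null, p = p,
       sig_x = obs_x, sig_c = sig_c, n_redrawn = redraws)
}
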