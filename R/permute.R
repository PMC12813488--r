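#' Nested exchangeability blocks (site / family / twin)
#'
#' Encodes the permutation constraints of a multisite family study:
#' subjects never cross sites; families move as whole units within their
#' site (among families of the same size); members — including twins —
#' permute within their family. Twin pairs must share a family; families
#' must be nested in exactly one site.
#'
#' @param site per-subject site labels
#' @param family per-subject family labels (default: every subject its own
#'   family)
#' @param twin_pair optional per-subject twin-pair labels (NA for
#'   non-twins); validated to lie within a single family
#' @return object of class `exchangeability_blocks`
#' @export
exchangeability_blocks <- function(site, family = NULL, twin_pair = NULL) {
  n <- length(site)
  site <- as.character(site)
  if (is.null(family)) family <- paste0("f", seq_len(n))
  family <- as.character(family)
  stopifnot(length(family) == n)

  fam_sites <- tapply(site, family, function(s) length(unique(s)))
  if (any(fam_sites > 1)) {
    stop("malformed nesting: family crosses sites: ",
         paste(names(fam_sites)[fam_sites > 1], collapse = ", "))
  }
  if (!is.null(twin_pair)) {
    tp <- as.character(twin_pair)
    ok <- !is.na(twin_pair)
    if (any(ok)) {
      pair_fams <- tapply(family[ok], tp[ok], function(f) length(unique(f)))
      if (any(pair_fams > 1)) {
        stop("malformed nesting: twin pair spans families: ",
             paste(names(pair_fams)[pair_fams > 1], collapse = ", "))
      }
    }
  }

  # per site: family index vectors grouped by family size, so whole
  # families can swap positions with same-sized families only
  sites <- split(seq_len(n), site)
  tree <- lapply(sites, function(idx) {
    fams <- split(idx, family[idx])
    split(fams, vapply(fams, length, 0L))
  })
  structure(list(n = n, site = site, family = family,
                 twin_pair = twin_pair, tree = tree),
            class = "exchangeability_blocks")
}

#' @export
print.exchangeability_blocks <- function(x, ...) {
  cat("<exchangeability_blocks> n =", x$n, ";",
      length(unique(x$site)), "sites;",
      length(unique(x$family)), "families\n")
  invisible(x)
}

#' Draw one block-respecting permutation
#'
#' Returns an index vector `perm` such that `y[perm]` is a valid
#' rearrangement: within each site, same-sized families swap positions as
#' intact units, and members shuffle within each family. Site labels never
#' cross.
#'
#' @param blocks an [exchangeability_blocks()] object
#' @return integer permutation of 1..n
#' @export
sample_permutation <- function(blocks) {
  perm <- integer(blocks$n)
  for (site_tree in blocks$tree) {
    for (size_class in site_tree) {
      nf <- length(size_class)
      fam_order <- if (nf > 1) sample.int(nf) else 1L
      for (k in seq_len(nf)) {
        slots <- size_class[[k]]                 # positions of family k
        members <- size_class[[fam_order[k]]]    # family placed there
        if (length(members) > 1) members <- members[sample.int(length(members))]
        perm[slots] <- members
      }
    }
  }
  perm
}

#' Check a permutation against the block constraints
#'
#' @param blocks an [exchangeability_blocks()] object
#' @param perm integer permutation
#' @return TRUE iff sites are preserved position-wise and every family's
#'   slot set is filled by exactly one same-sized source family
#' @export
validate_permutation <- function(blocks, perm) {
  if (!identical(sort(perm), seq_len(blocks$n))) return(FALSE)
  if (!all(blocks$site[perm] == blocks$site)) return(FALSE)
  src <- split(blocks$family[perm], blocks$family)
  all(vapply(src, function(f) length(unique(f)) == 1, TRUE)) &&
    all(vapply(names(src), function(f) {
      sum(blocks$family == src[[f]][1]) == length(src[[f]])
    }, TRUE))
}

#' Freedman-Lane permutation test with exchangeability blocks
#'
#' Nuisance-respecting permutation inference: fit the reduced model
#' (outcome on covariates only), permute its residuals by block-respecting
#' orderings, reconstruct pseudo-outcomes y* = fitted + permuted residuals,
#' and recompute the statistic on each y*. With no covariates the procedure
#' reduces to plain permutation of the outcome. The p-value uses the
#' (b + 1) / (B + 1) counting convention, so B = 10,000 bounds p below at
#' about 0.0001.
#'
#' @param y outcome vector
#' @param covariates nuisance covariate matrix or NULL
#' @param blocks an [exchangeability_blocks()] object
#' @param B number of permutations (>= 100)
#' @param statistic function of a single argument (the pseudo-outcome)
#'   returning a scalar; typically a closure over the feature matrix
#' @param alternative `"greater"` (default) or `"two.sided"` (on absolute
#'   values)
#' @return list: `observed`, `null` (length <= B), `p`, `n_dropped`
#' @export
freedman_lane_null <- function(y, covariates = NULL, blocks, B, statistic,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(B >= 100, inherits(blocks, "exchangeability_blocks"),
            length(y) == blocks$n)
  X0 <- cbind(rep(1, length(y)),
              if (!is.null(covariates)) as.matrix(covariates))
  qr0 <- qr(X0)
  fitted <- as.numeric(X0 %*% qr.coef(qr0, y))
  resid <- y - fitted

  observed <- statistic(y)
  null <- numeric(B)
  dropped <- 0L
  for (b in seq_len(B)) {
    ystar <- fitted + resid[sample_permutation(blocks)]
    s <- statistic(ystar)
    if (!is.finite(s)) {
      dropped <- dropped + 1L
      null[b] <- NA_real_
    } else {
      null[b] <- s
    }
  }
  if (dropped > 0.01 * B) {
    stop(dropped, " of ", B, " permutation statistics were non-finite (> 1%)")
  }
  null <- null[is.finite(null)]
  p <- if (alternative == "greater") {
    (1 + sum(null >= observed)) / (length(null) + 1)
  } else {
    (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
  }
  list(observed = observed, null = null, p = p, n_dropped = dropped)
}

#' In-sample multivariate r statistic for permutation inference
#'
#' Builds the statistic closure used to assess significance of the
#' PCR association: the feature PCA is computed once on the residualized
#' features; for each pseudo-outcome the component betas are refit and the
#' statistic is the in-sample correlation between the pseudo-outcome
#' (residualized against the covariates) and its PCR prediction at fixed K.
#' This keeps the pipeline fixed across permutations, refitting only what
#' depends on the outcome.
#'
#' @param X feature matrix (subjects x edges)
#' @param covariates covariate matrix or NULL (applied to the outcome
#'   inside the statistic; features are residualized once here)
#' @param K component count
#' @param residualize_X residualize features before PCA (default TRUE)
#' @return function(y) -> scalar in-sample r
#' @export
insample_r_statistic <- function(X, covariates = NULL, K,
                                 residualize_X = TRUE) {
  Xr <- if (residualize_X) residualize(X, covariates) else X
  Xc <- sweep(Xr, 2, colMeans(Xr))
  sv <- svd(Xc, nu = 0, nv = K)
  S <- Xc %*% sv$v
  ss <- colSums(S^2)
  force(covariates)
  function(y) {
    yr <- residualize(y, covariates)
    beta <- as.numeric(crossprod(S, yr - mean(yr)) / ss)
    yhat <- as.numeric(S %*% beta)
    if (stats::sd(yhat) == 0) return(NA_real_)
    stats::cor(yr, yhat)
  }
}
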