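#' Parcellated run time series
#'
#' Bundles one resting-state run: a volumes x parcels matrix, the repetition
#' time, the per-volume framewise displacement (FD, mm) trace, and a nuisance
#' regressor table (motion parameters, component regressors, any extra
#' columns). Validation enforces matching lengths and no missing values.
#'
#' @param data numeric matrix, volumes x parcels
#' @param tr_seconds repetition time in seconds (> 0)
#' @param fd_mm per-volume framewise displacement, mm, non-negative,
#'   length nrow(data)
#' @param nuisance optional numeric matrix of nuisance regressors with
#'   nrow(data) rows
#' @return object of class `run_timeseries`
#' @export
run_timeseries <- function(data, tr_seconds, fd_mm, nuisance = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) stop("time series contains missing or non-finite values")
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1, tr_seconds > 0)
  if (length(fd_mm) != nrow(data)) stop("fd_mm length must equal volume count")
  if (any(fd_mm < 0)) stop("framewise displacement must be non-negative")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(data)) stop("nuisance rows must equal volume count")
    if (anyNA(nuisance)) stop("nuisance regressors contain missing values")
  }
  structure(list(data = data, tr_seconds = tr_seconds,
                 fd_mm = as.numeric(fd_mm), nuisance = nuisance),
            class = "run_timeseries")
}

#' Motion-censoring mask
#'
#' Volumes *exceeding* the FD threshold are marked for censoring; a volume
#' exactly at the threshold is kept (strict inequality).
#'
#' @param fd_mm per-volume framewise displacement in mm
#' @param threshold_mm censoring threshold, default 0.5 mm
#' @return logical keep-mask, TRUE where fd_mm <= threshold_mm
#' @export
censor_mask <- function(fd_mm, threshold_mm = 0.5) {
  if (any(fd_mm < 0)) stop("framewise displacement must be non-negative")
  stopifnot(threshold_mm > 0)
  fd_mm <= threshold_mm
}

#' Run eligibility after censoring
#'
#' A run is usable when the retained volumes amount to at least
#' `min_minutes` of data.
#'
#' @param mask logical keep-mask from [censor_mask()]
#' @param tr_seconds repetition time in seconds
#' @param min_minutes minimum retained duration, default 4 minutes
#' @return TRUE iff sum(mask) * tr_seconds >= min_minutes * 60
#' @export
run_eligible <- function(mask, tr_seconds, min_minutes = 4) {
  stopifnot(length(mask) > 0, tr_seconds > 0)
  sum(mask) * tr_seconds >= min_minutes * 60
}

#' Discrete-cosine high-pass basis
#'
#' DCT-II columns covering frequencies strictly below `highpass_hz`; these
#' are entered as regressors so that removing them high-pass filters the
#' data inside the single cleaning regression.
#'
#' @param n_volumes number of volumes
#' @param tr_seconds repetition time in seconds
#' @param highpass_hz cutoff frequency, default 0.008 Hz
#' @return matrix n_volumes x K (K may be 0)
#' @export
dct_basis <- function(n_volumes, tr_seconds, highpass_hz = 0.008) {
  K <- floor(2 * n_volumes * tr_seconds * highpass_hz)
  if (K < 1) return(matrix(0, n_volumes, 0))
  t <- seq_len(n_volumes) - 0.5
  sapply(seq_len(K), function(k) cos(pi * t * k / n_volumes))
}

#' Nuisance regression of a run in a single step
#'
#' Regresses out, jointly in one multiple regression per parcel: an
#' intercept, a linear trend, the run's nuisance columns, a discrete-cosine
#' high-pass basis up to `highpass_hz`, and one spike regressor per censored
#' volume. Collinear design columns are dropped with a warning. Censored
#' volumes end up with residuals of exactly zero (the spike regressors
#' absorb them) and are additionally excluded from downstream correlation
#' via the `keep` attribute.
#'
#' @param run a [run_timeseries()] object
#' @param mask logical keep-mask; default computed from the run's FD at
#'   0.5 mm
#' @param highpass_hz high-pass cutoff in Hz; set to 0 or NULL to disable
#' @param detrend include a linear trend column (default TRUE)
#' @return cleaned volumes x parcels matrix with attribute `keep` (the mask)
#' @export
clean_timeseries <- function(run, mask = NULL, highpass_hz = 0.008,
                             detrend = TRUE) {
  stopifnot(inherits(run, "run_timeseries"))
  Y <- run$data
  n <- nrow(Y)
  if (is.null(mask)) mask <- censor_mask(run$fd_mm)
  stopifnot(length(mask) == n)

  X <- matrix(1, n, 1)
  if (detrend) X <- cbind(X, seq_len(n) - (n + 1) / 2)
  if (!is.null(run$nuisance) && ncol(run$nuisance) > 0) X <- cbind(X, run$nuisance)
  if (!is.null(highpass_hz) && highpass_hz > 0) {
    X <- cbind(X, dct_basis(n, run$tr_seconds, highpass_hz))
  }
  censored <- which(!mask)
  if (length(censored) > 0) {
    spikes <- matrix(0, n, length(censored))
    spikes[cbind(censored, seq_along(censored))] <- 1
    X <- cbind(X, spikes)
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning("dropping ", length(drop), " collinear design column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    qrX <- qr(X)
  }
  res <- Y - X %*% qr.coef(qrX, Y)
  attr(res, "keep") <- mask
  res
}

#' Fisher r-to-z connectome averaged across runs
#'
#' Per run, computes the Pearson correlation matrix over retained volumes,
#' applies the Fisher r-to-z transform (atanh), averages z across runs, and
#' vectorizes the upper triangle in the package's fixed row-major order.
#' Perfect correlations are clipped to +/- (1 - 1e-7) before atanh with a
#' warning.
#'
#' @param runs list of cleaned run matrices from [clean_timeseries()]
#'   (each carrying a `keep` attribute; a plain matrix is treated as fully
#'   retained)
#' @param networks per-parcel network labels for the resulting edge vector
#' @return an [edge_vector()] of averaged z values
#' @export
connectome_from_runs <- function(runs, networks) {
  stopifnot(length(runs) >= 1)
  zs <- lapply(runs, function(m) {
    keep <- attr(m, "keep")
    if (is.null(keep)) keep <- rep(TRUE, nrow(m))
    r <- stats::cor(m[keep, , drop = FALSE])
    lim <- 1 - 1e-7
    if (any(abs(vec_upper(r)) >= lim)) {
      warning("|r| = 1 encountered; clipping before Fisher transform")
      r[r > lim] <- lim
      r[r < -lim] <- -lim
    }
    atanh(vec_upper(r))
  })
  z <- Reduce(`+`, zs) / length(zs)
  edge_vector(z, networks)
}

#' Build one subject's connectome from raw runs
#'
#' Applies the full per-subject path: censor by FD, drop ineligible runs,
#' clean eligible runs in a single regression step, correlate over retained
#' volumes, Fisher-transform, and average across runs.
#'
#' @param runs list of [run_timeseries()] objects
#' @param networks per-parcel network labels
#' @param fd_threshold_mm censoring threshold (default 0.5 mm)
#' @param min_minutes minimum retained duration per run (default 4)
#' @param highpass_hz high-pass cutoff (default 0.008 Hz)
#' @return list with `connectome` (an [edge_vector()] or NULL if no run was
#'   eligible) and `n_runs_used`
#' @export
subject_connectome <- function(runs, networks, fd_threshold_mm = 0.5,
                               min_minutes = 4, highpass_hz = 0.008) {
  cleaned <- list()
  for (run in runs) {
    mask <- censor_mask(run$fd_mm, fd_threshold_mm)
    if (!run_eligible(mask, run$tr_seconds, min_minutes)) next
    cleaned[[length(cleaned) + 1L]] <-
      clean_timeseries(run, mask, highpass_hz = highpass_hz)
  }
  if (length(cleaned) == 0) {
    return(list(connectome = NULL, n_runs_used = 0L))
  }
  list(connectome = connectome_from_runs(cleaned, networks),
       n_runs_used = length(cleaned))
}
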