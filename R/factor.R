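#' Fit the three-indicator latent sleep-duration factor
#'
#' A single factor measured by three indicators (parent-reported duration,
#' child-reported duration, device-measured duration) is just-identified:
#' the standardized loadings have the closed form
#' lambda_1 = sqrt(r12 * r13 / r23) (and rotations thereof), and the fitted
#' model reproduces the observed 3x3 correlation matrix exactly, so no fit
#' indices exist. All three pairwise correlations must be positive; an
#' implied loading >= 1 (Heywood case) is an error.
#'
#' Scoring weights are the regression (Thurstone) method,
#' w = R^-1 lambda, applied to indicators standardized with the training
#' means/SDs stored in the model.
#'
#' @param indicators numeric matrix or data.frame with 3 columns; rows with
#'   missing values are dropped (complete-case, with a message)
#' @return object of class `sleep_factor_model` with fields `loadings`,
#'   `uniquenesses`, `scoring_weights`, `means`, `sds`, `correlations`, `n`
#' @export
fit_factor <- function(indicators) {
  ind <- as.matrix(indicators)
  if (ncol(ind) != 3) stop("exactly 3 indicators are required")
  cc <- stats::complete.cases(ind)
  if (!all(cc)) message("dropping ", sum(!cc), " incomplete row(s) for factor fit")
  ind <- ind[cc, , drop = FALSE]
  if (nrow(ind) < 10) stop("need at least 10 complete observations")
  R <- stats::cor(ind)
  r12 <- R[1, 2]; r13 <- R[1, 3]; r23 <- R[2, 3]
  if (min(r12, r13, r23) <= 0) {
    stop("all pairwise indicator correlations must be positive")
  }
  lam <- c(sqrt(r12 * r13 / r23),
           sqrt(r12 * r23 / r13),
           sqrt(r13 * r23 / r12))
  if (any(lam >= 1)) {
    bad <- which(lam >= 1)
    stop("Heywood case: implied loading >= 1 for indicator(s) ",
         paste(bad, collapse = ", "),
         " (triad r12=", signif(r12, 4), ", r13=", signif(r13, 4),
         ", r23=", signif(r23, 4), ")")
  }
  structure(list(
    loadings        = lam,
    uniquenesses    = 1 - lam^2,
    scoring_weights = as.numeric(solve(R, lam)),
    means           = colMeans(ind),
    sds             = apply(ind, 2, stats::sd),
    correlations    = R,
    n               = nrow(ind)
  ), class = "sleep_factor_model")
}

#' @export
print.sleep_factor_model <- function(x, ...) {
  cat("<sleep_factor_model> one factor, 3 indicators (just-identified)\n")
  cat("  loadings:    ", paste(signif(x$loadings, 3), collapse = ", "), "\n")
  cat("  determinacy: ", signif(factor_determinacy(x), 3), "\n")
  invisible(x)
}

#' Factor-score determinacy
#'
#' The maximal correlation attainable between regression-method factor
#' scores and the true latent variable: sqrt(lambda' R^-1 lambda).
#'
#' @param model a [fit_factor()] model
#' @return scalar in (0, 1)
#' @export
factor_determinacy <- function(model) {
  sqrt(sum(model$scoring_weights * model$loadings))
}

#' Per-subject factor scores
#'
#' Regression-method scores on indicators standardized with the training
#' means/SDs. Higher scores mean longer sleep; `orientation = "reduced"`
#' negates the score so that higher values mean *shorter* sleep, the target
#' of the predictive neurosignature. Subjects with any missing indicator
#' get NA and are reported.
#'
#' @param model a [fit_factor()] model
#' @param indicators matrix/data.frame with the 3 indicator columns in
#'   training order
#' @param orientation `"duration"` (default) or `"reduced"`
#' @return numeric vector of scores (NA for incomplete rows)
#' @export
factor_scores <- function(model, indicators,
                          orientation = c("duration", "reduced")) {
  orientation <- match.arg(orientation)
  ind <- as.matrix(indicators)
  stopifnot(ncol(ind) == 3)
  cc <- stats::complete.cases(ind)
  if (!all(cc)) message(sum(!cc), " subject(s) dropped: missing sleep indicator")
  z <- sweep(sweep(ind, 2, model$means, "-"), 2, model$sds, "/")
  s <- as.numeric(z %*% model$scoring_weights)
  s[!cc] <- NA_real_
  if (orientation == "reduced") -s else s
}

#' Weighted average of school-day and free-day sleep duration
#'
#' Standard 5:2 weekday/weekend weighting of daily sleep duration.
#'
#' @param weekday_hours,weekend_hours non-negative durations in hours
#' @param weights length-2 weights, default c(5, 2)
#' @return (5 * weekday + 2 * weekend) / 7 by default
#' @export
weighted_average_duration <- function(weekday_hours, weekend_hours,
                                      weights = c(5, 2)) {
  if (any(weekday_hours < 0, na.rm = TRUE) || any(weekend_hours < 0, na.rm = TRUE)) {
    stop("durations must be non-negative")
  }
  (weights[1] * weekday_hours + weights[2] * weekend_hours) / sum(weights)
}
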