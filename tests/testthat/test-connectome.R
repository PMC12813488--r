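test_that("censoring keeps volumes at or below the FD threshold", {
  expect_equal(censor_mask(c(0.2, 0.6, 0.3)), c(TRUE, FALSE, TRUE))
  expect_true(all(censor_mask(rep(0, 10))))
  expect_true(censor_mask(0.5))        # boundary: not "exceeding"
  expect_error(censor_mask(c(0.1, -0.2)), "non-negative")
})

test_that("run eligibility requires four retained minutes", {
  expect_true(run_eligible(rep(TRUE, 300), 0.8))    # 240 s exactly
  expect_false(run_eligible(rep(TRUE, 299), 0.8))
  expect_true(run_eligible(rep(TRUE, 100), 2.4))
  expect_false(run_eligible(c(rep(TRUE, 99), FALSE), 2.4))
})

test_that("cleaning with empty design reduces to per-parcel detrend", {
  set.seed(31)
  Y <- matrix(rnorm(200), 50, 4) + outer(1:50, c(0.1, -0.2, 0, 0.3))
  run <- run_timeseries(Y, 2, rep(0, 50))
  cleaned <- clean_timeseries(run, highpass_hz = 0)
  ref <- apply(Y, 2, function(y) residuals(lm(y ~ seq_len(50))))
  expect_equal(unname(cleaned[, ]), unname(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a parcel equal to a nuisance column is annihilated", {
  set.seed(32)
  nuis <- matrix(rnorm(300), 100, 3)
  Y <- cbind(nuis[, 2], rnorm(100))
  run <- run_timeseries(Y, 2, rep(0, 100), nuisance = nuis)
  cleaned <- clean_timeseries(run)
  expect_lt(max(abs(cleaned[, 1])), 1e-10)
})

test_that("spike regressors zero out censored volumes exactly", {
  set.seed(33)
  fd <- rep(0.1, 80)
  fd[c(10, 41)] <- 0.9
  run <- run_timeseries(matrix(rnorm(80 * 3), 80), 2.4, fd,
                        nuisance = matrix(rnorm(160), 80))
  cleaned <- clean_timeseries(run)
  expect_lt(max(abs(cleaned[c(10, 41), ])), 1e-10)
  expect_equal(attr(cleaned, "keep"), fd <= 0.5)
})

test_that("cleaning is idempotent", {
  set.seed(34)
  fd <- c(rep(0.1, 95), rep(0.8, 5))
  run <- run_timeseries(matrix(rnorm(100 * 5), 100), 2.4, fd,
                        nuisance = matrix(rnorm(200), 100))
  once <- clean_timeseries(run)
  run2 <- run_timeseries(unclass(once)[seq_len(100), ], 2.4, fd,
                         nuisance = run$nuisance)
  twice <- clean_timeseries(run2)
  expect_lt(max(abs(twice - once)), 1e-10)
})

test_that("Fisher-z connectomes average across runs and match atanh", {
  # exact sample correlation 0.5 between two parcels
  d <- exact_cor_data(120, matrix(c(1, 0.5, 0.5, 1), 2), seed = 35)
  one <- connectome_from_runs(list(d), networks = c("SMN", "VIS"))
  expect_equal(one$values, atanh(0.5), tolerance = 1e-10)
  expect_equal(one$values, 0.549306, tolerance = 1e-6)

  two <- connectome_from_runs(list(d, d), networks = c("SMN", "VIS"))
  expect_equal(two$values, one$values)   # identical runs: average = single

  z0 <- connectome_from_runs(list(exact_cor_data(90, diag(3), seed = 36)),
                             networks = c("A", "B", "C"))
  expect_equal(z0$values, rep(0, 3), tolerance = 1e-10)
})

test_that("perfect correlations are clipped with a warning", {
  x <- rnorm(50)
  m <- cbind(x, x)
  expect_warning(ev <- connectome_from_runs(list(m), c("A", "B")),
                 "clipping")
  expect_true(is.finite(ev$values))
})

test_that("subject connectomes skip ineligible runs", {
  set.seed(37)
  good <- run_timeseries(matrix(rnorm(120 * 3), 120), 2.4, rep(0.1, 120))
  bad <- run_timeseries(matrix(rnorm(50 * 3), 50), 2.4, rep(0.1, 50))
  res <- subject_connectome(list(good, bad), networks = c("A", "B", "C"))
  expect_equal(res$n_runs_used, 1L)
  res0 <- subject_connectome(list(bad), networks = c("A", "B", "C"))
  expect_null(res0$connectome)
})

test_that("run validation rejects malformed inputs", {
  expect_error(run_timeseries(matrix(c(1, NA, 2, 3), 2), 1, c(0, 0)), "missing")
  expect_error(run_timeseries(matrix(rnorm(4), 2), 1, c(0.1, -0.1)),
               "non-negative")
  expect_error(run_timeseries(matrix(rnorm(4), 2), 1, c(0.1, 0.1, 0.1)),
               "length")
})
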