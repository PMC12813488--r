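test_that("residualization is exact and train-fitted for held-out rows", {
  set.seed(61)
  y <- rnorm(50)
  expect_equal(residualize(y, NULL), y - mean(y), ignore_attr = TRUE)

  C <- cbind(rnorm(50), rnorm(50))
  r <- residualize(y, C)
  expect_lt(max(abs(cor(r, C))), 1e-10)
  expect_lt(max(abs(residualize(C[, 1], C))), 1e-10)

  # training betas applied to test rows differ from joint residualization
  # whenever the test covariate means differ
  Ctr <- cbind(rnorm(40))
  Cte <- cbind(rnorm(10) + 5)
  ytr <- 2 * Ctr[, 1] + rnorm(40, 0, 0.1)
  yte <- 2 * Cte[, 1] + rnorm(10, 0, 0.1)
  proper <- residualize(yte, Cte, fit = attr(residualize(ytr, Ctr), "fit"))
  joint <- residualize(c(ytr, yte), rbind(Ctr, Cte))[41:50]
  expect_gt(max(abs(proper - joint)), 0.01)

  expect_error(residualize(y, cbind(C, C[, 1])), "rank deficient")
})

test_that("the 1-SE rule picks the smallest model within one SE", {
  expect_equal(one_se_rule(c(1, 2, 4, 8), rep(3, 4), rep(0.1, 4)), 1)
  expect_equal(one_se_rule(c(1, 2, 4, 8), c(8, 6, 4, 2), rep(1e-9, 4)), 8)
  expect_equal(one_se_rule(c(1, 2, 4, 8), c(10, 5, 4.9, 4.85),
                           c(0.5, 0.3, 0.25, 0.2)), 2)
})

test_that("nested selection runs on real folds and clamps the grid", {
  set.seed(62)
  X <- matrix(rnorm(60 * 30), 60)
  y <- X[, 1] + rnorm(60, 0, 0.5)
  sel <- select_components(X, y, grid = c(1, 2, 4, 8, 16), inner_folds = 5)
  expect_true(sel$K %in% sel$grid)
  expect_error(select_components(X, y, grid = 500), "empty")
})

test_that("PCR at full rank equals OLS", {
  set.seed(63)
  X <- matrix(rnorm(40 * 20), 40)
  y <- rnorm(40)
  fit <- fit_pcr(X, y, 20)
  ols <- lm(y ~ X)
  expect_lt(max(abs(predict(fit, X) - fitted(ols))), 1e-8)
})

test_that("PCR handles degenerate targets and duplicated samples", {
  set.seed(64)
  X <- matrix(rnorm(30 * 10), 30)
  expect_lt(max(abs(fit_pcr(X, rep(2, 30), 5)$beta)), 1e-10)

  y <- rnorm(30)
  w1 <- fit_pcr(X, y, 4)$weights
  w2 <- fit_pcr(rbind(X, X), c(y, y), 4)$weights
  expect_equal(w1, w2, tolerance = 1e-8)

  expect_error(fit_pcr(X, y, 40), "rank")
})

test_that("the Haufe pattern equals the per-edge covariance oracle", {
  set.seed(65)
  X <- matrix(rnorm(80 * 25), 80)
  w <- rnorm(25)
  pat <- haufe_transform(X, w)
  yhat <- as.numeric(scale(X, scale = FALSE) %*% w)
  oracle <- vapply(seq_len(25), function(e) cov(X[, e], yhat), 0) / var(yhat)
  expect_equal(pat, oracle, tolerance = 1e-10)

  # whitened features: pattern proportional to the weights
  Xw <- matrix(rnorm(5000 * 6), 5000)
  Xw <- scale(Xw %*% solve(chol(cov(Xw))))
  patw <- haufe_transform(Xw, 1:6)
  expect_gt(cor(patw, 1:6), 0.9999)

  expect_error(haufe_transform(X, rep(0, 25)), "zero variance")
})

test_that("LOSO-CV is null-calibrated and flags degenerate sites", {
  set.seed(66)
  n <- 120
  X <- matrix(rnorm(n * 40), n)
  y <- rnorm(n)
  site <- rep(paste0("s", 1:4), each = 30)
  cv <- loso_cv(X, y, site, grid = c(1, 2, 4))
  expect_length(cv$per_site, 4)
  expect_true(all(abs(cv$per_site) <= 1))
  expect_lt(abs(cv$mean_r), 2.5 / sqrt(30))
  expect_error(loso_cv(X, y, rep("s1", n)), "3 sites")
})

test_that("identical connectomes give NA held-out correlation with warning", {
  set.seed(67)
  n <- 60
  X <- matrix(1.5, n, 20)
  y <- rnorm(n)
  site <- rep(paste0("s", 1:3), each = 20)
  w <- capture_warnings(cv <- loso_cv(X, y, site, grid = 1))
  expect_true(all(grepl("degenerate", w)))
  expect_true(all(is.na(cv$per_site)))
})

test_that("signature weights reproduce the component-space prediction path", {
  tr <- tiny_train()
  sig <- build_signature(tr$sim$X, tr$y, tr$covars, K = 3,
                         networks = tr$sim$networks)
  # component path: project residualized edges on the PCA basis, apply betas
  yr <- residualize(tr$y, tr$covars)
  Xr <- residualize(tr$sim$X, tr$covars)
  fit <- fit_pcr(Xr, yr, 3)
  idx <- sample(nrow(Xr), 50, replace = TRUE)
  via_weights <- sweep(Xr[idx, ], 2, fit$center) %*% sig$weights + fit$intercept
  S <- sweep(Xr[idx, ], 2, fit$center) %*% fit$rotation
  via_components <- S %*% fit$beta + fit$intercept
  expect_equal(as.numeric(via_weights), as.numeric(via_components),
               tolerance = 1e-10)

  sig1 <- build_signature(tr$sim$X, tr$y, tr$covars, K = 1,
                          networks = tr$sim$networks)
  v1 <- fit_pcr(Xr, yr, 1)$rotation[, 1]
  expect_gt(abs(cor(sig1$weights, v1)), 0.999999)
})

test_that("mean-K rounding is nearest integer, ties upward", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(2.49), 2)
  expect_equal(round_half_up(c(1.5, 2.5, 3.2)), c(2, 3, 3))
})
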