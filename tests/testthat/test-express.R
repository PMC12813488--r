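test_that("expression is the dot product and is linear", {
  nets <- c("SMN", "SMN", "VIS", "VIS")
  w <- c(1, -2, 0.5, 0, 3, -1)
  sig <- structure(list(weights = w, networks = nets), class = "neurosignature")
  c1 <- edge_vector(rnorm(6), nets)
  c2 <- edge_vector(rnorm(6), nets)
  expect_equal(express(sig, c1), sum(w * c1$values))
  expect_equal(express(sig, edge_vector(rep(0, 6), nets) ), 0)
  expect_equal(express(sig, edge_vector(w, nets)), sum(w^2))
  csum <- edge_vector(c1$values + c2$values, nets)
  expect_equal(express(sig, csum), express(sig, c1) + express(sig, c2),
               tolerance = 1e-12)
  # matrix form agrees with the per-connectome form
  M <- rbind(c1$values, c2$values)
  expect_equal(express(sig, M), c(express(sig, c1), express(sig, c2)))
})

test_that("edge-order mismatches are an error, never a silent reorder", {
  sig <- structure(list(weights = rnorm(6),
                        networks = c("SMN", "SMN", "VIS", "VIS")),
                   class = "neurosignature")
  other <- edge_vector(rnorm(6), c("VIS", "VIS", "SMN", "SMN"))
  expect_error(express(sig, other), "ordering mismatch")
  expect_error(express(sig, matrix(rnorm(10), 2, 5)), "edge count")
})

test_that("the longitudinal mixed model recovers a planted coupling", {
  d <- simulate_expression_change(800, -0.3, n_sites = 8, seed = 81)
  covs <- longitudinal_covariates(d$age_diff, d$fd_t1, d$fd_t2, d$sex)
  fit <- longitudinal_change_model(d$expr_t1, d$expr_t2, d$sleep_t1,
                                   d$sleep_t2, d$site, covs)
  expect_equal(fit$beta, -0.3, tolerance = 0.1)
  expect_lt(fit$p, 0.001)
  expect_equal(fit$method, "mixed")
  expect_error(longitudinal_change_model(d$expr_t1, d$expr_t2, d$sleep_t1,
                                         d$sleep_t2, rep("s1", 800)),
               "3 sites")
})

test_that("with zero site variance the mixed model collapses to OLS", {
  d <- simulate_expression_change(600, 0.25, n_sites = 6, site_sd = 0,
                                  seed = 82)
  fit <- suppressMessages(longitudinal_change_model(
    d$expr_t1, d$expr_t2, d$sleep_t1, d$sleep_t2, d$site))
  ols <- lm(scale(d$expr_t2 - d$expr_t1) ~ scale(d$sleep_t2 - d$sleep_t1))
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-6)
})

test_that("standardized beta is invariant to affine sleep rescaling", {
  d <- simulate_expression_change(400, -0.2, seed = 83)
  f1 <- longitudinal_change_model(d$expr_t1, d$expr_t2, d$sleep_t1,
                                  d$sleep_t2, d$site)
  f2 <- longitudinal_change_model(d$expr_t1, d$expr_t2,
                                  60 * d$sleep_t1 + 7, 60 * d$sleep_t2 + 7,
                                  d$site)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("the deprivation contrast matches the one-sample t closed form", {
  set.seed(84)
  n <- 76
  delta <- 0.5
  sigma <- 1.2
  typ <- rnorm(n, 2, 1)
  dep <- typ + delta + rnorm(n, 0, sigma)
  ct <- deprivation_contrast(typ, dep)
  tt <- t.test(dep - typ)
  expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ct$mean_diff, mean(dep - typ), tolerance = 1e-12)
  expect_equal(ct$t, delta * sqrt(n) / sigma, tolerance = 0.35)

  # covariate-adjusted intercept still estimates the mean difference when
  # covariates are centered and unrelated
  ct2 <- deprivation_contrast(typ, dep, sex = rbinom(n, 1, 0.5),
                              age_group = rbinom(n, 1, 0.5),
                              motion_typical = runif(n, 0.05, 0.3),
                              motion_deprived = runif(n, 0.05, 0.3))
  expect_equal(ct2$mean_diff, mean(dep - typ), tolerance = 0.15)
  expect_error(deprivation_contrast(typ[1:4], dep[1:4], sex = rbinom(4, 1, 0.5),
                                    age_group = rbinom(4, 1, 0.5),
                                    motion_typical = runif(4),
                                    motion_deprived = runif(4)),
               "too few")
})

test_that("expression rises under deprivation when signature matches pattern", {
  dep <- suppressMessages(simulate_deprivation(tiny_cfg(30, seed = 85), 1))
  w <- dep$truth$planted_map
  et <- express(w, dep$X_typical)
  ed <- express(w, dep$X_deprived)
  ct <- deprivation_contrast(et, ed, dep$cohort$sex, dep$cohort$age_group,
                             dep$cohort$mean_fd_typical,
                             dep$cohort$mean_fd_deprived)
  expect_gt(ct$mean_diff, 0)
  expect_gt(ct$t, 2)
})
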