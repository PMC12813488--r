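test_that("contrast signature recovers an additive planted pattern", {
  set.seed(91)
  n <- 40
  E <- n_edges(10)
  nets <- default_network_labels(10)
  typical <- matrix(rnorm(n * E, 0, 0.3), n)
  pattern <- rnorm(E)
  deprived <- typical + 0.5 * matrix(pattern, n, E, byrow = TRUE)

  # no difference: weights vanish
  cs0 <- contrast_signature(typical, typical, K = 20, networks = nets)
  expect_lt(max(abs(cs0$weights)), 1e-10)

  # deprived = typical + constant pattern: stacked residuals span the
  # typical rows plus the pattern direction, so full rank here is n
  cs <- contrast_signature(typical, deprived, K = n, networks = nets)
  cosine <- sum(cs$weights * pattern) /
    sqrt(sum(cs$weights^2) * sum(pattern^2))
  expect_gte(cosine, 0.999)

  ord <- sample(n)
  cs_shuffled <- contrast_signature(typical[ord, ], deprived[ord, ],
                                    K = n, networks = nets)
  expect_equal(cs$weights, cs_shuffled$weights, tolerance = 1e-9)

  expect_error(contrast_signature(typical, deprived, K = 500, networks = nets),
               "rank")
})

test_that("session-label flipping negates a subject's score contribution", {
  set.seed(92)
  n <- 12
  E <- n_edges(8)
  nets <- default_network_labels(8)
  typ <- matrix(rnorm(n * E), n)
  dep <- matrix(rnorm(n * E), n)
  cs <- contrast_signature(typ, dep, K = 5, networks = nets)
  # swap sessions for subject 1: the resulting map equals the original-basis
  # map with that subject's score-difference contribution negated (the PCA
  # basis may flip component signs between runs; the map is basis-invariant)
  typ2 <- typ; dep2 <- dep
  typ2[1, ] <- dep[1, ]; dep2[1, ] <- typ[1, ]
  cs2 <- contrast_signature(typ2, dep2, K = 5, networks = nets)
  flip <- c(-1, rep(1, n - 1))
  rebuilt <- as.numeric(cs$rotation %*% colMeans(cs$dscore * flip))
  expect_equal(cs2$weights, rebuilt, tolerance = 1e-8)
})

test_that("spatial correlation behaves on identities and degeneracies", {
  a <- rnorm(100)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  expect_error(spatial_correlation(a, rep(1, 100)), "zero-variance")

  nets <- c("SMN", "SMN", "VIS")
  sa <- edge_vector(rnorm(3), nets)
  sb <- edge_vector(rnorm(3), c("VIS", "SMN", "SMN"))
  expect_error(spatial_correlation(sa, sb), "ordering mismatch")
})

test_that("independent random maps have null-scale spatial correlation", {
  set.seed(93)
  r <- replicate(200, spatial_correlation(rnorm(1770), rnorm(1770)))
  expect_lt(quantile(abs(r), 0.95), 0.08)
})

test_that("the dual-permutation null is centered and calibrated in sign", {
  tr <- tiny_train()
  dep <- suppressMessages(simulate_deprivation(
    tiny_cfg(24, seed = 94), 1))
  co <- dep$cohort
  res <- dual_permutation_null(
    tr$sim$X, tr$y, tr$covars, K_x = 5,
    typical = dep$X_typical, deprived = dep$X_deprived,
    cov_typical = cbind(co$sex, co$age_group, co$mean_fd_typical),
    cov_deprived = cbind(co$sex, co$age_group, co$mean_fd_deprived),
    K_c = 5, networks = tr$sim$networks, B = 200)
  se <- sd(res$null) / sqrt(length(res$null))
  expect_lt(abs(mean(res$null)), 4 * se + 0.02)
  expect_true(res$p > 0 && res$p <= 1)
  # shared planted pattern: observed correspondence should sit high
  expect_gt(res$observed, quantile(res$null, 0.5))
})
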