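test_that("configuration is validated before any compute", {
  expect_error(sim_config(10, network_labels = c("SMN", "VIS")),
               "cover all parcels")
  expect_error(sim_config(10, n_parcels = 4,
                          network_labels = c("A", "B", "A", "B")),
               "SMN and VIS")
  expect_error(sim_config(10, indicator_loadings = c(0.8, 1.2, 0.5)))
  expect_error(sim_config(0))
})

test_that("same seed and config give byte-identical outputs", {
  a <- suppressMessages(simulate_cross_sectional(tiny_cfg(20, seed = 51)))
  b <- suppressMessages(simulate_cross_sectional(tiny_cfg(20, seed = 51)))
  expect_identical(a$X, b$X)
  expect_identical(a$cohort, b$cohort)

  cfg <- tiny_cfg(14, seed = 52)
  l1 <- suppressMessages(simulate_longitudinal(cfg, 0.5))
  l2 <- suppressMessages(simulate_longitudinal(cfg, 0.5))
  expect_identical(l1$X_t1, l2$X_t1)
  expect_identical(l1$X_t2, l2$X_t2)

  d1 <- suppressMessages(simulate_deprivation(cfg, 1))
  d2 <- suppressMessages(simulate_deprivation(cfg, 1))
  expect_identical(d1$X_deprived, d2$X_deprived)
})

test_that("site/family/twin nesting is a strict tree", {
  sim <- tiny_train()$sim
  co <- sim$cohort
  expect_silent(exchangeability_blocks(co$site_id, co$family_id,
                                       co$twin_pair_id))
  fam_site <- tapply(co$site_id, co$family_id,
                     function(s) length(unique(s)))
  expect_true(all(fam_site == 1))
  tw <- !is.na(co$twin_pair_id)
  if (any(tw)) {
    pair_fam <- tapply(co$family_id[tw], co$twin_pair_id[tw],
                       function(f) length(unique(f)))
    expect_true(all(pair_fam == 1))
    # pairs may lose a member to motion exclusion, never gain one
    expect_true(all(table(co$twin_pair_id[tw]) <= 2))
  }
})

test_that("null generator leaves every network block uncorrelated with sleep", {
  # motion confounding is also disabled: it is a deliberate correlation
  # pathway between sleep and connectivity, controlled by covariates
  cfg <- tiny_cfg(150, seed = 53, effect_size_smn = 0, effect_size_vis = 0,
                  motion_confound_strength = 0)
  sim <- suppressMessages(simulate_cross_sectional(cfg))
  lat <- sim$cohort$latent_sleep
  for (net in unique(sim$networks)) {
    block <- rowMeans(sim$X[, within_network_edges(sim$networks, net),
                            drop = FALSE])
    expect_lt(abs(cor(block, lat)), 3 / sqrt(nrow(sim$X)))
  }
})

test_that("the planted effect is confined to SMN and VIS blocks", {
  cfg <- tiny_cfg(150, seed = 54)
  sim <- suppressMessages(simulate_cross_sectional(cfg))
  reduced <- -sim$cohort$latent_sleep
  smn <- within_network_edges(sim$networks, "SMN")
  vis <- within_network_edges(sim$networks, "VIS")
  expect_gt(cor(rowMeans(sim$X[, smn, drop = FALSE]), reduced), 0.3)
  expect_lt(cor(rowMeans(sim$X[, vis, drop = FALSE]), reduced), -0.3)
  other <- !(smn | vis)
  r_other <- cor(sim$X[, other], reduced)
  expect_lt(abs(mean(r_other)), 0.06)
})

test_that("indicator correlations converge to loading products", {
  cfg <- sim_config(n_subjects = 5000, n_parcels = 12,
                    network_labels = default_network_labels(12),
                    indicator_loadings = c(0.8, 0.6, 0.5), seed = 55)
  sim <- simulate_cross_sectional(cfg, imaging = FALSE)
  R <- cor(sim$cohort[, indicator_cols])
  lam <- c(0.8, 0.6, 0.5)
  expect_equal(R[1, 2], lam[1] * lam[2], tolerance = 0.03)
  expect_equal(R[1, 3], lam[1] * lam[3], tolerance = 0.03)
  expect_equal(R[2, 3], lam[2] * lam[3], tolerance = 0.03)
})

test_that("longitudinal generator validates and stores its ground truth", {
  cfg <- tiny_cfg(12, seed = 56)
  expect_error(simulate_longitudinal(cfg, -0.1), "non-negative")
  lng <- suppressMessages(simulate_longitudinal(cfg, 0.4))
  expect_identical(lng$truth$delta_sleep_sd, 0.4)
  expect_equal(lng$cohort$latent_t2 - lng$cohort$latent_t1,
               lng$cohort$delta_latent, tolerance = 1e-12)
})

test_that("zero latent change yields no sleep-related edge change", {
  cfg <- tiny_cfg(60, seed = 57)
  lng <- suppressMessages(simulate_longitudinal(cfg, 0))
  expect_true(all(lng$cohort$delta_latent == 0))
  d_edge <- rowMeans((lng$X_t2 - lng$X_t1)[,
    within_network_edges(lng$networks, "SMN"), drop = FALSE])
  d_sleep <- lng$cohort$sleep_t2 - lng$cohort$sleep_t1
  b <- coef(lm(d_edge ~ d_sleep))[2]
  expect_lt(abs(b), 2.5 * summary(lm(d_edge ~ d_sleep))$coefficients[2, 2])
})

test_that("deprivation generator plants the session contrast", {
  cfg0 <- tiny_cfg(40, seed = 58)
  dep0 <- suppressMessages(simulate_deprivation(cfg0, 0))
  md <- colMeans(dep0$X_deprived - dep0$X_typical)
  expect_lt(max(abs(md)), 3.5 * max(apply(dep0$X_deprived - dep0$X_typical,
                                          2, sd)) / sqrt(nrow(dep0$cohort)))

  dep <- suppressMessages(simulate_deprivation(cfg0, 1))
  d <- colMeans(dep$X_deprived - dep$X_typical)
  expect_gt(mean(d[within_network_edges(dep$networks, "SMN")]), 0)
  expect_lt(mean(d[within_network_edges(dep$networks, "VIS")]), 0)
})

test_that("expression-change generator plants the standardized coupling", {
  d <- simulate_expression_change(500, -0.10, seed = 59)
  expect_identical(attr(d, "truth")$coupling, -0.10)
  expect_equal(sd(d$expr_t2 - d$expr_t1), 1, tolerance = 0.15)
})
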