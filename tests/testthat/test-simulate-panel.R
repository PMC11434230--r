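test_that("line effects have covariance 2 * G_true", {
  G <- diag(0.5, 6)
  dimnames(G) <- list(trait_names, trait_names)
  cfg <- panel_sim_config(G, n_lines = 400, seed = 3)
  tab <- simulate_line_phenotypes(cfg)
  eff <- attr(tab, "line_effects")
  expect_lt(rel_frob(cov(eff), 2 * G), 0.25)   # sampling error ~ sqrt(2/n)
  # every line appears in >= 2 blocks
  n_blocks <- tapply(tab$block_id, tab$line_id, function(b) length(unique(b)))
  expect_true(all(n_blocks >= 2))
  # covariates standardized
  expect_equal(mean(tab$temperature), 0, tolerance = 1e-10)
  expect_equal(sd(tab$density), 1, tolerance = 1e-10)
})

test_that("G_true = 0 gives no line variance and zero covariate effects recover", {
  G0 <- matrix(0, 6, 6)
  cfg <- panel_sim_config(G0, n_lines = 300, residual_cov = diag(0.1, 6),
                          seed = 5)
  tab <- simulate_line_phenotypes(cfg)
  expect_equal(max(abs(attr(tab, "line_effects"))), 0)
  fit <- fit_line_model(tab, method = "moments")
  expect_lt(max(abs(fit$G_mean)), 0.05)
  # no planted covariate effect: regression slopes ~ 0 (covariates vary at
  # block level, so the slope noise floor is set by the ~45 blocks)
  sl <- coef(lm(as.matrix(tab[, trait_names]) ~ tab$temperature))[2, ]
  expect_true(all(abs(sl) < 0.08))
})

test_that("planted covariate effects are recovered by regression", {
  B <- matrix(0, 6, 3)
  B[1, 1] <- 0.5                       # temperature effect on SF
  cfg <- panel_sim_config(diag(0.05, 6), n_lines = 200,
                          covariate_effect_matrix = B,
                          residual_cov = diag(0.05, 6), seed = 8)
  tab <- simulate_line_phenotypes(cfg)
  sl <- coef(lm(SF ~ temperature + humidity + density, data = tab))
  expect_equal(unname(sl["temperature"]), 0.5, tolerance = 0.1)
})

test_that("fitness generator evaluates the quadratic surface exactly", {
  g0 <- matrix(0, 6, 6)
  cfg <- fitness_sim_config(g0, alpha = 1, noise_sd = 0, seed = 1)
  Z <- random_line_traits(20, seed = 2)
  w <- simulate_fitness(Z, cfg)
  expect_equal(w$fitness, rep(1, 20))
  # gamma = diag(-1, 0...), z = e1 -> w = alpha - 0.5
  g1 <- diag(c(-1, 0, 0, 0, 0, 0))
  Z1 <- matrix(0, 2, 6, dimnames = list(c("a", "b"), trait_names))
  Z1[1, 1] <- 1
  w1 <- simulate_fitness(Z1, fitness_sim_config(g1, alpha = 1, noise_sd = 0))
  expect_equal(w1$fitness, c(0.5, 1))
  # cross-product term
  g2 <- matrix(0, 6, 6); g2[1, 2] <- g2[2, 1] <- 0.4
  Z2 <- matrix(0, 1, 6, dimnames = list("a", trait_names))
  Z2[1, 1:2] <- c(2, 3)
  w2 <- simulate_fitness(Z2, fitness_sim_config(g2, alpha = 0, noise_sd = 0))
  expect_equal(w2$fitness, 0.4 * 6)
  expect_error(simulate_fitness(Z1[, 1:3], fitness_sim_config(g1)),
               "dimension mismatch")
})

test_that("drift simulator obeys closed-form decay and boundary cases", {
  # negligible decay at very large Ne
  G0 <- planted_G()
  a <- simulate_drift_panel(G0, Ne = 1e5, generations = 10, seed = 2)
  expect_lt(rel_frob(a[, , 11], G0), 0.05)
  # mean decay over replicates matches (1 - 1/(2Ne))^t
  ends <- sapply(1:40, function(r) {
    sum(diag(simulate_drift_panel(diag(1, 6), Ne = 300, generations = 40,
                                  seed = 400 + r)[, , 41]))
  })
  expected <- 6 * (1 - 1 / 600)^40
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - expected), 4 * se + 0.01)
  # singular axis stays empty
  v <- c(1, 0, 0, 0, 0, 0)
  G1 <- tcrossprod(c(0, 1, 1, 0, 0, 0)) * 0.5
  b <- simulate_drift_panel(G1, Ne = 100, generations = 20, seed = 3)
  expect_lt(abs(project_variance(b[, , 21], v)), 1e-20)
  expect_error(simulate_drift_panel(G1, Ne = 1, generations = 5), "Ne")
  expect_error(simulate_drift_panel(G1, Ne = 100, generations = -1),
               "generations")
})

test_that("panel simulation is reproducible and validates its config", {
  cfg <- panel_sim_config(diag(0.1, 6), n_lines = 20, seed = 11)
  expect_identical(simulate_line_phenotypes(cfg), simulate_line_phenotypes(cfg))
  expect_error(panel_sim_config(diag(0.1, 6), n_lines = 1), "n_lines")
  expect_error(panel_sim_config(matrix(1:36, 6)), "symmetric")
  notpsd <- diag(6); notpsd[1, 1] <- -1
  expect_error(panel_sim_config(notpsd), "positive semi-definite")
})
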