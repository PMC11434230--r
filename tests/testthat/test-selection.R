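test_that("relative fitness preparation matches hand arithmetic", {
  expect_equal(prepare_relative_fitness(c(0, 0, 0)), rep(1, 3))
  expect_equal(prepare_relative_fitness(c(0, log(2))), c(2 / 3, 4 / 3),
               tolerance = 1e-12)
  set.seed(1)
  w <- prepare_relative_fitness(rnorm(50))
  expect_equal(mean(w), 1, tolerance = 1e-12)
  expect_error(prepare_relative_fitness(c(1, NA)), "finite")
  d <- prepare_relative_fitness(data.frame(line_id = c("a", "b"),
                                           fertility = c(0, log(2))))
  expect_equal(d$fitness, c(2 / 3, 4 / 3))
})

test_that("noise-free fitness is interpolated to the exact gamma", {
  Z <- random_line_traits(250, seed = 2)
  g <- planted_gamma()
  w <- simulate_fitness(Z, fitness_sim_config(g, alpha = 1, noise_sd = 0,
                                              seed = 3))
  fit <- fit_gamma(Z, w, seed = 1)
  expect_lt(max(abs(fit$gamma - g)), 1e-8)
  expect_equal(fit$alpha, 1, tolerance = 1e-8)
})

test_that("gamma recovery with noise covers truth elementwise", {
  Z <- random_line_traits(250, seed = 4)
  g <- planted_gamma()
  w <- simulate_fitness(Z, fitness_sim_config(g, alpha = 1, noise_sd = 0.1,
                                              seed = 5))
  fit <- fit_gamma(Z, w, n_draws = 2000, seed = 1)
  covered <- mapply(function(i, j) {
    x <- fit$gamma_draws[i, j, ]
    g[i, j] >= quantile(x, 0.025) && g[i, j] <= quantile(x, 0.975)
  }, row(g)[upper.tri(g, diag = TRUE)], col(g)[upper.tri(g, diag = TRUE)])
  expect_gte(sum(covered), 19)          # ~ binomial(21, 0.95)
})

test_that("permuted fitness gives a gamma posterior centered on zero", {
  Z <- random_line_traits(200, seed = 6)
  g <- planted_gamma()
  w <- simulate_fitness(Z, fitness_sim_config(g, noise_sd = 0.1, seed = 7))
  set.seed(8)
  w$fitness <- sample(w$fitness)
  fit <- suppressWarnings(fit_gamma(Z, w, seed = 1))
  expect_lt(max(abs(fit$gamma)), 0.2 * max(abs(g)) + 0.05)
})

test_that("gamma estimation is equivariant under trait rotation", {
  Z <- random_line_traits(150, seed = 9)
  g <- planted_gamma()
  w <- simulate_fitness(Z, fitness_sim_config(g, noise_sd = 0, seed = 1))
  set.seed(10)
  R <- qr.Q(qr(matrix(rnorm(36), 6)))
  ZR <- Z %*% R
  colnames(ZR) <- trait_names
  fitR <- suppressWarnings(fit_gamma(ZR, w, seed = 1))
  expect_lt(max(abs(fitR$gamma - t(R) %*% g %*% R)), 1e-8)
})

test_that("canonical analysis diagonalizes gamma with sorted eigenvalues", {
  g <- diag(c(1, -2, 0, 0, 0, 0))
  can <- canonical_analysis(g)
  expect_equal(can$lambda, c(1, 0, 0, 0, 0, -2))
  expect_equal(can$classification[1], "disruptive")
  expect_equal(can$classification[6], "stabilizing")
  g2 <- planted_gamma()
  can2 <- canonical_analysis(g2)
  expect_lt(max(abs(can2$U %*% diag(can2$lambda) %*% t(can2$U) - g2)), 1e-10)
  expect_lt(max(abs(crossprod(can2$U) - diag(6))), 1e-10)
  # eigenvalues invariant under trait permutation
  p <- c(3, 1, 6, 2, 5, 4)
  expect_equal(canonical_analysis(g2[p, p])$lambda, can2$lambda,
               tolerance = 1e-10)
})

test_that("G rotation preserves trace and matches projections", {
  G <- planted_G()
  can <- canonical_analysis(planted_gamma())
  Gp <- rotate_gmatrix(G, can$U)
  expect_equal(matrix_trace(Gp), matrix_trace(G), tolerance = 1e-12)
  for (i in 1:6) {
    expect_equal(Gp[i, i], project_variance(G, can$U[, i]), tolerance = 1e-12)
  }
  expect_gte(min(diag(Gp)), 0)
  expect_equal(rotate_gmatrix(G, diag(6)), G, ignore_attr = TRUE)
  expect_error(rotate_gmatrix(G, matrix(1, 6, 6)), "orthogonal")
})

test_that("permutation null of rotated eigenvalues centers on zero", {
  Z <- random_line_traits(200, seed = 12)
  g <- planted_gamma()
  w <- simulate_fitness(Z, fitness_sim_config(g, noise_sd = 0.1, seed = 13))
  fit <- suppressWarnings(fit_gamma(Z, w, seed = 1))
  can <- canonical_analysis(fit)
  nl <- null_lambda_distribution(Z, w, can$U, n_perm = 200, seed = 14)
  expect_true(all(abs(colMeans(nl)) < 2 * apply(nl, 2, sd) / sqrt(nrow(nl)) + 0.01))
  # strong planted stabilizing axis lies below the null band
  expect_lt(can$lambda[6], attr(nl, "quantiles")["2.5%", "y6"])
})

test_that("alignment correlations identify shared axes", {
  g <- planted_gamma()
  Z <- random_line_traits(300, seed = 15)
  w <- simulate_fitness(Z, fitness_sim_config(g, noise_sd = 0.02, seed = 16))
  fit <- fit_gamma(Z, w, seed = 1)
  can <- canonical_analysis(fit)
  # a tensor vector constructed to equal the first canonical axis
  tab <- alignment_correlations(list(e11 = can$U[, 1]), fit, n_draws = 200)
  best <- tab$abs_r_mean[tab$axis == "y1"]
  expect_gt(best, 0.95)
  expect_true(all(best >= tab$abs_r_mean[tab$axis != "y1"]))
  # orthogonal vectors are uncorrelated
  expect_equal(cor(c(1, -1, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0)), 0)
})
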