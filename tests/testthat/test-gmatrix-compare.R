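test_that("trace and spectral decomposition satisfy their identities", {
  expect_equal(matrix_trace(diag(6)), 6)
  expect_equal(matrix_trace(diag(0.1, 6)), 0.6)
  set.seed(2)
  A <- crossprod(matrix(rnorm(36), 6))
  es <- eigen_decompose(A)
  expect_equal(sum(es$values), matrix_trace(A), tolerance = 1e-12)
  recon <- es$vectors %*% diag(es$values) %*% t(es$vectors)
  expect_lt(max(abs(recon - A)), 1e-10)
  expect_error(eigen_decompose(matrix(rnorm(36), 6)), "asymmetric")
  # diagonal matrix: gmax is the leading basis vector
  es2 <- eigen_decompose(diag(c(3, 2, 1, 1, 1, 1)))
  expect_equal(es2$vectors[, 1], c(1, 0, 0, 0, 0, 0))
  expect_equal(es2$values[1], 3)
  # rank-1: gmax parallel to the generating vector
  v <- c(1, 2, 3, 0, -1, 2); v <- v / sqrt(sum(v^2))
  es3 <- eigen_decompose(tcrossprod(v))
  expect_lt(angle_between(es3$vectors[, 1], v), 1e-6)
  expect_lt(max(abs(es3$values[-1])), 1e-12)
})

test_that("projected variance behaves as a quadratic form", {
  G <- planted_G()
  es <- eigen_decompose(G)
  expect_equal(project_variance(G, es$vectors[, 1]), es$values[1],
               tolerance = 1e-12)
  # orthogonal to the support of a rank-1 matrix
  v <- c(1, 0, 0, 0, 0, 0)
  G1 <- tcrossprod(c(0, 1, 0, 0, 0, 0))
  expect_equal(project_variance(G1, v), 0)
  expect_error(project_variance(G, rep(0, 6)), "non-zero")
  # isotropic average identity: E_v[v' G v] = trace(G)/6
  set.seed(5)
  vs <- matrix(rnorm(6 * 4000), ncol = 6)
  vs <- vs / sqrt(rowSums(vs^2))
  pv <- apply(vs, 1, function(u) project_variance(G, u))
  expect_equal(mean(pv), matrix_trace(G) / 6, tolerance = 0.02)
})

test_that("angles fold to [0, 90] and match hand values", {
  v <- c(1, 2, 0, 0, 0, 1)
  expect_equal(angle_between(v, v), 0)
  expect_equal(angle_between(v, -v), 0)
  e1 <- c(1, 0, 0, 0, 0, 0); e2 <- c(0, 1, 0, 0, 0, 0)
  expect_equal(angle_between(e1, e2), 90)
  expect_equal(angle_between(c(1, 1, 0, 0, 0, 0) / sqrt(2), e1), 45,
               tolerance = 1e-10)
  expect_error(angle_between(rep(0, 6), e1), "non-zero")
})

test_that("uniform-vector null angle distribution is stable and bounded", {
  th <- null_angle_distribution(6, 1000, seed = 3)
  expect_true(all(th >= 0 & th <= 90))
  # reproducible
  expect_identical(th, null_angle_distribution(6, 1000, seed = 3))
  # 2-D folded angles: near-uniform on [0, 90] (oracle re-simulation + KS)
  th2 <- null_angle_distribution(2, 20000, seed = 4)
  ks <- suppressWarnings(ks.test(th2, "punif", 0, 90)$statistic)
  expect_lt(ks, 0.05)
  big <- null_angle_distribution(2, 50000, seed = 5)
  expect_equal(median(th2), median(big), tolerance = 0.05)
})

test_that("angle posterior concentrates as posterior uncertainty vanishes", {
  G <- planted_G()
  gmax <- eigen_decompose(G)$vectors[, 1]
  set.seed(6)
  draws <- array(NA_real_, c(6, 6, 50))
  for (d in 1:50) {
    E <- matrix(rnorm(36, sd = 1e-4), 6); E <- (E + t(E)) / 2
    draws[, , d] <- G + E
  }
  ap <- angle_posterior(gmax, draws, k = 1)
  expect_lt(ap$q97.5, 0.5)
  expect_lt(ap$q8.5, ap$q91.5)
})

test_that("scaled half-vectorization is a Frobenius isometry", {
  set.seed(7)
  for (r in 1:5) {
    A <- crossprod(matrix(rnorm(36), 6))
    B <- crossprod(matrix(rnorm(36), 6))
    expect_equal(sqrt(sum((vech_scaled(A) - vech_scaled(B))^2)),
                 norm(A - B, "F"), tolerance = 1e-12)
    expect_equal(unvech_scaled(vech_scaled(A)), A, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("planted one-element divergence yields the known eigentensor", {
  G1 <- diag(0.5, 6); G2 <- diag(0.5, 6)
  G1[1, 1] <- 0.75; G2[1, 1] <- 0.25
  tn <- build_covariance_tensor(list(A = G1, B = G2))
  et <- eigentensor_decompose(tn)
  # variance between the two 21-vectors: sample variance (m - 1) = 0.125
  expect_equal(et$alpha[1], 0.125, tolerance = 1e-12)
  expect_lt(max(abs(et$alpha[-1])), 1e-12)
  E1 <- et$E[[1]]
  expect_equal(abs(E1[1, 1]), 1, tolerance = 1e-12)
  expect_lt(max(abs(E1[-1])), 1e-12)
  # e11 of the planted case is the first trait basis vector
  expect_equal(unname(abs(et$tensor_eigen[[1]]$vectors[1, 1])), 1,
               tolerance = 1e-12)
  # coordinates sum to zero and are +-0.25
  expect_equal(sum(et$coordinates[, 1]), 0, tolerance = 1e-12)
  expect_equal(sort(et$coordinates[, 1]), c(-0.25, 0.25), ignore_attr = TRUE)
})

test_that("identical populations give a zero tensor and rank bound holds", {
  G <- planted_G()
  tn0 <- build_covariance_tensor(list(G, G, G))
  expect_lt(max(abs(tn0$S)), 1e-14)
  expect_lt(max(eigentensor_decompose(tn0)$alpha), 1e-14)
  # m matrices give at most m - 1 nonzero eigenvalues
  set.seed(8)
  Gs <- lapply(1:3, function(i) crossprod(matrix(rnorm(36), 6)) / 6)
  et <- eigentensor_decompose(build_covariance_tensor(Gs))
  expect_lt(max(abs(et$alpha[3:21])), 1e-12)
  # total variance identity: sum(alpha) = sum of elementwise variances
  V <- sapply(Gs, vech_scaled)
  expect_equal(sum(et$alpha), sum(apply(V, 1, var)), tolerance = 1e-12)
})

test_that("tensor reconstruction reproduces S", {
  set.seed(9)
  Gs <- lapply(1:4, function(i) crossprod(matrix(rnorm(36), 6)) / 6)
  tn <- build_covariance_tensor(Gs)
  et <- eigentensor_decompose(tn)
  S_rec <- Reduce(`+`, lapply(1:21, function(i) {
    et$alpha[i] * tcrossprod(vech_scaled(et$E[[i]]))
  }))
  expect_lt(max(abs(S_rec - tn$S)), 1e-10)
})

test_that("finite-line sampling null calibrates alpha and detects divergence", {
  G <- planted_G()
  # no true divergence: observed alpha from noisy re-estimates of one G
  set.seed(10)
  null_a <- tensor_sampling_null(list(G, G, G), n_lines_per_pop = 50,
                                 n_rep = 60, seed = 2)
  expect_true(all(null_a >= 0))
  # planted strong divergence: ancestral G vs two matrices with gmax removed
  G_red <- G * 0.2
  obs <- eigentensor_decompose(build_covariance_tensor(list(G, G_red, G_red)))
  expect_gt(obs$alpha[1], attr(null_a, "q95")[1])
})
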