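#' Trace of a (co)variance matrix, per posterior draw if given an array
#'
#' The trace of G is the total genetic variance, the standard measure of
#' G-matrix size.
#'
#' @param G Square matrix, or 3-d array of matrices (draws in the third
#'   dimension).
#' @return Scalar, or vector of per-draw traces.
#' @export
matrix_trace <- function(G) {
  if (is.array(G) && length(dim(G)) == 3L) {
    return(apply(G, 3L, function(m) sum(diag(m))))
  }
  if (!is.matrix(G) || nrow(G) != ncol(G)) stop("G must be square")
  sum(diag(G))
}

# deterministic sign convention: largest-magnitude loading positive
.fix_sign <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Spectral decomposition of a G-matrix
#'
#' Eigendecomposition with eigenvalues sorted in decreasing order; the first
#' eigenvector is `gmax`, the trait combination carrying maximal genetic
#' variance. Eigenvector signs are fixed so the largest-magnitude loading is
#' positive.
#'
#' @param G Symmetric matrix (symmetrized if asymmetry is below `tol`,
#'   rejected otherwise).
#' @param tol Asymmetry tolerance.
#' @return Object of class `eigen_structure`: `values`, `vectors` (columns,
#'   first = gmax), `proportion` of total variance per axis.
#' @export
eigen_decompose <- function(G, tol = 1e-9) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) stop("G must be square")
  asym <- max(abs(G - t(G)))
  if (asym > tol * max(1, max(abs(G)))) {
    stop("matrix is asymmetric beyond tolerance (", format(asym), ")")
  }
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  V <- .fix_sign(eg$vectors)
  rownames(V) <- rownames(G)
  structure(list(values = eg$values, vectors = V,
                 proportion = eg$values / sum(eg$values)),
            class = "eigen_structure")
}

#' Genetic variance along a phenotypic direction
#'
#' Computes `v' G v`, the (genetic) variance of the trait combination `v`;
#' applied over posterior draws it yields the projected-variance posterior.
#'
#' @param G Matrix or 3-d array of draws.
#' @param v Unit vector (renormalized if within 1e-6 of unit norm).
#' @return Scalar or per-draw vector.
#' @export
project_variance <- function(G, v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("v must be a non-zero vector")
  v <- v / nv
  if (is.array(G) && length(dim(G)) == 3L) {
    return(apply(G, 3L, function(m) drop(crossprod(v, m %*% v))))
  }
  drop(crossprod(v, G %*% v))
}

#' Angle between two trait-space directions
#'
#' Arc-cosine of the normalized dot product, in degrees, folded to
#' `[0, 90]`: since `g` and `-g` span the same axis, angles above 90 degrees
#' map to their supplement.
#'
#' @param g_i,g_j Non-zero numeric vectors of equal length.
#' @return Angle in degrees in `[0, 90]`.
#' @export
angle_between <- function(g_i, g_j) {
  ni <- sqrt(sum(g_i^2)); nj <- sqrt(sum(g_j^2))
  if (ni == 0 || nj == 0) stop("vectors must be non-zero")
  u <- g_i / ni
  w <- g_j / nj
  # chord formula: stable where acos of the dot product loses precision
  # near parallel/antiparallel vectors; folding is built in via the min
  m <- min(sqrt(sum((u - w)^2)), sqrt(sum((u + w)^2)))
  2 * asin(min(1, m / 2)) * 180 / pi
}

#' Posterior distribution of the angle to a reference direction
#'
#' For each posterior draw of G, the angle between its `k`-th eigenvector
#' and a fixed reference vector (e.g. the ancestral gmax), folded to
#' `[0, 90]` degrees.
#'
#' @param v_ref Reference direction.
#' @param G_draws 6x6xD array of posterior G draws (or a
#'   `gmatrix_posterior`).
#' @param k Eigenvector index of each draw to compare (1 = gmax).
#' @return Object of class `angle_result`: `draws`, `mean`, and
#'   83/95 percent quantile intervals.
#' @export
angle_posterior <- function(v_ref, G_draws, k = 1L) {
  if (inherits(G_draws, "gmatrix_posterior")) G_draws <- G_draws$G_draws
  draws <- apply(G_draws, 3L, function(m) {
    angle_between(v_ref, eigen_decompose(m)$vectors[, k])
  })
  q <- stats::quantile(draws, c(0.025, 0.085, 0.915, 0.975))
  structure(list(draws = draws, mean = mean(draws),
                 q2.5 = q[[1]], q8.5 = q[[2]], q91.5 = q[[3]], q97.5 = q[[4]]),
            class = "angle_result")
}

#' Null distribution of angles between random directions
#'
#' Angles between pairs of random vectors with i.i.d. `Uniform(-1, 1)`
#' coordinates, folded to `[0, 90]` degrees: the reference distribution for
#' "no alignment" between eigenvectors.
#'
#' @param dim Trait-space dimension (>= 2).
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed.
#' @return Numeric vector of `n_pairs` angles, with attribute `"quantiles"`
#'   (2.5/5/50/95/97.5 percent).
#' @export
null_angle_distribution <- function(dim = 6L, n_pairs = 1000L, seed = 1L) {
  if (dim < 2L) stop("dim must be >= 2")
  set.seed(seed)
  a <- matrix(stats::runif(n_pairs * dim, -1, 1), n_pairs)
  b <- matrix(stats::runif(n_pairs * dim, -1, 1), n_pairs)
  cth <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  th <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
  th <- ifelse(th > 90, 180 - th, th)
  attr(th, "quantiles") <- stats::quantile(th, c(0.025, 0.05, 0.5, 0.95, 0.975))
  th
}

# half-vectorization with sqrt(2) off-diagonal scaling (Frobenius isometry)
.vech_idx <- local({
  ii <- jj <- integer(0)
  for (j in 1:6) for (i in j:6) { ii <- c(ii, i); jj <- c(jj, j) }
  cbind(row = ii, col = jj)
})

#' Half-vectorize a symmetric matrix with Frobenius scaling
#'
#' Maps a symmetric 6x6 matrix to the 21-vector of its lower triangle with
#' off-diagonal entries scaled by `sqrt(2)`, so that Euclidean geometry on
#' the vectors equals Frobenius geometry on the matrices. `unvech_scaled`
#' inverts the map.
#'
#' @param G Symmetric 6x6 matrix.
#' @return Length-21 numeric vector.
#' @export
vech_scaled <- function(G) {
  v <- G[.vech_idx]
  off <- .vech_idx[, 1] != .vech_idx[, 2]
  v[off] <- v[off] * sqrt(2)
  v
}

#' @rdname vech_scaled
#' @param v Length-21 vector.
#' @export
unvech_scaled <- function(v) {
  G <- matrix(0, 6, 6, dimnames = list(trait_names, trait_names))
  off <- .vech_idx[, 1] != .vech_idx[, 2]
  v[off] <- v[off] / sqrt(2)
  G[.vech_idx] <- v
  G[.vech_idx[, c(2, 1)]] <- v
  G
}

#' Build the genetic covariance tensor across populations
#'
#' The fourth-order covariance tensor describing variation among a set of
#' G-matrices, represented as a 21x21 covariance matrix over the scaled
#' half-vectorized symmetric space. Each population's matrix is
#' half-vectorized, matrices are centered across populations, and their
#' covariance (denominator `m - 1`) accumulated. When posterior draw arrays
#' are supplied, the tensor is computed per draw index (draws paired across
#' populations by index) and averaged, retaining the per-draw tensors for
#' uncertainty propagation.
#'
#' @param G_list List (>= 2) of `gmatrix_posterior` objects, 6x6 matrices,
#'   or 6x6xD draw arrays, one per population.
#' @param n_draws Number of paired draws to use (default: the minimum
#'   available).
#' @return Object of class `covariance_tensor`: `S` (21x21), `S_draws`
#'   (21x21xD or NULL), `G_means`, `m`, `populations`.
#' @export
build_covariance_tensor <- function(G_list, n_draws = NULL) {
  if (length(G_list) < 2L) stop("need G-matrices from at least 2 populations")
  arrs <- lapply(G_list, function(g) {
    if (inherits(g, "gmatrix_posterior")) g <- g$G_draws
    if (is.matrix(g)) g <- array(g, c(dim(g), 1L))
    stopifnot(length(dim(g)) == 3L, dim(g)[1] == 6L, dim(g)[2] == 6L)
    g
  })
  nm <- lapply(arrs, function(a) dimnames(a)[[1]])
  nm <- nm[!vapply(nm, is.null, TRUE)]
  if (length(nm) > 1L && !all(vapply(nm, identical, TRUE, nm[[1]]))) {
    stop("trait order differs between populations")
  }
  m <- length(arrs)
  D <- min(vapply(arrs, function(a) dim(a)[3], 1L))
  if (!is.null(n_draws)) D <- min(D, n_draws)
  S_draws <- array(0, c(21, 21, D))
  for (dr in seq_len(D)) {
    V <- t(vapply(arrs, function(a) vech_scaled(a[, , dr]), numeric(21)))
    Vc <- sweep(V, 2L, colMeans(V))
    S_draws[, , dr] <- crossprod(Vc) / (m - 1)
  }
  S <- apply(S_draws, c(1, 2), mean)
  G_means <- lapply(arrs, function(a) apply(a, c(1, 2), mean))
  structure(list(S = S, S_draws = if (D > 1L) S_draws else NULL,
                 G_means = G_means, m = m,
                 populations = names(G_list) %||%
                   paste0("pop", seq_len(m))),
            class = "covariance_tensor")
}

#' Eigentensor decomposition of a genetic covariance tensor
#'
#' Eigenvectors of the 21x21 tensor representation are mapped back to
#' symmetric 6x6 eigentensors `E_i` with unit Frobenius norm; their
#' eigenvalues `alpha_i` quantify the variance among G-matrices each
#' orthogonal direction of matrix space captures. Each eigentensor is in
#' turn eigendecomposed into trait-space eigenvectors `e_ij`. Coordinates
#' of the (centered) population matrices on each eigentensor are the
#' Frobenius inner products; they sum to zero by construction.
#'
#' @param tensor A `covariance_tensor`, or a symmetric PSD 21x21 matrix.
#' @param tol Negative-eigenvalue tolerance for the PSD check.
#' @return Object of class `eigentensor_decomposition`: `alpha`,
#'   `alpha_draws` (per-draw leading eigenvalues, or NULL), `E` (list of
#'   6x6 eigentensors), `tensor_eigen` (list of `eigen_structure` per
#'   eigentensor), `coordinates` (populations x eigentensors), `S`.
#' @export
eigentensor_decompose <- function(tensor, tol = 1e-8) {
  S <- if (inherits(tensor, "covariance_tensor")) tensor$S else tensor
  if (!is.matrix(S) || !all(dim(S) == 21L)) stop("S must be 21x21")
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) stop("S must be symmetric")
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(eg$values) < -tol * max(1, max(abs(eg$values)))) {
    stop("S is not positive semi-definite")
  }
  V <- .fix_sign(eg$vectors)
  E <- lapply(seq_len(21L), function(i) unvech_scaled(V[, i]))
  tensor_eigen <- lapply(E, eigen_decompose)
  coords <- NULL
  if (inherits(tensor, "covariance_tensor")) {
    Gc <- tensor$G_means
    Gbar <- Reduce(`+`, Gc) / length(Gc)
    coords <- t(vapply(Gc, function(g) {
      vapply(E, function(e) sum((g - Gbar) * e), numeric(1))
    }, numeric(21)))
    rownames(coords) <- tensor$populations
  }
  alpha_draws <- NULL
  if (inherits(tensor, "covariance_tensor") && !is.null(tensor$S_draws)) {
    alpha_draws <- t(apply(tensor$S_draws, 3L, function(s) {
      eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
    }))
  }
  structure(list(alpha = pmax(eg$values, 0), alpha_draws = alpha_draws,
                 E = E, tensor_eigen = tensor_eigen,
                 coordinates = coords, S = S),
            class = "eigentensor_decomposition")
}

#' Finite-sampling null distribution of eigentensor eigenvalues
#'
#' Reference distribution for `alpha_i` under no true differentiation:
#' for each replicate, line effects for every population are simulated from
#' a single pooled G-matrix with the stated finite number of lines, each
#' population's G re-estimated as half the sample line covariance, and the
#' eigentensor eigenvalues of the re-estimated set recorded.
#'
#' @param G_list As in [build_covariance_tensor()]; the pooled G is the mean
#'   of the population means.
#' @param n_lines_per_pop Number of lines sampled per population (scalar or
#'   vector of length m).
#' @param n_rep Number of null replicates.
#' @param seed Integer seed.
#' @return Matrix `n_rep x 21` of null `alpha` values (sorted decreasing per
#'   row), with attribute `"q95"` (per-index 95th percentile).
#' @export
tensor_sampling_null <- function(G_list, n_lines_per_pop, n_rep = 1000L,
                                 seed = 1L) {
  arrs <- lapply(G_list, function(g) {
    if (inherits(g, "gmatrix_posterior")) return(g$G_mean)
    if (is.array(g) && length(dim(g)) == 3L) return(apply(g, c(1, 2), mean))
    g
  })
  m <- length(arrs)
  if (length(n_lines_per_pop) == 1L) n_lines_per_pop <- rep(n_lines_per_pop, m)
  G_pool <- Reduce(`+`, arrs) / m
  G_pool <- .nearest_psd(G_pool)
  set.seed(seed)
  out <- matrix(NA_real_, n_rep, 21L)
  for (r in seq_len(n_rep)) {
    Gs <- lapply(seq_len(m), function(p) {
      eff <- .rmvn(n_lines_per_pop[p], 2 * G_pool)
      stats::cov(eff) / 2
    })
    tn <- build_covariance_tensor(Gs)
    out[r, ] <- eigen(tn$S, symmetric = TRUE, only.values = TRUE)$values
  }
  out <- pmax(out, 0)
  attr(out, "q95") <- apply(out, 2L, stats::quantile, probs = 0.95)
  out
}

.nearest_psd <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  out <- eg$vectors %*% (ev * t(eg$vectors))
  dimnames(out) <- dimnames(M)
  out
}
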