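#' Convert log fertility estimates to relative fitness
#'
#' Exponentiates log-scale (covariate-adjusted) fertility values and divides
#' by their mean so that mean relative fitness is exactly 1.
#'
#' @param x Numeric vector of log fertility values, or a `data.frame` with
#'   `line_id` and a `fertility` (or second) column.
#' @return Numeric vector of relative fitness, or a `data.frame` with
#'   columns `line_id`, `fitness`.
#' @examples
#' prepare_relative_fitness(c(0, log(2)))  # 2/3, 4/3
#' @export
prepare_relative_fitness <- function(x) {
  if (is.data.frame(x)) {
    val_col <- if ("fertility" %in% names(x)) "fertility" else
      setdiff(names(x), "line_id")[1]
    w <- prepare_relative_fitness(x[[val_col]])
    return(data.frame(line_id = x$line_id, fitness = w,
                      stringsAsFactors = FALSE))
  }
  if (any(!is.finite(x))) stop("fertility values must be finite")
  e <- exp(x)
  e / mean(e)
}

# quadratic design matrix: 1/2 z_k^2 columns then z_k1 z_k2 cross products
.gamma_design <- function(Z, covariates = NULL, include_linear = FALSE) {
  n <- nrow(Z)
  quad <- 0.5 * Z^2
  colnames(quad) <- paste0("q_", colnames(Z))
  cross <- matrix(NA_real_, n, 15L)
  cn <- character(15L)
  k <- 0L
  for (k1 in 1:5) for (k2 in (k1 + 1):6) {
    k <- k + 1L
    cross[, k] <- Z[, k1] * Z[, k2]
    cn[k] <- paste0("c_", colnames(Z)[k1], "_", colnames(Z)[k2])
  }
  colnames(cross) <- cn
  X <- cbind(`(Intercept)` = 1, quad, cross)
  if (include_linear) {
    lin <- Z
    colnames(lin) <- paste0("l_", colnames(Z))
    X <- cbind(X, lin)
  }
  if (!is.null(covariates)) {
    covariates <- scale(as.matrix(covariates))
    X <- cbind(X, covariates)
  }
  X
}

#' Fit the quadratic selection surface (gamma matrix)
#'
#' Bayesian linear regression of relative fitness on the quadratic design
#' `w = alpha + 1/2 sum_k gamma_kk z_k^2 + sum_{k1<k2} gamma_k1k2 z_k1 z_k2
#' + e`, with the 1/2 factor built into the diagonal design columns so the
#' reported coefficients are the quadratic selection gradients gamma without
#' post-hoc doubling. Traits are centered before the quadratic terms are
#' formed. Posterior draws use the conjugate normal-inverse-chi-squared
#' posterior under a flat prior (so the posterior mode equals the
#' least-squares estimate). Linear (directional) terms are excluded by
#' default and can be added with `include_linear = TRUE`.
#'
#' @param traits `data.frame` (with `line_id` and the six trait columns) or
#'   matrix of line trait means.
#' @param fitness `data.frame` with `line_id`, `fitness`, or a numeric
#'   vector aligned with `traits`.
#' @param covariates Optional matrix/data.frame of environmental covariates
#'   (standardized internally).
#' @param n_draws Posterior draws.
#' @param include_linear Add linear selection gradients to the design.
#' @param seed Integer seed.
#' @return Object of class `gamma_fit`: `gamma` (6x6 posterior-mode matrix),
#'   `gamma_draws` (6x6x`n_draws`), `alpha`, `summary` (per-element mean,
#'   mode, 2.5/8.5/91.5/97.5 percent quantiles), `residual_normality`
#'   (Shapiro-Wilk p-value).
#' @export
fit_gamma <- function(traits, fitness, covariates = NULL, n_draws = 1000L,
                      include_linear = FALSE, seed = 1L) {
  Z <- .trait_matrix(traits)
  Z <- sweep(Z, 2L, colMeans(Z))
  if (is.data.frame(fitness)) {
    idx <- match(rownames(Z), fitness$line_id)
    if (anyNA(idx)) stop("fitness table is missing lines present in traits")
    w <- fitness$fitness[idx]
  } else w <- fitness
  if (length(w) != nrow(Z)) stop("trait/fitness dimension mismatch")
  n <- nrow(Z)
  X <- .gamma_design(Z, covariates, include_linear)
  p <- ncol(X)
  if (n <= p) stop("more parameters (", p, ") than lines (", n, ")")
  if (n < 10 * p) warning("fewer than ~10 lines per parameter; gamma estimates will be noisy")
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  }
  beta_hat <- qr.coef(qrX, w)
  res <- w - drop(X %*% beta_hat)
  s2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  set.seed(seed)
  sig2 <- (n - p) * s2 / stats::rchisq(n_draws, n - p)
  cXtX <- chol((XtX_inv + t(XtX_inv)) / 2)
  B <- matrix(stats::rnorm(n_draws * p), n_draws, p) %*% cXtX
  B <- sweep(B * sqrt(sig2), 2L, beta_hat, "+")
  colnames(B) <- colnames(X)

  to_gamma <- function(b) {
    g <- diag(b[paste0("q_", trait_names)])
    k <- 0L
    for (k1 in 1:5) for (k2 in (k1 + 1):6) {
      k <- k + 1L
      g[k1, k2] <- g[k2, k1] <-
        b[paste0("c_", trait_names[k1], "_", trait_names[k2])]
    }
    dimnames(g) <- list(trait_names, trait_names)
    g
  }
  gamma_draws <- array(NA_real_, c(6, 6, n_draws),
                       dimnames = list(trait_names, trait_names, NULL))
  for (dr in seq_len(n_draws)) gamma_draws[, , dr] <- to_gamma(B[dr, ])
  sw <- if (n >= 10 && n <= 5000) stats::shapiro.test(res)$p.value else NA_real_
  structure(list(
    gamma = to_gamma(beta_hat), gamma_draws = gamma_draws,
    alpha = beta_hat[["(Intercept)"]],
    beta_draws = B, summary = .gmatrix_summary(gamma_draws),
    residual_normality = sw, n_lines = n
  ), class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("Quadratic selection surface (gamma), ", x$n_lines, " lines\n", sep = "")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Canonical analysis of the selection surface
#'
#' Rotates the gamma matrix into its eigenbasis, `Lambda = U' gamma U`:
#' positive eigenvalues indicate disruptive selection along the canonical
#' axis, negative ones stabilizing selection. Eigenvalues are sorted in
#' decreasing order.
#'
#' @param gamma A symmetric 6x6 matrix or a `gamma_fit` (whose posterior
#'   draws then yield eigenvalue credible intervals).
#' @return Object of class `canonical_decomposition`: `U` (orthogonal,
#'   columns = canonical axes y1..y6), `lambda`, `classification`
#'   (disruptive/stabilizing), and if draws are available `lambda_draws`
#'   plus quantile summaries.
#' @export
canonical_analysis <- function(gamma) {
  draws <- NULL
  if (inherits(gamma, "gamma_fit")) {
    draws <- gamma$gamma_draws
    gamma <- gamma$gamma
  }
  es <- eigen_decompose(gamma)
  out <- list(U = es$vectors, lambda = es$values,
              classification = ifelse(es$values > 0, "disruptive",
                                      "stabilizing"))
  colnames(out$U) <- paste0("y", 1:6)
  if (!is.null(draws)) {
    out$lambda_draws <- t(apply(draws, 3L, function(g) {
      eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
    }))
    out$lambda_mode <- apply(out$lambda_draws, 2L, .post_mode)
    out$lambda_q <- apply(out$lambda_draws, 2L, stats::quantile,
                          probs = c(0.025, 0.085, 0.915, 0.975))
  }
  structure(out, class = "canonical_decomposition")
}

#' Rotate a G-matrix into the canonical selection frame
#'
#' Computes `G' = U' G U`. The diagonal of `G'` is the genetic variance
#' along each canonical axis; the trace is preserved.
#'
#' @param G Symmetric matrix (or 6x6xD draw array, rotated per draw).
#' @param U Orthogonal matrix (checked to 1e-8).
#' @return Rotated matrix (or array).
#' @export
rotate_gmatrix <- function(G, U) {
  if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8) {
    stop("U is not orthogonal")
  }
  if (is.array(G) && length(dim(G)) == 3L) {
    out <- array(NA_real_, dim(G))
    for (dr in seq_len(dim(G)[3])) out[, , dr] <- t(U) %*% G[, , dr] %*% U
    return(out)
  }
  t(U) %*% G %*% U
}

#' Permutation null for the rotated selection eigenvalues
#'
#' For each permutation, relative fitness values are shuffled across lines,
#' gamma is re-estimated (least-squares point estimate, i.e. the posterior
#' mode), and the resulting matrix is rotated by the FIXED observed `U`;
#' the diagonal is retained. This is the null distribution against which
#' the observed canonical eigenvalues are judged.
#'
#' @inheritParams fit_gamma
#' @param U_fixed Canonical axes from the observed fit.
#' @param n_perm Number of permutations.
#' @return Matrix `n_perm x 6` of null rotated diagonals, with attribute
#'   `"quantiles"` (2.5/5/95/97.5 percent per axis).
#' @export
null_lambda_distribution <- function(traits, fitness, U_fixed,
                                     n_perm = 1000L, covariates = NULL,
                                     seed = 1L) {
  Z <- .trait_matrix(traits)
  Z <- sweep(Z, 2L, colMeans(Z))
  if (is.data.frame(fitness)) {
    w <- fitness$fitness[match(rownames(Z), fitness$line_id)]
  } else w <- fitness
  X <- .gamma_design(Z, covariates)
  qrX <- qr(X)
  set.seed(seed)
  out <- matrix(NA_real_, n_perm, 6L,
                dimnames = list(NULL, paste0("y", 1:6)))
  for (r in seq_len(n_perm)) {
    b <- qr.coef(qrX, sample(w))
    g <- diag(b[paste0("q_", trait_names)])
    k <- 0L
    for (k1 in 1:5) for (k2 in (k1 + 1):6) {
      k <- k + 1L
      g[k1, k2] <- g[k2, k1] <-
        b[paste0("c_", trait_names[k1], "_", trait_names[k2])]
    }
    out[r, ] <- diag(t(U_fixed) %*% g %*% U_fixed)
  }
  attr(out, "quantiles") <- apply(out, 2L, stats::quantile,
                                  probs = c(0.025, 0.05, 0.95, 0.975))
  out
}

#' Alignment of divergence directions with the selection surface
#'
#' Pearson correlations between trait-space directions of genetic divergence
#' (eigentensor eigenvectors `e_ij`) and the canonical selection axes
#' `y1..y6`, with uncertainty propagated by recomputing the canonical axes
#' for each posterior draw of gamma.
#'
#' @param tensor_vectors Named list of unit 6-vectors (e.g. `e11`, `e12`).
#' @param gamma_fit A `gamma_fit` object.
#' @param n_draws Posterior draws of gamma to use.
#' @return `data.frame` with one row per (vector, axis): posterior mean of
#'   the signed correlation `r`, mean `|r|`, and 2.5/97.5 percent quantiles
#'   of `|r|`.
#' @export
alignment_correlations <- function(tensor_vectors, gamma_fit,
                                   n_draws = 1000L) {
  stopifnot(inherits(gamma_fit, "gamma_fit"))
  D <- min(n_draws, dim(gamma_fit$gamma_draws)[3])
  vv <- lapply(tensor_vectors, function(v) {
    if (length(v) != 6L) stop("tensor vectors must have length 6")
    v / sqrt(sum(v^2))
  })
  res <- array(NA_real_, c(length(vv), 6L, D))
  for (dr in seq_len(D)) {
    U <- eigen_decompose(gamma_fit$gamma_draws[, , dr])$vectors
    for (i in seq_along(vv)) res[i, , dr] <- stats::cor(vv[[i]], U)
  }
  out <- do.call(rbind, lapply(seq_along(vv), function(i) {
    do.call(rbind, lapply(1:6, function(j) {
      r <- res[i, j, ]
      data.frame(vector = names(vv)[i] %||% paste0("v", i),
                 axis = paste0("y", j),
                 r_mean = mean(r), abs_r_mean = mean(abs(r)),
                 abs_r_q2.5 = stats::quantile(abs(r), 0.025)[[1]],
                 abs_r_q97.5 = stats::quantile(abs(r), 0.975)[[1]],
                 row.names = NULL)
    }))
  }))
  out
}
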