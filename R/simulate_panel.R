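#' Configuration for the inbred-line panel simulator
#'
#' Generative counterpart of the multivariate mixed model used for G-matrix
#' estimation: line effects are drawn from a 6-variate normal with covariance
#' `2 * G_true` (so that half the between-line covariance equals `G_true`,
#' the broad-sense convention for panels of inbred lines), block effects and
#' standardized environmental covariates (temperature, humidity, density) are
#' added, and technical-replicate residuals complete the record.
#'
#' @param G_true 6x6 symmetric positive semi-definite genetic covariance of
#'   the log transition rates (trait order `SF, SB, FS, FB, BS, BF`).
#' @param n_lines Number of inbred lines (>= 2).
#' @param blocks_per_line Technical replicates (blocks) per line, >= 2.
#' @param covariate_effect_matrix 6x3 matrix of fixed effects of the
#'   standardized covariates (columns: temperature, humidity, density).
#' @param block_sd Per-trait standard deviation of block effects (length 1
#'   or 6).
#' @param residual_cov 6x6 PSD residual covariance.
#' @param grand_mean Length-6 vector of trait means (log rates).
#' @param lines_per_block Approximate number of lines sharing a block.
#' @param population Population label stored in the table.
#' @param seed Integer seed.
#' @return Object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(G_true,
                             n_lines = 150L,
                             blocks_per_line = 3L,
                             covariate_effect_matrix = matrix(0, 6, 3),
                             block_sd = 0.1,
                             residual_cov = diag(0.5, 6),
                             grand_mean = rep(log(2), 6),
                             lines_per_block = 20L,
                             population = "A0",
                             seed = 1L) {
  .check_psd(G_true, "G_true")
  .check_psd(residual_cov, "residual_cov")
  if (n_lines < 2L) stop("n_lines must be >= 2 (no between-line variance otherwise)")
  if (blocks_per_line < 2L) stop("blocks_per_line must be >= 2")
  if (!all(dim(covariate_effect_matrix) == c(6L, 3L))) {
    stop("covariate_effect_matrix must be 6x3 (traits x [T, H, D])")
  }
  if (length(block_sd) == 1L) block_sd <- rep(block_sd, 6L)
  structure(list(G_true = G_true, n_lines = as.integer(n_lines),
                 blocks_per_line = as.integer(blocks_per_line),
                 covariate_effect_matrix = covariate_effect_matrix,
                 block_sd = block_sd, residual_cov = residual_cov,
                 grand_mean = grand_mean,
                 lines_per_block = as.integer(lines_per_block),
                 population = population, seed = as.integer(seed)),
            class = "panel_sim_config")
}

.check_psd <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop(name, " must be a square matrix")
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(name, " must be symmetric")
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) stop(name, " must be positive semi-definite")
  invisible(TRUE)
}

# MVN draws tolerating singular covariance
.rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  matrix(stats::rnorm(n * p), n, p) %*% t(eg$vectors %*% diag(sqrt(ev), p))
}

#' Simulate an inbred-line phenotype table
#'
#' @param config A [panel_sim_config()].
#' @return `data.frame` with columns `line_id`, `population`, `block_id`,
#'   `temperature`, `humidity`, `density` (standardized covariates) and the
#'   six log transition-rate traits (`SF` ... `BF`). The drawn line effects
#'   are attached as attribute `"line_effects"` for recovery checks.
#' @export
simulate_line_phenotypes <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n_blocks <- max(config$blocks_per_line,
                  ceiling(config$n_lines * config$blocks_per_line /
                            config$lines_per_block))
  line_eff <- .rmvn(config$n_lines, 2 * config$G_true)
  block_eff <- sapply(config$block_sd, function(s) stats::rnorm(n_blocks, 0, s))
  block_cov <- matrix(stats::rnorm(n_blocks * 3L), n_blocks, 3L)  # T, H, D per block

  rows_line <- rep(seq_len(config$n_lines), each = config$blocks_per_line)
  # assign each line to distinct random blocks
  rows_block <- unlist(lapply(seq_len(config$n_lines), function(i) {
    sample.int(n_blocks, config$blocks_per_line)
  }))
  n <- length(rows_line)
  covs <- block_cov[rows_block, , drop = FALSE]
  covs <- scale(covs)                       # standardized to mean 0, sd 1
  y <- matrix(config$grand_mean, n, 6L, byrow = TRUE) +
    line_eff[rows_line, , drop = FALSE] +
    block_eff[rows_block, , drop = FALSE] +
    covs %*% t(config$covariate_effect_matrix) +
    .rmvn(n, config$residual_cov)
  colnames(y) <- trait_names
  out <- data.frame(
    line_id = sprintf("L%04d", rows_line),
    population = config$population,
    block_id = sprintf("B%03d", rows_block),
    temperature = covs[, 1L], humidity = covs[, 2L], density = covs[, 3L],
    y, stringsAsFactors = FALSE
  )
  attr(out, "line_effects") <- line_eff
  out
}

#' Configuration for the line-fitness simulator
#'
#' @param gamma_true 6x6 symmetric matrix of quadratic selection gradients.
#' @param alpha Mean relative fitness.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Object of class `fitness_sim_config`.
#' @export
fitness_sim_config <- function(gamma_true, alpha = 1, noise_sd = 0.1, seed = 1L) {
  if (!is.matrix(gamma_true) || !all(dim(gamma_true) == c(6L, 6L))) {
    stop("gamma_true must be 6x6")
  }
  if (max(abs(gamma_true - t(gamma_true))) > 1e-8) stop("gamma_true must be symmetric")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(gamma_true = gamma_true, alpha = alpha,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fitness_sim_config")
}

#' Simulate line fitness from a quadratic selection surface
#'
#' Relative fitness follows
#' `w = alpha + 1/2 sum_k gamma_kk z_k^2 + sum_{k1<k2} gamma_k1k2 z_k1 z_k2
#' + e`, with `e ~ Normal(0, noise_sd^2)` and `z` the centered line trait
#' values.
#'
#' @param traits `data.frame` with `line_id` and the six trait columns
#'   (centered), or a matrix of line trait means with rownames as line ids.
#' @param config A [fitness_sim_config()].
#' @return `data.frame` with columns `line_id`, `fitness`.
#' @export
simulate_fitness <- function(traits, config) {
  stopifnot(inherits(config, "fitness_sim_config"))
  Z <- .trait_matrix(traits)
  if (ncol(Z) != ncol(config$gamma_true)) {
    stop("trait/gamma dimension mismatch: ", ncol(Z), " traits vs ",
         ncol(config$gamma_true), " gamma columns")
  }
  set.seed(config$seed)
  g <- config$gamma_true
  quad <- 0.5 * rowSums((Z %*% diag(diag(g))) * Z)
  cross <- numeric(nrow(Z))
  for (k1 in 1:5) for (k2 in (k1 + 1):6) {
    cross <- cross + g[k1, k2] * Z[, k1] * Z[, k2]
  }
  w <- config$alpha + quad + cross + stats::rnorm(nrow(Z), 0, config$noise_sd)
  data.frame(line_id = rownames(Z), fitness = w, stringsAsFactors = FALSE)
}

.trait_matrix <- function(traits) {
  if (is.matrix(traits)) {
    Z <- traits
    if (is.null(rownames(Z))) rownames(Z) <- sprintf("L%04d", seq_len(nrow(Z)))
    return(Z)
  }
  if (!all(trait_names %in% names(traits))) {
    stop("traits must contain columns ", paste(trait_names, collapse = ", "))
  }
  Z <- as.matrix(traits[, trait_names])
  rownames(Z) <- if ("line_id" %in% names(traits)) traits$line_id else
    sprintf("L%04d", seq_len(nrow(Z)))
  Z
}

#' Individual-based drift simulation under the infinitesimal model
#'
#' Tracks the realized genetic covariance matrix of `Ne` diploid parents over
#' generations of random mating and drift. Offspring breeding values are the
#' midparent value plus a segregation deviation with covariance half the
#' current realized G, which reproduces the expected geometric decay of
#' genetic variance `(1 - 1/(2*Ne))^t`.
#'
#' @param G0 6x6 PSD ancestral genetic covariance.
#' @param Ne Effective (= census, here) population size, >= 2.
#' @param generations Number of generations (>= 0).
#' @param seed Integer seed.
#' @return Array `6 x 6 x (generations + 1)` of realized G matrices;
#'   slice 1 is the realized ancestral G.
#' @export
simulate_drift_panel <- function(G0, Ne, generations, seed = 1L) {
  .check_psd(G0, "G0")
  if (Ne < 2) stop("Ne must be >= 2")
  if (generations < 0) stop("generations must be >= 0")
  set.seed(seed)
  p <- ncol(G0)
  Z <- .rmvn(Ne, G0)
  out <- array(NA_real_, c(p, p, generations + 1L))
  out[, , 1L] <- stats::cov(Z)
  if (generations > 0) for (g in seq_len(generations)) {
    Gc <- stats::cov(Z)
    dams <- sample.int(Ne, Ne, replace = TRUE)
    sires <- sample.int(Ne, Ne, replace = TRUE)
    mid <- (Z[dams, , drop = FALSE] + Z[sires, , drop = FALSE]) / 2
    Z <- mid + .rmvn(Ne, Gc / 2)
    out[, , g + 1L] <- stats::cov(Z)
  }
  dimnames(out) <- list(colnames(G0), colnames(G0), NULL)
  out
}
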