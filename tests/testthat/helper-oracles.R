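# Independent oracles and shared fixtures for the test suite.

# truncated Taylor-series matrix exponential (oracle for P(dt) = exp(dt Q))
expm_series <- function(A, order = 80L) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# brute-force per-pair log-likelihood over raw track observations; per-pair
# terms are collected and summed once so floating-point accumulation error
# stays below the comparison tolerance
naive_loglik <- function(Q, tracks) {
  terms <- lapply(unique(tracks$track_id), function(tid) {
    d <- tracks[tracks$track_id == tid, ]
    d <- d[order(d$time_s), ]
    if (nrow(d) < 2L) return(numeric(0))
    i <- match(d$state, worm_states)
    vapply(seq_len(nrow(d) - 1L), function(l) {
      P <- transition_probability(Q, d$time_s[l + 1L] - d$time_s[l])
      log(P[i[l], i[l + 1L]])
    }, numeric(1))
  })
  sum(unlist(terms))
}

# asymmetric example rate matrix used across tests
example_theta <- c(SF = 2, SB = 0.5, FS = 0.5, FB = 0.5, BS = 0.5, BF = 0.5)
example_Q <- rate_matrix(example_theta)

# strongly elliptical planted G mirroring an ancestral lab-adapted matrix
planted_G <- function(lead = 0.6, floor = 0.025) {
  v1 <- c(1, 1, -1, -1, -1, -1) / sqrt(6)
  G <- lead * tcrossprod(v1) + diag(floor, 6)
  dimnames(G) <- list(trait_names, trait_names)
  G
}

# planted quadratic selection surface with distinct eigenvalues
planted_gamma <- function() {
  g <- matrix(0.04, 6, 6)
  diag(g) <- c(0.3, 0.15, 0.05, -0.05, -0.15, -0.4)
  g <- (g + t(g)) / 2
  dimnames(g) <- list(trait_names, trait_names)
  g
}

# centered line trait means for selection tests
random_line_traits <- function(n_lines, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(n_lines * 6), n_lines, 6)
  colnames(Z) <- trait_names
  rownames(Z) <- sprintf("L%04d", seq_len(n_lines))
  sweep(Z, 2, colMeans(Z))
}

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")
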