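#' Movement states and trait order
#'
#' Locomotion is described by three movement states: still (`S`), forward
#' (`F`) and backward (`B`), in that fixed index order. The six non-self
#' transition rates between them, in the fixed order
#' `SF, SB, FS, FB, BS, BF`, are the component traits used throughout the
#' package (on the natural-log scale when treated as phenotypes).
#'
#' @format `worm_states` is a character vector of length 3; `trait_names` a
#'   character vector of length 6.
#' @export
worm_states <- c("S", "F", "B")

#' @rdname worm_states
#' @export
trait_names <- c("SF", "SB", "FS", "FB", "BS", "BF")

# index pairs (from, to) for the six rates, in trait_names order
.rate_index <- cbind(
  from = c(1L, 1L, 2L, 2L, 3L, 3L),
  to   = c(2L, 3L, 1L, 3L, 1L, 2L)
)

#' Construct a transition-rate matrix
#'
#' Builds the 3x3 generator `Q` of the continuous-time Markov chain over
#' movement states from the six non-self rates. Diagonals are set to minus
#' the corresponding row sums so that every row of `Q` sums to zero.
#'
#' @param theta Numeric vector of the six non-self transition rates
#'   (per second), in the order `SF, SB, FS, FB, BS, BF`. A full 3x3 matrix
#'   is also accepted and validated.
#' @return A 3x3 numeric matrix with `worm_states` dimnames.
#' @examples
#' Q <- rate_matrix(c(2, 0.5, 0.5, 0.5, 0.5, 0.5))
#' rowSums(Q)  # all zero
#' @export
rate_matrix <- function(theta) {
  if (is.matrix(theta)) {
    validate_rate_matrix(theta)
    Q <- theta
    dimnames(Q) <- list(worm_states, worm_states)
    return(Q)
  }
  if (length(theta) != 6L || !is.numeric(theta)) {
    stop("theta must be the six non-self rates (SF, SB, FS, FB, BS, BF)")
  }
  if (any(!is.finite(theta))) stop("transition rates must be finite")
  if (any(theta < 0)) stop("transition rates must be non-negative")
  Q <- matrix(0, 3, 3, dimnames = list(worm_states, worm_states))
  Q[.rate_index] <- theta
  diag(Q) <- -rowSums(Q)
  Q
}

#' Extract the six non-self rates from a rate matrix
#'
#' @param Q A valid 3x3 rate matrix.
#' @return Named numeric vector in `trait_names` order.
#' @export
rate_theta <- function(Q) {
  validate_rate_matrix(Q)
  stats::setNames(Q[.rate_index], trait_names)
}

#' Validate a transition-rate matrix
#'
#' Checks that `Q` is a finite 3x3 matrix with non-negative off-diagonal
#' entries and rows summing to zero.
#'
#' @param Q Matrix to check.
#' @param tol Tolerance on the zero row sums.
#' @return Invisibly `TRUE`; otherwise an error naming the violated
#'   constraint.
#' @export
validate_rate_matrix <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || !identical(dim(Q), c(3L, 3L))) {
    stop("Q must be a 3x3 matrix")
  }
  if (any(!is.finite(Q))) stop("Q contains non-finite entries")
  off <- Q[row(Q) != col(Q)]
  if (any(off < -tol)) stop("Q has negative off-diagonal rates")
  rs <- rowSums(Q)
  if (any(abs(rs) > tol * max(1, max(abs(Q))))) {
    stop("Q rows must sum to zero (diagonal = -sum of off-diagonal rates)")
  }
  invisible(TRUE)
}

# Eigendecomposition of Q reusable across many dt values; falls back to
# Matrix::expm when Q is numerically defective.
.q_propagator <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eg)) tryCatch(solve(eg$vectors), error = function(e) NULL)
  ok <- !is.null(Vi) &&
    max(Mod(eg$vectors %*% (eg$values * Vi) - Q)) < 1e-9 * max(1, max(abs(Q)))
  if (ok) {
    function(dt) {
      P <- Re(eg$vectors %*% (exp(eg$values * dt) * Vi))
      .clean_stochastic(P)
    }
  } else {
    function(dt) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(dt * Q)))
      .clean_stochastic(P)
    }
  }
}

.clean_stochastic <- function(P) {
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1 & P < 1 + 1e-12] <- 1
  dimnames(P) <- list(worm_states, worm_states)
  P
}

#' Transition probabilities over a time interval
#'
#' Computes `P(dt) = exp(dt * Q)`, the matrix of probabilities of occupying
#' state `j` after `dt` seconds given state `i` now.
#'
#' @param Q A valid rate matrix (see [rate_matrix()]).
#' @param dt Non-negative time interval in seconds.
#' @return A 3x3 stochastic matrix (rows sum to 1).
#' @examples
#' Q <- rate_matrix(rep(1, 6))
#' transition_probability(Q, log(2) / 3)  # diagonal 2/3, off-diagonal 1/6
#' @export
transition_probability <- function(Q, dt) {
  validate_rate_matrix(Q)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop("dt must be a single non-negative number of seconds")
  }
  .q_propagator(Q)(dt)
}

#' Stationary distribution of the movement-state chain
#'
#' Solves `f Q = 0` with `sum(f) = 1`. For an irreducible chain this equals
#' any row of `P(Inf)`: the long-run relative frequency of each state.
#'
#' @param Q A valid rate matrix.
#' @return Named numeric 3-vector of state frequencies.
#' @export
stationary_distribution <- function(Q) {
  validate_rate_matrix(Q)
  ev <- eigen(t(Q))
  null_idx <- which(abs(ev$values) < 1e-9 * max(1, max(abs(Q))))
  if (length(null_idx) > 1L) {
    stop("Q is reducible: stationary distribution is not unique")
  }
  if (length(null_idx) == 0L) null_idx <- which.min(abs(ev$values))
  f <- Re(ev$vectors[, null_idx])
  f <- f / sum(f)
  if (any(f < -1e-10)) stop("Q is reducible or invalid: negative stationary mass")
  f[f < 0] <- 0
  f <- f / sum(f)
  if (any(f < 1e-12)) {
    warning("stationary distribution has zero mass in some state (boundary/absorbing chain)")
  }
  stats::setNames(f, worm_states)
}
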