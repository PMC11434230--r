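#' Expected genetic variance under drift
#'
#' Under the infinitesimal model, genetic variance is lost at rate
#' `V / (2 Ne)` per generation, giving the geometric decay
#' `V(t) = V0 (1 - 1/(2 Ne))^t`.
#'
#' @param V0 Initial variance (>= 0); vectorized.
#' @param Ne Effective population size (>= 1).
#' @param t Generations (>= 0); vectorized.
#' @return Expected variance after `t` generations.
#' @examples
#' drift_decay(1, 1000, 100)  # 0.95122
#' @export
drift_decay <- function(V0, Ne, t) {
  if (any(Ne < 1)) stop("Ne must be >= 1")
  if (any(t < 0)) stop("t must be >= 0")
  if (any(V0 < 0)) stop("V0 must be >= 0")
  V0 * (1 - 1 / (2 * Ne))^t
}

#' Compare observed projected variances against the drift expectation
#'
#' Rotates each generation's G-matrix posterior into the canonical frame,
#' summarizes the genetic variance along each canonical axis, and compares
#' the evolved posteriors against the drift trajectory anchored at the
#' ancestral posterior (mode by default). An axis/generation is flagged when
#' its 95 percent credible interval excludes the drift expectation.
#'
#' @param G_posteriors_by_generation Named list of `gmatrix_posterior`
#'   objects (or 6x6xD arrays); names are generation numbers and must
#'   include `"0"` (the ancestral population).
#' @param U Orthogonal rotation (canonical axes).
#' @param Ne Effective population size.
#' @param anchor `"mode"` (default) or `"mean"`: ancestral summary anchoring
#'   the trajectory.
#' @return `data.frame` with columns `axis`, `generation`, `expected`,
#'   `mode`, `q2.5`, `q8.5`, `q91.5`, `q97.5`, `flagged`.
#' @export
drift_envelope_compare <- function(G_posteriors_by_generation, U, Ne,
                                   anchor = c("mode", "mean")) {
  anchor <- match.arg(anchor)
  gens <- suppressWarnings(as.numeric(names(G_posteriors_by_generation)))
  if (anyNA(gens)) stop("list names must be generation numbers")
  if (!any(gens == 0)) stop("missing ancestral generation \"0\"")
  arrs <- lapply(G_posteriors_by_generation, function(g) {
    if (inherits(g, "gmatrix_posterior")) g$G_draws else g
  })
  rot <- lapply(arrs, rotate_gmatrix, U = U)
  axis_var <- lapply(rot, function(a) {
    t(apply(a, 3L, diag))                    # draws x 6
  })
  anc <- axis_var[[which(gens == 0)]]
  V0 <- if (anchor == "mode") apply(anc, 2L, .post_mode) else colMeans(anc)
  out <- do.call(rbind, lapply(seq_along(gens), function(gi) {
    av <- axis_var[[gi]]
    do.call(rbind, lapply(1:6, function(ax) {
      x <- av[, ax]
      q <- stats::quantile(x, c(0.025, 0.085, 0.915, 0.975))
      expd <- drift_decay(V0[ax], Ne, gens[gi])
      data.frame(axis = paste0("y", ax), generation = gens[gi],
                 expected = expd, mode = .post_mode(x),
                 q2.5 = q[[1]], q8.5 = q[[2]], q91.5 = q[[3]], q97.5 = q[[4]],
                 flagged = expd < q[[1]] | expd > q[[4]],
                 row.names = NULL)
    }))
  }))
  out
}
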