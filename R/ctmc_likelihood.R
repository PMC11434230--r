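#' Compress tracks into transition counts by time lag
#'
#' Every consecutive pair of observations within a track contributes one
#' transition `(state_l, state_{l+1})` at lag `dt = t_{l+1} - t_l`. The pairs
#' are tallied into one 3x3 count matrix per distinct lag, which is a lossless
#' sufficient statistic for the time-homogeneous Markov likelihood: the
#' compressed likelihood equals the per-pair sum exactly. Lags closer than
#' `dt_tolerance` are merged onto their (count-weighted) mean lag.
#'
#' @param tracks Track `data.frame` (`track_id`, `plate_id`, `time_s`,
#'   `state`).
#' @param dt_tolerance Non-negative merge tolerance on lags, in seconds.
#' @return An object of class `transition_counts`: list with `dt` (sorted
#'   unique lags), `counts` (3x3xK integer array), `n_pairs`, `plates`.
#' @export
compress_tracks <- function(tracks, dt_tolerance = 1e-6) {
  if (dt_tolerance < 0) stop("dt_tolerance must be >= 0")
  empty <- structure(list(dt = numeric(), counts = array(0L, c(3, 3, 0)),
                          n_pairs = 0L, plates = character()),
                     class = "transition_counts")
  if (is.null(tracks) || nrow(tracks) == 0L) return(empty)
  dt_tab <- data.table::as.data.table(tracks)
  data.table::setorder(dt_tab, track_id, time_s)
  dt_tab[, `:=`(si = match(state, worm_states))]
  if (anyNA(dt_tab$si)) stop("tracks contain invalid state symbols")
  dt_tab[, `:=`(
    dt = c(diff(time_s), NA_real_),
    sj = c(si[-1L], NA_integer_)
  ), by = track_id]
  bad <- dt_tab[!is.na(dt) & dt <= 0]
  if (nrow(bad)) {
    stop("non-increasing timestamps in track ", bad$track_id[1])
  }
  pairs <- dt_tab[!is.na(dt)]
  if (nrow(pairs) == 0L) return(empty)
  # merge lags within tolerance: cluster sorted unique lags greedily
  u <- sort(unique(pairs$dt))
  cl <- cumsum(c(1, diff(u) > dt_tolerance))
  key <- data.table::data.table(dt = u, cl = cl)
  pairs <- key[pairs, on = "dt"]
  tab <- pairs[, .N, by = .(cl, si, sj)]
  rep_dt <- pairs[, .(dtm = sum(dt) / .N), by = cl][order(cl)]
  K <- nrow(rep_dt)
  counts <- array(0L, c(3, 3, K))
  tab[, cli := match(cl, rep_dt$cl)]
  counts[cbind(tab$si, tab$sj, tab$cli)] <- tab$N
  structure(list(dt = rep_dt$dtm, counts = counts,
                 n_pairs = nrow(pairs),
                 plates = sort(unique(tracks$plate_id))),
            class = "transition_counts")
}

#' Log-likelihood of a rate matrix given compressed transition counts
#'
#' For each distinct lag the transition-probability matrix `P(dt) =
#' exp(dt * Q)` is computed once and the contribution is the sum of
#' `count * log(p)` over its 3x3 cells (the Hadamard-product form of the
#' Markov likelihood). Cells with zero count contribute nothing; a positive
#' count where `p = 0` yields `-Inf`.
#'
#' @param Q A valid rate matrix.
#' @param counts A `transition_counts` object.
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
log_likelihood <- function(Q, counts) {
  validate_rate_matrix(Q)
  stopifnot(inherits(counts, "transition_counts"))
  if (length(counts$dt) == 0L) return(0)
  prop <- .q_propagator(Q)
  # accumulate per-cell contributions and sum once (long-double accumulator)
  terms <- vector("list", length(counts$dt))
  for (k in seq_along(counts$dt)) {
    P <- prop(counts$dt[k])
    N <- counts$counts[, , k]
    pos <- N > 0L
    if (!any(pos)) next
    p <- P[pos]
    if (any(p <= 0)) return(-Inf)
    terms[[k]] <- N[pos] * log(p)
  }
  sum(unlist(terms))
}
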