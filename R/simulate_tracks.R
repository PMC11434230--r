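#' Configuration for the worm-track simulator
#'
#' Bundles the generative parameters for simulated multi-worm-tracker output:
#' an underlying rate matrix, the number of tracks per plate, how long tracks
#' last, the acquisition frame rate and the burn-in interval at the start of a
#' movie that yields no usable observations.
#'
#' @param Q_true True 3x3 transition-rate matrix (per second).
#' @param n_tracks Number of tracks per plate.
#' @param mean_track_duration Mean track duration in seconds.
#' @param frame_rate Acquisition frame rate in Hz.
#' @param burn_in_discard Seconds at the start of each movie whose frames are
#'   discarded (plate handling perturbs the worms).
#' @param movie_duration Total movie length in seconds.
#' @param gap_probability Probability that any individual frame of a track is
#'   dropped, producing irregular observation intervals.
#' @param duration_distribution `"exponential"` (default) or `"fixed"` track
#'   durations.
#' @param seed Integer seed; all randomness in [simulate_tracks()] flows from
#'   it.
#' @return An object of class `track_sim_config`.
#' @export
track_sim_config <- function(Q_true,
                             n_tracks = 1000L,
                             mean_track_duration = 60,
                             frame_rate = 4,
                             burn_in_discard = 300,
                             movie_duration = 1200,
                             gap_probability = 0,
                             duration_distribution = c("exponential", "fixed"),
                             seed = 1L) {
  validate_rate_matrix(Q_true)
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (mean_track_duration <= 0) stop("mean_track_duration must be > 0")
  if (gap_probability < 0 || gap_probability >= 1) {
    stop("gap_probability must lie in [0, 1)")
  }
  if (movie_duration <= burn_in_discard) {
    stop("movie_duration must exceed burn_in_discard")
  }
  structure(list(
    Q_true = rate_matrix(Q_true),
    n_tracks = as.integer(n_tracks),
    mean_track_duration = mean_track_duration,
    frame_rate = frame_rate,
    burn_in_discard = burn_in_discard,
    movie_duration = movie_duration,
    gap_probability = gap_probability,
    duration_distribution = match.arg(duration_distribution),
    seed = as.integer(seed)
  ), class = "track_sim_config")
}

# One exact CTMC sample path: exponential holding times with rate q_i and
# jump probabilities q_ij / q_i. Returns step function (times, states).
.simulate_ctmc_path <- function(Q, t_max, init_state) {
  times <- 0
  states <- init_state
  t <- 0
  s <- init_state
  repeat {
    q_i <- -Q[s, s]
    if (q_i <= 0) break                       # absorbing state
    t <- t + stats::rexp(1L, q_i)
    if (t >= t_max) break
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(3L, 1L, prob = p)
    times <- c(times, t)
    states <- c(states, s)
  }
  list(times = times, states = states)
}

# state of a path at arbitrary query times
.path_state_at <- function(path, at) {
  path$states[findInterval(at, path$times)]
}

#' Simulate worm tracks from a continuous-time Markov chain
#'
#' Generates exact CTMC sample paths (exponential holding times, jump
#' probabilities `q_ij / q_i`), places each track at a uniform start time
#' within the movie, observes its state on the absolute frame grid of the
#' movie, drops frames that fall in the burn-in interval and drops further
#' frames independently with probability `gap_probability`. Initial states are
#' drawn from the stationary distribution of `Q_true` (uniform over states
#' when `Q_true` has an absorbing state or is the zero generator).
#'
#' @param config A [track_sim_config()].
#' @param n_plates Number of plates (technical replicates) to simulate.
#' @return A `data.frame` with columns `track_id`, `plate_id`, `time_s`,
#'   `state` (one of `"S"`, `"F"`, `"B"`), ordered by plate, track, time.
#' @export
simulate_tracks <- function(config, n_plates = 1L) {
  stopifnot(inherits(config, "track_sim_config"))
  Q <- config$Q_true
  set.seed(config$seed)
  f0 <- tryCatch(suppressWarnings(stationary_distribution(Q)),
                 error = function(e) rep(1 / 3, 3))
  frame_dt <- 1 / config$frame_rate
  out <- vector("list", n_plates)
  for (pl in seq_len(n_plates)) {
    plate_rows <- vector("list", config$n_tracks)
    for (tr in seq_len(config$n_tracks)) {
      dur <- switch(config$duration_distribution,
        exponential = stats::rexp(1L, 1 / config$mean_track_duration),
        fixed = config$mean_track_duration
      )
      dur <- min(dur, config$movie_duration)
      start <- stats::runif(1L, 0, config$movie_duration - dur)
      init <- sample.int(3L, 1L, prob = f0)
      path <- .simulate_ctmc_path(Q, dur, init)
      frames <- seq(ceiling(start / frame_dt), floor((start + dur) / frame_dt))
      frame_t <- frames * frame_dt
      frame_t <- frame_t[frame_t >= config$burn_in_discard]
      if (config$gap_probability > 0 && length(frame_t)) {
        frame_t <- frame_t[stats::runif(length(frame_t)) >= config$gap_probability]
      }
      if (!length(frame_t)) next
      st <- .path_state_at(path, frame_t - start)
      plate_rows[[tr]] <- data.frame(
        track_id = sprintf("p%03d_t%05d", pl, tr),
        plate_id = sprintf("p%03d", pl),
        time_s = frame_t,
        state = worm_states[st],
        stringsAsFactors = FALSE
      )
    }
    out[[pl]] <- do.call(rbind, plate_rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(track_id = character(), plate_id = character(),
                      time_s = numeric(), state = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write / read worm tracks as TSV
#'
#' The on-disk format mirrors post-processed tracker output: one observation
#' per row with columns `track_id`, `plate_id`, `time_s`, `state`.
#'
#' @param tracks Track `data.frame` as produced by [simulate_tracks()].
#' @param path File path.
#' @return `read_tracks` returns the validated `data.frame`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(tracks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("track_id", "plate_id", "time_s", "state")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("track file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!x$state %in% worm_states)
  if (length(bad)) {
    stop(sprintf("unknown state symbol %s at row %d (states must be S, F or B)",
                 dQuote(x$state[bad[1]]), bad[1]))
  }
  if (any(!is.finite(x$time_s))) stop("non-numeric or non-finite time_s values")
  x
}
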