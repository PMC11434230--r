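test_that("MAP estimation recovers planted rates", {
  cfg <- track_sim_config(example_Q, n_tracks = 400,
                          duration_distribution = "fixed", seed = 101)
  cc <- compress_tracks(simulate_tracks(cfg))
  fit <- fit_transition_rates(cc, seed = 1)
  # moderate data size: allow for prior shrinkage on the rarer transitions
  expect_true(all(abs(fit$map / example_theta - 1) < 0.10))
  expect_s3_class(fit, "rate_posterior")
  expect_true(all(fit$summary$q2.5 < fit$summary$q97.5))
  expect_true(all(fit$summary$q8.5 < fit$summary$q91.5))
})

test_that("repeated fits with a fixed seed are identical", {
  cfg <- track_sim_config(example_Q, n_tracks = 30, seed = 5)
  cc <- compress_tracks(simulate_tracks(cfg))
  f1 <- fit_transition_rates(cc, seed = 4)
  f2 <- fit_transition_rates(cc, seed = 4)
  expect_identical(f1$summary, f2$summary)
})

test_that("rates out of an unvisited state are prior-dominated and flagged", {
  # B is never entered, so q_BS and q_BF carry no information
  Q <- rate_matrix(c(1, 0, 0.8, 0, 0.5, 0.5))
  cfg <- track_sim_config(Q, n_tracks = 150, seed = 7)
  tr <- simulate_tracks(cfg)
  expect_false(any(tr$state == "B"))
  expect_warning(
    fit <- fit_transition_rates(compress_tracks(tr), seed = 2),
    "never observed"
  )
  expect_true(all(fit$diagnostics$prior_dominated[c("BS", "BF")]))
  # exit rates from the unseen state are far less certain than observed ones
  post_sd <- apply(fit$log_samples, 2, sd)
  expect_gt(min(post_sd[c("BS", "BF")]), 4 * max(post_sd[c("SF", "FS")]))
  # the well-observed rates are still recovered
  expect_lt(abs(fit$map[["SF"]] - 1), 0.15)
  expect_lt(abs(fit$map[["FS"]] - 0.8), 0.15)
})

test_that("credible intervals contract as data grow", {
  widths <- sapply(c(40, 160, 640), function(n) {
    cfg <- track_sim_config(example_Q, n_tracks = n,
                            duration_distribution = "fixed",
                            mean_track_duration = 30, seed = 900 + n)
    fit <- fit_transition_rates(compress_tracks(simulate_tracks(cfg)), seed = 1)
    mean(log(fit$summary$q97.5) - log(fit$summary$q2.5))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("Metropolis sampling agrees with the Laplace approximation", {
  cfg <- track_sim_config(example_Q, n_tracks = 150, seed = 13)
  cc <- compress_tracks(simulate_tracks(cfg))
  fl <- fit_transition_rates(cc, seed = 1)
  fm <- suppressWarnings(
    fit_transition_rates(cc, method = "mcmc", seed = 1,
                         mcmc_control = list(n_iter = 4000, burn_in = 800,
                                             thin = 4))
  )
  expect_identical(fl$map, fm$map)
  expect_true(all(abs(fm$summary$mean / fl$summary$mean - 1) < 0.1))
  expect_gt(fm$diagnostics$acceptance_rate, 0.05)
})

test_that("state-frequency diagnostic sits on the identity for Markov data", {
  cfg <- track_sim_config(example_Q, n_tracks = 150, seed = 17)
  tr <- simulate_tracks(cfg, n_plates = 3)
  fit <- fit_transition_rates(compress_tracks(tr), seed = 1)
  d <- predicted_state_frequencies(fit, tr)
  expect_equal(attr(d, "slope"), 1, tolerance = 0.05)
  expect_gt(attr(d, "rank_correlation"), 0.9)
  # single-state tracks: observed frequency 1 for that state
  solo <- data.frame(track_id = "t", plate_id = "p",
                     time_s = c(0, 0.25, 0.5), state = "F")
  ds <- predicted_state_frequencies(example_Q, solo)
  expect_equal(ds$observed[ds$state == "F"], 1)
})

test_that("non-exponential dwell times are detected as lack of fit", {
  # semi-Markov data: gamma-distributed (shape 8) dwells in S, exponential
  # elsewhere; time-in-state deviates from the fitted Markov stationary f
  set.seed(23)
  mk_track <- function(id) {
    t <- 0; s <- 1L; times <- numeric(); states <- integer()
    while (t < 120) {
      dwell <- if (s == 1L) rgamma(1, shape = 8, rate = 8 * 1.5) else rexp(1, 1.5)
      times <- c(times, t); states <- c(states, s)
      t <- t + dwell
      s <- sample((1:3)[-s], 1L)
    }
    grid <- seq(0, 120, by = 0.25)
    data.frame(track_id = id, plate_id = paste0("sp", (match(id, ids) - 1) %/% 20),
               time_s = grid,
               state = worm_states[states[findInterval(grid, times)]])
  }
  ids <- sprintf("g%03d", 1:60)
  tr <- do.call(rbind, lapply(ids, mk_track))
  fit <- fit_transition_rates(compress_tracks(tr), seed = 1)
  d <- predicted_state_frequencies(fit, tr)
  expect_gt(max(abs(d$observed - d$expected)), 0.02)
})
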