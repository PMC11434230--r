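#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of the end-to-end synthetic
#' analysis: seeds, problem sizes, sampler settings, effective population
#' size for the drift expectation. Configurations round-trip through YAML.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_tracks,n_plates Track-simulation sizes for the rate-estimation
#'   stage.
#' @param n_lines_ancestral,n_lines_derived Panel sizes.
#' @param blocks_per_line Technical replicates per line.
#' @param n_generations Focal generations between ancestral and derived
#'   panels.
#' @param Ne Effective population size for drift.
#' @param gibbs List of Gibbs sampler settings (`n_iter`, `burn_in`,
#'   `thin`).
#' @param n_perm Permutations for the null distributions.
#' @param populations Names of the derived populations.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed = 1L,
                            n_tracks = 150L, n_plates = 2L,
                            n_lines_ancestral = 100L,
                            n_lines_derived = 50L,
                            blocks_per_line = 3L,
                            n_generations = 100L,
                            Ne = 1000L,
                            gibbs = list(n_iter = 3000L, burn_in = 500L,
                                         thin = 5L),
                            n_perm = 100L,
                            populations = c("CA1", "CA2", "CA3")) {
  cfg <- list(seed = as.integer(seed), n_tracks = as.integer(n_tracks),
              n_plates = as.integer(n_plates),
              n_lines_ancestral = as.integer(n_lines_ancestral),
              n_lines_derived = as.integer(n_lines_derived),
              blocks_per_line = as.integer(blocks_per_line),
              n_generations = as.integer(n_generations),
              Ne = as.integer(Ne),
              gibbs = lapply(gibbs, as.integer),
              n_perm = as.integer(n_perm),
              populations = populations)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an inbred-line phenotype table
#'
#' @param path CSV with columns `line_id`, `population`, `block_id`,
#'   `temperature`, `humidity`, `density` and the six trait columns.
#' @return Validated `data.frame`.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("line_id", "block_id", "temperature", "humidity", "density",
           trait_names)
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("phenotype file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (tc in trait_names) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x[[tc]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric trait value in column %s at row %d", tc, bad[1]))
    }
  }
  x
}

#' Read a line-fitness table
#'
#' @param path CSV with columns `line_id`, `fitness`.
#' @return Validated `data.frame`.
#' @export
read_fitness <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "fitness") %in% names(x))) {
    stop("fitness file must have columns line_id, fitness")
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(x$fitness))))
  if (length(bad)) stop("non-numeric fitness at row ", bad[1])
  x
}

.write_csv <- function(x, path) {
  utils::write.csv(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the method end to end on simulated data with known ground truth:
#' (1) simulate worm tracks from a planted rate matrix and re-estimate the
#' transition rates; (2) simulate an ancestral inbred-line panel from a
#' planted G and derived panels whose G-matrices have drifted for
#' `n_generations`; (3) estimate all G-matrices with the Gibbs sampler;
#' (4) compare them (trace, gmax, angles to the ancestral gmax, eigentensor
#' decomposition with its finite-sampling null); (5) simulate line fitness
#' from a planted quadratic surface, estimate gamma, canonical axes and the
#' permutation null of the rotated eigenvalues; (6) compare projected
#' genetic variances against the drift expectation. All stage outputs are
#' written as CSV together with a JSON manifest of seeds, configuration and
#' file checksums. Identical configurations yield byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_full_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sd0 <- config$seed

  ## ground truth -----------------------------------------------------------
  theta_true <- c(SF = 0.9, SB = 0.25, FS = 0.6, FB = 0.15,
                  BS = 0.45, BF = 1.1)
  Q_true <- rate_matrix(theta_true)
  # ancestral G with a dominant axis (elliptical, as in lab-adapted panels)
  v1 <- c(1, 1, -1, -1, -1, -1) / sqrt(6)
  G_true <- 0.35 * tcrossprod(v1) + diag(0.05, 6)
  dimnames(G_true) <- list(trait_names, trait_names)
  gamma_true <- diag(c(0.1, 0.05, 0.02, -0.02, -0.06, -0.3))
  dimnames(gamma_true) <- list(trait_names, trait_names)

  ## stage 1: tracks and rate estimation ------------------------------------
  tcfg <- track_sim_config(Q_true, n_tracks = config$n_tracks,
                           seed = sd0 + 11L)
  tracks <- simulate_tracks(tcfg, n_plates = config$n_plates)
  counts <- compress_tracks(tracks)
  rate_fit <- fit_transition_rates(counts, seed = sd0 + 12L)
  .write_csv(rate_fit$summary, file.path(out_dir, "transition_rates.csv"))

  ## stage 2: panels --------------------------------------------------------
  panels <- list()
  pcfg_anc <- panel_sim_config(G_true, n_lines = config$n_lines_ancestral,
                               blocks_per_line = config$blocks_per_line,
                               population = "A0", seed = sd0 + 21L)
  panels[["A0"]] <- simulate_line_phenotypes(pcfg_anc)
  G_drifted <- list()
  for (i in seq_along(config$populations)) {
    pop <- config$populations[i]
    traj <- simulate_drift_panel(G_true, config$Ne, config$n_generations,
                                 seed = sd0 + 30L + i)
    G_pop <- .nearest_psd(traj[, , dim(traj)[3]])
    G_drifted[[pop]] <- G_pop
    pcfg <- panel_sim_config(G_pop, n_lines = config$n_lines_derived,
                             blocks_per_line = config$blocks_per_line,
                             population = pop, seed = sd0 + 40L + i)
    panels[[pop]] <- simulate_line_phenotypes(pcfg)
  }
  for (pop in names(panels)) {
    .write_csv(panels[[pop]], file.path(out_dir, paste0("phenotypes_", pop, ".csv")))
  }

  ## stage 3: G-matrix estimation -------------------------------------------
  g_fits <- lapply(names(panels), function(pop) {
    fit_line_model(panels[[pop]],
                   n_iter = config$gibbs$n_iter,
                   burn_in = config$gibbs$burn_in,
                   thin = config$gibbs$thin,
                   seed = sd0 + 50L + match(pop, names(panels)))
  })
  names(g_fits) <- names(panels)
  g_summ <- do.call(rbind, lapply(names(g_fits), function(pop) {
    cbind(population = pop, g_fits[[pop]]$summary)
  }))
  .write_csv(g_summ, file.path(out_dir, "gmatrix_summaries.csv"))

  ## stage 4: comparison ----------------------------------------------------
  es_anc <- eigen_decompose(g_fits[["A0"]]$G_mean)
  gmax <- es_anc$vectors[, 1]
  angles <- do.call(rbind, lapply(config$populations, function(pop) {
    a <- angle_posterior(gmax, g_fits[[pop]], k = 1L)
    data.frame(population = pop, mean = a$mean, q2.5 = a$q2.5,
               q8.5 = a$q8.5, q91.5 = a$q91.5, q97.5 = a$q97.5)
  }))
  null_ang <- null_angle_distribution(6, 1000, seed = sd0 + 61L)
  angles$null_q5 <- attr(null_ang, "quantiles")[["5%"]]
  .write_csv(angles, file.path(out_dir, "gmax_angles.csv"))
  traces <- data.frame(
    population = names(g_fits),
    trace_mean = vapply(g_fits, function(f) mean(matrix_trace(f$G_draws)), 1),
    gmax_variance = vapply(g_fits, function(f)
      mean(project_variance(f$G_draws, gmax)), 1)
  )
  .write_csv(traces, file.path(out_dir, "gmatrix_traces.csv"))
  tensor <- build_covariance_tensor(g_fits, n_draws = 200L)
  et <- eigentensor_decompose(tensor)
  a_null <- tensor_sampling_null(g_fits,
                                 n_lines_per_pop = c(config$n_lines_ancestral,
                                                     rep(config$n_lines_derived,
                                                         length(config$populations))),
                                 n_rep = config$n_perm, seed = sd0 + 62L)
  tensor_tab <- data.frame(
    eigentensor = paste0("E", 1:4),
    alpha = et$alpha[1:4],
    alpha_fraction = (et$alpha / sum(et$alpha))[1:4],
    null_q95 = attr(a_null, "q95")[1:4]
  )
  .write_csv(tensor_tab, file.path(out_dir, "eigentensor.csv"))

  ## stage 5: selection -----------------------------------------------------
  line_means <- attr(panels[["A0"]], "line_effects")
  colnames(line_means) <- trait_names
  rownames(line_means) <- sprintf("L%04d", seq_len(nrow(line_means)))
  fcfg <- fitness_sim_config(gamma_true, alpha = 1, noise_sd = 0.1,
                             seed = sd0 + 71L)
  fitness <- simulate_fitness(line_means, fcfg)
  .write_csv(fitness, file.path(out_dir, "fitness_A0.csv"))
  gfit <- fit_gamma(line_means, fitness, seed = sd0 + 72L)
  can <- canonical_analysis(gfit)
  lam_null <- null_lambda_distribution(line_means, fitness, can$U,
                                       n_perm = config$n_perm,
                                       seed = sd0 + 73L)
  can_tab <- data.frame(
    axis = paste0("y", 1:6), lambda = can$lambda,
    lambda_mode = can$lambda_mode,
    classification = can$classification,
    null_q2.5 = attr(lam_null, "quantiles")["2.5%", ],
    null_q97.5 = attr(lam_null, "quantiles")["97.5%", ]
  )
  .write_csv(can_tab, file.path(out_dir, "canonical_selection.csv"))
  e11 <- et$tensor_eigen[[1]]$vectors[, 1]
  align <- alignment_correlations(list(e11 = e11), gfit, n_draws = 200L)
  .write_csv(align, file.path(out_dir, "alignment.csv"))

  ## stage 6: drift ---------------------------------------------------------
  by_gen <- c(list(`0` = g_fits[["A0"]]),
              stats::setNames(g_fits[config$populations],
                              rep(config$n_generations,
                                  length(config$populations))))
  drift_tab <- drift_envelope_compare(by_gen, can$U, config$Ne)
  .write_csv(drift_tab, file.path(out_dir, "drift_envelope.csv"))

  ## manifest ----------------------------------------------------------------
  files <- sort(list.files(out_dir, pattern = "\\.csv$"))
  manifest <- list(
    package = "wormqg",
    config = unclass(config),
    stage_seeds = list(tracks = sd0 + 11L, rates = sd0 + 12L,
                       panels = sd0 + 21L, gibbs = sd0 + 50L,
                       nulls = sd0 + 62L, fitness = sd0 + 71L),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(rate_fit = rate_fit, g_fits = g_fits, tensor = et,
                 canonical = can, drift = drift_tab, manifest = manifest))
}
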