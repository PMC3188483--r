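#' Experiment configuration
#'
#' A validated description of one experiment on one model tier, covering the
#' sweep axes (input widths, afferent counts, two-tone separations, variant
#' flags), replication and seeding. Physical units: `sigma`, `delta_x` in um;
#' `fs_vt` in mV; `noise_sd` in mV of membrane fluctuation; `background_rate`
#' in Hz.
#'
#' @param tier `"spiking"`, `"feedforward"` or `"rate"`.
#' @param sigma input widths (um) — thalamic envelope sd (spiking/rate) or
#'   normalized width grid (feedforward).
#' @param n_max peak afferent counts (spiking/rate) or normalized peak
#'   currents (feedforward).
#' @param n_sweeps sweeps per condition (spiking tier).
#' @param seed master seed; per-condition seeds derive deterministically.
#' @param scale spiking-sheet grid scaling in (0, 1].
#' @param delta_x two-tone separations (um); empty for single-stimulus runs.
#' @param fs_vt FS spike-threshold values (mV) to sweep; empty keeps the
#'   control value.
#' @param noise_sd target membrane-fluctuation sd (mV); 0 disables noise.
#' @param background_rate background firing rate (Hz) for steady-state
#'   synaptic depression; 0 disables.
#' @param theta,r_ei feedforward threshold and unequal-tuning factor.
#' @param kernel_family rate-model connectivity kernel families to sweep.
#' @param f_max peak afferent rate (Hz, spiking tier).
#' @param duration stimulus duration (ms).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(tier = c("spiking", "feedforward", "rate"),
                              sigma, n_max, n_sweeps = 50, seed = 1,
                              scale = 1, delta_x = numeric(0),
                              fs_vt = numeric(0), noise_sd = 0,
                              background_rate = 0, theta = 1, r_ei = 1,
                              kernel_family = "gaussian",
                              f_max = 50, duration = 100) {
  tier <- match.arg(tier)
  cfg <- list(tier = tier, sigma = as.numeric(sigma),
              n_max = as.numeric(n_max), n_sweeps = as.integer(n_sweeps),
              seed = as.integer(seed), scale = as.numeric(scale),
              delta_x = as.numeric(delta_x), fs_vt = as.numeric(fs_vt),
              noise_sd = as.numeric(noise_sd),
              background_rate = as.numeric(background_rate),
              theta = as.numeric(theta), r_ei = as.numeric(r_ei),
              kernel_family = kernel_family,
              f_max = as.numeric(f_max), duration = as.numeric(duration))
  problems <- character(0)
  if (length(cfg$sigma) == 0) problems <- c(problems, "sigma: empty sweep axis")
  if (length(cfg$n_max) == 0) problems <- c(problems, "n_max: empty sweep axis")
  if (cfg$n_sweeps < 1) problems <- c(problems, "n_sweeps: must be >= 1")
  if (cfg$scale <= 0 || cfg$scale > 1)
    problems <- c(problems, "scale: must be in (0, 1]")
  if (any(cfg$sigma <= 0)) problems <- c(problems, "sigma: must be > 0")
  if (any(cfg$n_max < 0)) problems <- c(problems, "n_max: must be >= 0")
  if (length(problems))
    stop("invalid experiment config:\n  ", paste(problems, collapse = "\n  "))
  structure(cfg, class = "experiment_config")
}

#' Serialize / parse an experiment configuration
#'
#' Human-readable YAML round-trip: `config_read(config_write(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `config_write` returns `path` invisibly; `config_read` returns the
#'   parsed `experiment_config`.
#' @export
config_write <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' Named experiment presets
#'
#' Ready-made configurations for the package's standard experiments: the
#' width-ratio transition, gain and two-tone analyses on the spiking sheet,
#' the feedforward and rate-model surfaces, the intensity trajectories, and
#' the robustness variants (background noise, steady-state depression, FS
#' excitability, threshold-free feedforward transform, unequal E/I input
#' tuning, non-Gaussian kernels).
#'
#' @param name preset name; call with no argument to list the presets.
#' @return an [experiment_config()].
#' @export
preset_config <- function(name) {
  presets <- list(
    fig3_transition = function() experiment_config(
      "spiking", sigma = c(40, 55, 70, 90, 110), n_max = c(60, 100)),
    fig4_gain = function() experiment_config(
      "spiking", sigma = c(40, 75, 110), n_max = seq(10, 100, by = 10)),
    fig4_twotone = function() experiment_config(
      "spiking", sigma = c(40, 110), n_max = 60,
      delta_x = seq(0, 300, by = 50)),
    fig5_surface = function() experiment_config(
      "feedforward", sigma = seq(0.25, 4, by = 0.25),
      n_max = seq(1.2, 6, by = 0.4), theta = 1),
    fig6_surfaces = function() experiment_config(
      "rate", sigma = seq(20, 160, by = 20), n_max = seq(4, 40, by = 4)),
    fig7_trajectories = function() experiment_config(
      "rate", sigma = seq(5, 160, by = 10), n_max = seq(0, 1000, by = 50)),
    s1_noise = function() experiment_config(
      "spiking", sigma = c(40, 110), n_max = 100, noise_sd = 8),
    s2_background = function() experiment_config(
      "spiking", sigma = c(40, 110), n_max = 60, background_rate = 5),
    s3_fs_threshold = function() experiment_config(
      "spiking", sigma = c(40, 110), n_max = 100,
      fs_vt = c(-52, -47, -37)),
    s4_no_threshold = function() experiment_config(
      "feedforward", sigma = c(0.25, 0.5, 1, 2, 4, 8, 16, 50), n_max = 2,
      theta = 0),
    s5_unequal = function() experiment_config(
      "feedforward", sigma = seq(0.25, 4, by = 0.25),
      n_max = seq(1.2, 6, by = 0.4), theta = 1, r_ei = 1.3),
    s6_kernels = function() experiment_config(
      "rate", sigma = seq(20, 160, by = 20), n_max = 20,
      kernel_family = c("gaussian", "box", "quadratic", "binomial")))
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]()
}

#' Run a configured experiment
#'
#' Executes every condition of a configuration on its tier, writes tidy
#' summary tables and a manifest (config hash, per-condition seeds, runtime)
#' to `out_dir`, and returns the summaries. Re-running with the same
#' configuration reproduces the tables exactly.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param n_sweeps,scale optional scaled-down overrides of the config.
#' @return list with `summary` (tibble) and `manifest` (list), invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL, n_sweeps = NULL,
                           scale = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(n_sweeps)) config$n_sweeps <- as.integer(n_sweeps)
  if (!is.null(scale)) config$scale <- as.numeric(scale)
  t0 <- Sys.time()
  res <- switch(config$tier,
    spiking = run_spiking_tier(config),
    feedforward = run_feedforward_tier(config),
    rate = run_rate_tier(config))
  manifest <- list(
    tier = config$tier,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("cotuner")),
    master_seed = config$seed,
    conditions = res$conditions,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    config_write(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(summary = res$summary, manifest = manifest))
}

run_spiking_tier <- function(cfg) {
  fs_vt <- if (length(cfg$fs_vt)) cfg$fs_vt else neuron_params("FS")$VT
  dx_axis <- if (length(cfg$delta_x)) cfg$delta_x else NA_real_
  grid <- tidyr::expand_grid(sigma = cfg$sigma, n_max = cfg$n_max,
                             fs_vt = fs_vt, delta_x = dx_axis)
  net <- build_network(scale = cfg$scale, seed = cfg$seed)
  noise <- c(p = 0, fs = 0)
  if (cfg$noise_sd > 0) {
    noise <- c(p = calibrate_noise(cfg$noise_sd, neuron_params("P"),
                                   seed = cfg$seed),
               fs = calibrate_noise(cfg$noise_sd, neuron_params("FS"),
                                    seed = cfg$seed))
  }
  conds <- list()
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    drv <- thalamic_drive(n_max = g$n_max, sigma = g$sigma,
                          f_max = cfg$f_max, duration = cfg$duration)
    if (!is.na(g$delta_x)) drv <- two_tone_drive(drv, g$delta_x)
    cond_seed <- child_seed(cfg$seed, i)
    conds[[i]] <<- list(condition = i, seed = cond_seed,
                        n_sweeps = cfg$n_sweeps)
    rec <- simulate_network(net, drv, n_sweeps = cfg$n_sweeps,
                            seed = cond_seed,
                            nrn_fs = neuron_params("FS", VT = g$fs_vt),
                            noise = noise,
                            background_rate = cfg$background_rate,
                            rec_tmax = min(cfg$duration, 60))
    wr <- tryCatch(ei_width_ratio(rec),
                   error = function(e) tibble(w_exc = NA_real_,
                                              w_inh = NA_real_,
                                              ratio = NA_real_))
    cw <- count_window(rec)
    center <- cw$count[nearest_cell(rec$p_coords, rec$center)]
    fs_count <- sum(rec$spikes$pop == "FS" & rec$spikes$t <= 50) / cfg$n_sweeps
    tibble(sigma = g$sigma, n_max = g$n_max, fs_vt = g$fs_vt,
           delta_x = g$delta_x, center_count = center,
           fs_count = fs_count, w_exc = wr$w_exc, w_inh = wr$w_inh,
           ratio = wr$ratio, runaway = rec$runaway)
  })
  list(summary = rows, conditions = conds)
}

run_feedforward_tier <- function(cfg) {
  surf <- ff_surface(i_max_norm = cfg$n_max, sigma_norm = cfg$sigma,
                     theta = cfg$theta, r_ei = cfg$r_ei)
  list(summary = surf,
       conditions = list(list(condition = 1, seed = cfg$seed)))
}

run_rate_tier <- function(cfg) {
  rows <- purrr::map_dfr(cfg$kernel_family, function(fam) {
    p <- rate_params(kernel_family = fam)
    s <- rate_surfaces(p, n_max = cfg$n_max, sigma = cfg$sigma)
    s$kernel_family <- fam
    s
  })
  list(summary = rows,
       conditions = list(list(condition = 1, seed = cfg$seed)))
}
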