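# group realized afferent trains into CSR offsets and apply TM efficacies;
# returns time-sorted delivery arrays for one target population
thal_deliveries <- function(trains, syn) {
  if (nrow(trains) == 0) {
    return(list(t = numeric(0), cell = integer(0), w = numeric(0)))
  }
  key <- cumsum(!duplicated(trains[c("cell", "train")]))
  off <- c(0L, which(diff(key) != 0), nrow(trains))
  eff <- tm_efficacies_cpp(trains$t, as.integer(off), syn$U, syn$tau_rec,
                           syn$tau_facil)
  t_arr <- trains$t + syn$delay
  o <- order(t_arr)
  list(t = t_arr[o], cell = as.integer(trains$cell[o] - 1L),
       w = (eff * syn$A * syn$scale)[o])
}

#' Simulate the full spiking sheet under a thalamic drive
#'
#' Runs clock-driven (forward Euler) integration of the aEIF sheet with
#' event-driven alpha-conductance synapses and per-connection short-term
#' plasticity. Each sweep draws a fresh realization of the thalamic afferent
#' trains; pathway-resolved conductance traces onto every P cell (thalamic,
#' recurrent excitatory, FS inhibitory) are averaged over sweeps.
#'
#' @param net a [build_network()] result.
#' @param drive a [thalamic_drive()] (possibly two-tone).
#' @param n_sweeps number of stimulus repetitions.
#' @param seed optional master seed; per-sweep seeds are derived from it, so
#'   identical `(net, drive, seed)` reproduce the record exactly.
#' @param dt integration step (ms), <= 0.1.
#' @param nrn_p,nrn_fs neuron parameters ([neuron_params()]); `nrn_fs$VT` can
#'   be overridden to emulate mutual FS inhibition (-52 / -47 / -37 mV).
#' @param syn named list of [synapse_params()] overrides (`thal_p`,
#'   `thal_fs`, `pp`, `pfs`, `fsp`).
#' @param noise named numeric `c(p = , fs = )`: white-noise current
#'   amplitudes (pA sqrt(ms), see [calibrate_noise()]).
#' @param background_rate background firing rate (Hz) whose steady-state
#'   synaptic depression prescales every unitary amplitude
#'   ([steady_state_depression()]); 0 disables.
#' @param rec_dt conductance recording resolution (ms).
#' @param rec_tmax end of the conductance recording window (ms); defaults to
#'   the drive duration.
#' @param rate_ceiling population-rate ceiling (Hz per cell) above which the
#'   record is flagged as runaway.
#' @param density_compensation scale intracortical unitary amplitudes by the
#'   cell-density ratio of a coarsened grid (`scale < 1`) so that the total
#'   synaptic input per cell — and hence the network regime — is preserved.
#'   Has no effect at full scale.
#' @return an object of class `sim_record`: `spikes` (tibble: `sweep`, `pop`,
#'   `cell`, `x`, `y`, `t`), `cond` (list: `times` plus sweep-averaged nP x T
#'   matrices `thal`, `rec`, `inh`), coordinates, the drive and run metadata.
#' @export
simulate_network <- function(net, drive, n_sweeps = 1, seed = NULL, dt = 0.05,
                             nrn_p = neuron_params("P"),
                             nrn_fs = neuron_params("FS"),
                             syn = list(),
                             noise = c(p = 0, fs = 0),
                             background_rate = 0,
                             rec_dt = 0.5, rec_tmax = NULL,
                             rate_ceiling = 400,
                             density_compensation = TRUE) {
  stopifnot(inherits(net, "cortical_net"), inherits(drive, "thalamic_drive"),
            dt > 0, dt <= 0.1, n_sweeps >= 1)
  syn_all <- list(thal_p = synapse_params("thal_p"),
                  thal_fs = synapse_params("thal_fs"),
                  pp = synapse_params("pp"), pfs = synapse_params("pfs"),
                  fsp = synapse_params("fsp"))
  for (nm in names(syn)) {
    if (!nm %in% names(syn_all)) stop("unknown pathway override: ", nm)
    syn_all[[nm]] <- syn[[nm]]
  }
  if (density_compensation) {
    comp_p <- (160 / net$n_p_side)^2
    comp_fs <- (32 / net$n_fs_side)^2
    syn_all$pp$scale <- syn_all$pp$scale * comp_p
    syn_all$pfs$scale <- syn_all$pfs$scale * comp_p
    syn_all$fsp$scale <- syn_all$fsp$scale * comp_fs
  }
  if (background_rate > 0) {
    for (nm in names(syn_all)) {
      syn_all[[nm]]$scale <- syn_all[[nm]]$scale *
        steady_state_depression(background_rate, syn_all[[nm]])
    }
  }
  duration <- drive$duration + 5  # let late deliveries play out
  if (is.null(rec_tmax)) rec_tmax <- duration
  nP <- nrow(net$p_coords)
  nFS <- nrow(net$fs_coords)
  n_rec <- min(floor(duration / rec_dt), floor(rec_tmax / rec_dt) + 1)
  rec_every <- max(1L, as.integer(round(rec_dt / dt)))
  acc_thal <- matrix(0, nP, n_rec)
  acc_rec <- matrix(0, nP, n_rec)
  acc_inh <- matrix(0, nP, n_rec)
  spikes <- vector("list", n_sweeps)
  runaway <- FALSE
  for (k in seq_len(n_sweeps)) {
    sk <- child_seed(seed, k)
    res <- with_seed(sk, {
      trains_p <- realize_drive(drive, net$p_coords)
      trains_f <- realize_drive(drive, net$fs_coords)
      dp <- thal_deliveries(trains_p, syn_all$thal_p)
      df <- thal_deliveries(trains_f, syn_all$thal_fs)
      run_sweep_cpp(nP, nFS, unclass(nrn_p), unclass(nrn_fs),
                    unclass(syn_all$pp), unclass(syn_all$pfs),
                    unclass(syn_all$fsp),
                    net$csr$pp$offsets, net$csr$pp$targets,
                    net$csr$pfs$offsets, net$csr$pfs$targets,
                    net$csr$fsp$offsets, net$csr$fsp$targets,
                    dp$t, dp$cell, dp$w, syn_all$thal_p$tau, syn_all$thal_p$Erev,
                    df$t, df$cell, df$w, syn_all$thal_fs$tau, syn_all$thal_fs$Erev,
                    dt, duration, noise[["p"]], noise[["fs"]],
                    rec_every, rec_tmax, acc_thal, acc_rec, acc_inh,
                    rate_ceiling)
    })
    runaway <- runaway || res$runaway
    spikes[[k]] <- dplyr::bind_rows(
      tibble(sweep = k, pop = "P", cell = res$p_cell, t = res$p_t),
      tibble(sweep = k, pop = "FS", cell = res$fs_cell, t = res$fs_t))
  }
  spikes <- dplyr::bind_rows(spikes)
  # attach coordinates
  if (nrow(spikes)) {
    isP <- spikes$pop == "P"
    spikes$x <- ifelse(isP, net$p_coords$x[spikes$cell],
                       net$fs_coords$x[spikes$cell])
    spikes$y <- ifelse(isP, net$p_coords$y[spikes$cell],
                       net$fs_coords$y[spikes$cell])
  } else {
    spikes$x <- numeric(0); spikes$y <- numeric(0)
  }
  structure(
    list(spikes = as_tibble(spikes),
         cond = list(times = (seq_len(n_rec) - 1) * rec_dt,
                     thal = acc_thal / n_sweeps, rec = acc_rec / n_sweeps,
                     inh = acc_inh / n_sweeps),
         p_coords = net$p_coords, fs_coords = net$fs_coords,
         center = drive$centers[1, ], drive = drive,
         n_sweeps = n_sweeps, dt = dt, runaway = runaway),
    class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record> ", x$n_sweeps, " sweep(s), ", nrow(x$spikes),
      " spikes (", sum(x$spikes$pop == "P"), " P / ",
      sum(x$spikes$pop == "FS"), " FS)",
      if (isTRUE(x$runaway)) " [RUNAWAY FLAGGED]", "\n", sep = "")
  invisible(x)
}

#' @rdname simulate_network
#' @param x a `sim_record`.
#' @param ... unused.
#' @export
tidy.sim_record <- function(x, ...) x$spikes

#' @rdname simulate_network
#' @export
glance.sim_record <- function(x, ...) {
  tibble(n_sweeps = x$n_sweeps,
         n_spikes_p = sum(x$spikes$pop == "P"),
         n_spikes_fs = sum(x$spikes$pop == "FS"),
         runaway = isTRUE(x$runaway))
}
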