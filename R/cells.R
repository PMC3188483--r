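#' One integration step of an aEIF neuron
#'
#' Forward-Euler update of the adaptive exponential integrate-and-fire state
#' (membrane potential `V`, adaptation current `w`, refractory clock `refr`)
#' under an injected current. The exponential spike-initiation term is
#' evaluated with `V` clamped at the numerical cutoff `Vcut`; on crossing the
#' cutoff, `V` resets, `w` increments by `b` and the refractory clock starts.
#'
#' @param state named numeric `c(V = , w = , refr = )` (mV, pA, ms).
#' @param params a [neuron_params()].
#' @param I injected current (pA).
#' @param dt time step (ms), in (0, 0.1].
#' @return named numeric `c(V, w, refr, spike)` where `spike` is 0/1.
#' @export
aeif_step <- function(state, params, I, dt = 0.05) {
  stopifnot(inherits(params, "neuron_params"), dt > 0, dt <= 0.1)
  if (any(!is.finite(state))) stop("non-finite neuron state")
  r <- aeif_step_cpp(unclass(params), state[["V"]], state[["w"]],
                     state[["refr"]], I, dt)
  c(V = r$V, w = r$w, refr = r$refr, spike = as.numeric(r$spike))
}

#' Single-cell response to an injected current
#'
#' @param params a [neuron_params()].
#' @param I injected current: a scalar (constant, pA) or a per-step vector.
#' @param duration simulated time (ms); required when `I` is scalar.
#' @param dt time step (ms).
#' @return list with `V` (membrane trace, mV, one sample per step), `spikes`
#'   (spike times, ms), `dt`.
#' @export
simulate_cell <- function(params, I, duration = NULL, dt = 0.05) {
  stopifnot(inherits(params, "neuron_params"))
  if (length(I) == 1) {
    stopifnot(!is.null(duration), duration > 0)
    I <- rep(I, round(duration / dt))
  }
  r <- simulate_cell_cpp(unclass(params), I, dt)
  list(V = r$V, spikes = r$spikes, dt = dt)
}

#' Firing rate versus injected current (F/I curve)
#'
#' @param params a [neuron_params()].
#' @param currents constant currents to scan (pA).
#' @param duration simulated time per current (ms).
#' @param dt time step (ms).
#' @return tibble with `I` (pA) and `rate` (Hz).
#' @export
fi_curve <- function(params, currents, duration = 500, dt = 0.05) {
  rate <- vapply(currents, function(I0) {
    length(simulate_cell(params, I0, duration, dt)$spikes) / duration * 1000
  }, numeric(1))
  tibble(I = currents, rate = rate)
}

#' Rheobase current of a cell
#'
#' Smallest constant current that elicits at least one spike, found by
#' bisection on a scan bracket.
#'
#' @param params a [neuron_params()].
#' @param bracket search interval (pA).
#' @param duration test duration (ms).
#' @param tol bisection tolerance (pA).
#' @return rheobase (pA).
#' @export
rheobase <- function(params, bracket = c(0, 2000), duration = 500, tol = 1) {
  fires <- function(I0) length(simulate_cell(params, I0, duration)$spikes) > 0
  lo <- bracket[1]; hi <- bracket[2]
  if (!fires(hi)) stop("upper bracket does not elicit firing")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Tsodyks-Markram per-spike synaptic efficacies
#'
#' Runs the short-term plasticity recursion over a presynaptic spike train:
#' resources recover with `tau_rec`, a fraction (utilization `U`, optionally
#' facilitating with `tau_facil`) is released per spike. The returned efficacy
#' of spike n is the released fraction, in (0, 1]; it multiplies the unitary
#' amplitude `A`. A first (fully recovered) spike has efficacy `U`.
#'
#' @param times spike times (ms), strictly increasing.
#' @param params a [synapse_params()].
#' @return numeric vector of efficacies, one per spike.
#' @export
tm_efficacy <- function(times, params) {
  stopifnot(inherits(params, "synapse_params"))
  if (length(times) == 0) return(numeric(0))
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  as.numeric(tm_efficacies_cpp(times, c(0L, length(times)),
                               params$U, params$tau_rec, params$tau_facil))
}

#' Steady-state depression scale at a background firing rate
#'
#' Closed-form fixed point of the Tsodyks-Markram recursion for a periodic
#' presynaptic train: the factor by which sustained background firing at
#' `rate` scales the effective unitary amplitude, relative to a fully
#' recovered synapse. Equals 1 at rate 0 and decays toward 0 for
#' depression-dominated parameters.
#'
#' @param rate background firing rate (Hz), >= 0.
#' @param params a [synapse_params()].
#' @return scale factor in (0, 1].
#' @export
steady_state_depression <- function(rate, params) {
  stopifnot(inherits(params, "synapse_params"), all(rate >= 0))
  vapply(rate, function(r) {
    if (r == 0) return(1)
    q <- exp(-1000 / (r * params$tau_rec))
    if (params$tau_facil > 0) {
      qf <- exp(-1000 / (r * params$tau_facil))
      u <- params$U / (1 - (1 - params$U) * qf)
      x <- (1 - q) / (1 - q * (1 - u))
      (u * x) / params$U
    } else {
      (1 - q) / (1 - q * (1 - params$U))
    }
  }, numeric(1))
}

#' Calibrate white-noise current to a target membrane fluctuation
#'
#' Finds the white-noise current amplitude that produces subthreshold
#' membrane-potential fluctuations of a given standard deviation in an
#' unstimulated cell, emulating in-vivo background synaptic barrages. The
#' injected current at each step is `amp * N(0,1) / sqrt(dt)` so the
#' fluctuation level is independent of the integration step. Secant iteration
#' on the measured sd (fluctuations are near-linear in the amplitude)
#' converges to within 5% of the target.
#'
#' @param target_sd target membrane sd (mV), >= 0.
#' @param params a [neuron_params()].
#' @param seed optional integer seed for the calibration noise.
#' @param duration measurement window per evaluation (ms).
#' @param dt time step (ms).
#' @return noise amplitude (pA sqrt(ms)), suitable for
#'   [simulate_network()]'s `noise` option.
#' @export
calibrate_noise <- function(target_sd, params, seed = NULL, duration = 10000,
                            dt = 0.05) {
  stopifnot(inherits(params, "neuron_params"), target_sd >= 0)
  if (target_sd == 0) return(0)
  measure <- function(amp, s) {
    I <- with_seed(s, rnorm(round(duration / dt))) * amp / sqrt(dt)
    r <- simulate_cell(params, I, dt = dt)
    skip <- round(200 / dt)  # discard the settling transient
    v <- r$V[-seq_len(skip)]
    sub <- v < params$VT
    if (mean(sub) < 0.5) {
      stop("target membrane sd unreachable without spiking; ceiling sd ~ ",
           signif(sd(v[sub]), 3), " mV")
    }
    list(sd = sd(v[sub]), n_spikes = length(r$spikes))
  }
  s0 <- if (is.null(seed)) 1L else seed
  amp <- target_sd * params$gL * sqrt(2 * params$C / params$gL)  # OU-style guess
  for (i in 1:6) {
    m <- measure(amp, s0)
    if (abs(m$sd - target_sd) / target_sd < 0.02) break
    amp <- amp * target_sd / m$sd
  }
  amp
}
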