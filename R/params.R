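#' Membrane parameters for one cell class
#'
#' Adaptive exponential integrate-and-fire (aEIF) constants for the two cell
#' classes of the sheet: regular-spiking pyramidal (P) cells with
#' spike-frequency adaptation, and fast-spiking (FS) interneurons with a fast
#' membrane, sharp spike initiation and no adaptation. Defaults follow the
#' standard aEIF literature for these firing phenotypes; every value can be
#' overridden. The FS spike-initiation threshold `VT` defaults to -47 mV (its
#' control value); raising it emulates the net effect of mutual FS inhibition.
#'
#' @param class `"P"` or `"FS"`.
#' @param ... named overrides of any field: `C` (pF), `gL` (nS), `EL` (mV),
#'   `VT` (mV), `DT` (mV, slope factor), `a` (nS), `tau_w` (ms), `b` (pA),
#'   `Vreset` (mV), `Vcut` (mV, numerical spike cutoff), `tref` (ms).
#' @return a named list of class `neuron_params`.
#' @export
neuron_params <- function(class = c("P", "FS"), ...) {
  class <- match.arg(class)
  p <- switch(class,
    P = list(C = 200, gL = 10, EL = -70, VT = -50, DT = 2,
             a = 2, tau_w = 150, b = 30, Vreset = -58, Vcut = 0, tref = 2),
    FS = list(C = 100, gL = 10, EL = -65, VT = -47, DT = 0.4,
              a = 0, tau_w = 30, b = 0, Vreset = -55, Vcut = 0, tref = 2))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$C > 0, p$gL > 0, p$tau_w > 0, p$DT > 0, p$Vreset < p$Vcut)
  structure(c(p, list(class = class)), class = "neuron_params")
}

#' Synaptic parameters for one pathway
#'
#' Unitary conductance amplitude, alpha-kernel time constant, reversal
#' potential, Tsodyks-Markram short-term plasticity constants and transmission
#' delay for each of the five pathways of the circuit. All pathways depress
#' (`U`, `tau_rec`); facilitation is available via `tau_facil` but unused by
#' default. The alpha kernel is normalized so its peak equals the (plasticity-
#' scaled) unitary amplitude `A`. Amplitudes were calibrated once so the
#' network operates in the regimes the circuit is known to occupy: cortical
#' firing begins near N_max ~ 20 with a 40-um-wide stimulus, FS inhibition
#' onto P cells is substantially stronger than the sparse recurrent
#' excitation, and evoked rates sit in the midrange of the cells' F/I curves.
#'
#' @param pathway one of `"thal_p"`, `"thal_fs"`, `"pp"`, `"pfs"`, `"fsp"`.
#' @param ... named overrides: `A` (nS), `tau` (ms, alpha time-to-peak),
#'   `Erev` (mV), `U` (in (0,1]), `tau_rec` (ms), `tau_facil` (ms; 0 = none),
#'   `delay` (ms), `scale` (multiplicative prescale of `A`, used for
#'   steady-state background depression).
#' @return a named list of class `synapse_params`.
#' @export
synapse_params <- function(pathway = c("thal_p", "thal_fs", "pp", "pfs", "fsp"),
                           ...) {
  pathway <- match.arg(pathway)
  p <- switch(pathway,
    thal_p  = list(A = 0.6, tau = 5.0, Erev = 0, U = 0.7, tau_rec = 500,
                   tau_facil = 0, delay = 1, scale = 1),
    thal_fs = list(A = 5.0, tau = 1.2, Erev = 0, U = 0.3, tau_rec = 300,
                   tau_facil = 0, delay = 1, scale = 1),
    pp      = list(A = 0.8, tau = 2.0, Erev = 0, U = 0.4, tau_rec = 400,
                   tau_facil = 0, delay = 1, scale = 1),
    pfs     = list(A = 0.15, tau = 0.8, Erev = 0, U = 0.5, tau_rec = 400,
                   tau_facil = 0, delay = 1, scale = 1),
    fsp     = list(A = 6.0, tau = 3.0, Erev = -80, U = 0.25, tau_rec = 300,
                   tau_facil = 0, delay = 1, scale = 1))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown synapse parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$U > 0, p$U <= 1, p$tau_rec > 0, p$tau > 0, p$A >= 0)
  structure(c(p, list(pathway = pathway)), class = "synapse_params")
}

#' Gaussian distance-dependent connection-probability profile
#'
#' @param peak connection probability at zero intersomatic distance (in
#'   \[0, 1\]).
#' @param sigma radial spread of connectivity (um).
#' @return a list of class `connectivity_profile`.
#' @export
connectivity_profile <- function(peak, sigma) {
  stopifnot(peak >= 0, peak <= 1, sigma > 0)
  structure(list(peak = peak, sigma = sigma), class = "connectivity_profile")
}

#' In-vitro connectivity profiles for the three intracortical pathways
#'
#' Peak probabilities 0.10 (P to P), 0.30 (P to FS) and 0.39 (FS to P) with
#' radial spreads of 145, 92 and 92 um respectively, as measured in the
#' thalamorecipient layers of auditory cortex.
#'
#' @return named list of [connectivity_profile()] objects (`pp`, `pfs`, `fsp`).
#' @export
default_connectivity <- function() {
  list(pp  = connectivity_profile(0.10, 145),
       pfs = connectivity_profile(0.30, 92),
       fsp = connectivity_profile(0.39, 92))
}

#' Connection probability at a given intersomatic distance
#'
#' @param d radial distance (um), >= 0.
#' @param profile a [connectivity_profile()].
#' @return probability `peak * exp(-d^2 / (2 sigma^2))`.
#' @examples
#' connection_probability(0, connectivity_profile(0.39, 92))   # 0.39
#' @export
connection_probability <- function(d, profile) {
  stopifnot(inherits(profile, "connectivity_profile"), all(d >= 0))
  profile$peak * exp(-d^2 / (2 * profile$sigma^2))
}
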