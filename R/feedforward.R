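#' Parameters of the reduced feedforward model
#'
#' The feedforward reduction of the circuit: thalamic current with a Gaussian
#' spatial profile drives excitatory and inhibitory cells; inhibitory firing
#' is a threshold-linear transform of that current (the iceberg effect), is
#' spread by the Gaussian inhibitory-to-excitatory connection profile, and is
#' converted back to a current. Widths are naturally expressed in units of
#' the inhibitory spread `sigma_inh`, currents in units of the firing
#' threshold.
#'
#' @param sigma_thal standard deviation of the thalamic input profile (um, or
#'   any length unit).
#' @param i_max peak thalamic current (arbitrary current units).
#' @param theta threshold current for inhibitory-cell firing (same units);
#'   0 removes the threshold (linear transform).
#' @param sigma_inh standard deviation of the inhibitory axonal spread (same
#'   length unit as `sigma_thal`).
#' @param m slope of the firing-current relation (Hz per current unit).
#' @param k_c current-per-rate conversion constant (nA/Hz); scales the peak
#'   inhibitory current but cancels in width ratios.
#' @param r_ei ratio of the thalamic input width seen by inhibitory cells to
#'   that seen by excitatory cells (1 = equal tuning).
#' @param dx lattice spacing; defaults to `min(sigma_inh, sigma_thal) / 50`.
#' @param span half-extent of the lattice; defaults to 6 standard deviations
#'   of the widest profile.
#' @return a list of class `ff_params`.
#' @export
ff_params <- function(sigma_thal, i_max = 2, theta = 1, sigma_inh = 1,
                      m = 1, k_c = 1, r_ei = 1, dx = NULL, span = NULL) {
  stopifnot(sigma_thal > 0, sigma_inh > 0, m > 0, theta >= 0, r_ei > 0,
            i_max > 0)
  if (is.null(dx)) dx <- min(sigma_inh, sigma_thal) / 50
  if (is.null(span)) span <- 6 * max(sigma_thal * max(1, r_ei), sigma_inh)
  structure(list(sigma_thal = sigma_thal, sigma_inh = sigma_inh,
                 i_max = i_max, theta = theta, m = m, k_c = k_c,
                 r_ei = r_ei, dx = dx, span = span),
            class = "ff_params")
}

# symmetric 1-D lattice
ff_lattice <- function(p) {
  n <- ceiling(p$span / p$dx)
  seq(-n, n) * p$dx
}

# same-length discrete convolution (FFT) of a profile with a symmetric kernel
conv_same <- function(f, kernel, dx) {
  full <- convolve(f, kernel, type = "open")
  start <- (length(kernel) + 1) / 2
  full[start:(start + length(f) - 1)] * dx
}

#' Excitatory input profile of the feedforward model
#'
#' Inherited directly from the thalamic input: a Gaussian with peak `i_max`
#' and standard deviation `sigma_thal`.
#'
#' @param params an [ff_params()].
#' @return tibble with `x` and `value` (class `cotune_profile`).
#' @export
ff_excitatory_profile <- function(params) {
  stopifnot(inherits(params, "ff_params"))
  x <- ff_lattice(params)
  out <- tibble(x = x,
                value = params$i_max * exp(-x^2 / (2 * params$sigma_thal^2)))
  class(out) <- c("cotune_profile", class(out))
  out
}

#' Inhibitory input profile of the feedforward model
#'
#' The thalamic current to inhibitory cells (width `r_ei * sigma_thal`) is
#' passed through the threshold-linear rate transform
#' `m * max(I - theta, 0)`, convolved with the Gaussian inhibitory axonal
#' spread, and scaled by the current-per-rate constant. Identically zero when
#' `i_max <= theta`.
#'
#' @param params an [ff_params()].
#' @return tibble with `x` and `value` (class `cotune_profile`).
#' @export
ff_inhibitory_profile <- function(params) {
  stopifnot(inherits(params, "ff_params"))
  x <- ff_lattice(params)
  s_i <- params$sigma_thal * params$r_ei
  i_thal <- params$i_max * exp(-x^2 / (2 * s_i^2))
  f_inh <- params$m * pmax(i_thal - params$theta, 0)
  if (sum(f_inh) > 0) {
    edge <- max(f_inh[1], f_inh[length(f_inh)])
    if (edge > 1e-6 * sum(f_inh)) {
      stop("lattice too narrow: profile mass at the boundary; increase `span`")
    }
  }
  kern <- exp(-x^2 / (2 * params$sigma_inh^2))
  out <- tibble(x = x, value = params$k_c * conv_same(f_inh, kern, params$dx))
  class(out) <- c("cotune_profile", class(out))
  out
}

#' Width ratio of the feedforward model at one parameter point
#'
#' @param params an [ff_params()].
#' @return one-row tibble with `w_exc`, `w_inh` and `ratio` (`NA` when the
#'   inhibitory profile is identically zero, i.e. below threshold).
#' @export
ff_width_ratio <- function(params) {
  pe <- ff_excitatory_profile(params)
  pinh <- ff_inhibitory_profile(params)
  w_exc <- half_width(pe)
  if (max(pinh$value) <= 0) {
    return(tibble(w_exc = w_exc, w_inh = NA_real_, ratio = NA_real_))
  }
  w_inh <- half_width(pinh)
  tibble(w_exc = w_exc, w_inh = w_inh, ratio = w_inh / w_exc)
}

#' Width-ratio and peak-current surfaces over the stimulus plane
#'
#' Recomputes the feedforward model over a grid of peak input currents
#' (normalized by the firing threshold, i.e. rheobase) and thalamic widths
#' (normalized by the inhibitory spread), reporting the inhibitory/excitatory
#' half-width ratio and both peak currents at every grid point. Lateral
#' inhibition shows as ratios above 1 at small widths; the ratio = 1 contour
#' marks exact co-tuning.
#'
#' @param i_max_norm peak currents in units of `theta` (>= 1 for the
#'   supra-threshold regime).
#' @param sigma_norm thalamic widths in units of `sigma_inh`.
#' @param theta threshold current (0 removes the threshold; `i_max_norm` is
#'   then interpreted as an absolute current).
#' @param r_ei unequal-tuning factor (see [ff_params()]).
#' @param ... further arguments passed to [ff_params()].
#' @return tibble with `i_max_norm`, `sigma_norm`, `w_exc`, `w_inh`, `ratio`,
#'   `peak_exc`, `peak_inh`; below-threshold points carry `NA` ratios.
#' @export
ff_surface <- function(i_max_norm, sigma_norm, theta = 1, r_ei = 1, ...) {
  grid <- tidyr::expand_grid(i_max_norm = i_max_norm, sigma_norm = sigma_norm)
  purrr::pmap_dfr(grid, function(i_max_norm, sigma_norm) {
    i_abs <- if (theta > 0) i_max_norm * theta else i_max_norm
    p <- ff_params(sigma_thal = sigma_norm, sigma_inh = 1, i_max = i_abs,
                   theta = theta, r_ei = r_ei, ...)
    pinh <- ff_inhibitory_profile(p)
    wr <- ff_width_ratio(p)
    tibble(i_max_norm = i_max_norm, sigma_norm = sigma_norm,
           w_exc = wr$w_exc, w_inh = wr$w_inh, ratio = wr$ratio,
           peak_exc = i_abs, peak_inh = max(pinh$value))
  })
}

#' Co-tuning contour of a width-ratio surface
#'
#' Extracts the `ratio = 1` polyline: for each input level, the width
#' (interpolated along `sigma_norm`) where the surface crosses unity.
#'
#' @param surface a [ff_surface()] (or rate-model surface) tibble with
#'   columns `i_max_norm` (or `n_max`), `sigma_norm` (or `sigma`) and
#'   `ratio`.
#' @return tibble with one row per input level that crosses 1.
#' @export
cotuning_contour <- function(surface) {
  icol <- intersect(c("i_max_norm", "n_max"), names(surface))[1]
  scol <- intersect(c("sigma_norm", "sigma"), names(surface))[1]
  purrr::map_dfr(split(surface, surface[[icol]]), function(df) {
    df <- df[order(df[[scol]]), ]
    ok <- is.finite(df$ratio)
    df <- df[ok, ]
    if (nrow(df) < 2) return(NULL)
    s <- sign(df$ratio - 1)
    k <- which(s[-1] * s[-nrow(df)] < 0)
    if (length(k) == 0) return(NULL)
    k <- k[1]
    x0 <- df[[scol]][k]; x1 <- df[[scol]][k + 1]
    r0 <- df$ratio[k]; r1 <- df$ratio[k + 1]
    out <- tibble(a = df[[icol]][1], b = x0 + (1 - r0) / (r1 - r0) * (x1 - x0))
    names(out) <- c(icol, scol)
    out
  })
}
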