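#' Naka-Rushton transfer function
#'
#' Saturating rate-versus-input relation `M * x^n / (x^n + theta^n)` with
#' semi-saturation at `x = theta`. Negative inputs are rectified to 0 (net
#' inhibition silences, it does not produce negative rates).
#'
#' @param x input (current units); vectorized.
#' @param M maximum rate (Hz).
#' @param theta semi-saturation input.
#' @param n exponent (>= 1).
#' @return rate (Hz), in \[0, M).
#' @examples
#' naka_rushton(0.5, M = 75, theta = 0.5, n = 4)  # M/2 = 37.5
#' @export
naka_rushton <- function(x, M, theta, n) {
  stopifnot(M > 0, theta > 0, n >= 1)
  x <- pmax(x, 0)
  M * x^n / (x^n + theta^n)
}

#' Parameters of the spatial firing-rate model
#'
#' One-dimensional Wilson-Cowan-style population model: excitatory and
#' inhibitory rate fields relax (time constants `tau_exc` > `tau_inh`,
#' mirroring the P and FS membranes) toward a Naka-Rushton transform of their
#' net input current. Synaptic weight kernels are `rho * A * P(x)`:
#' presynaptic cell density times unitary strength (pA/Hz) times the
#' connectivity profile. Thalamic drive is a constant current with a Gaussian
#' spatial profile, `w_thal * F_thal * n_max * exp(-x^2 / (2 sigma^2))`, with
#' `F_thal` fixed at 20 Hz and identical (n_max, sigma) for both populations.
#' Defaults reproduce the model's characteristic regimes: sustained, narrow
#' firing under narrow input and transient firing with broadened inhibition
#' under wide input. No short-term plasticity (transient responses only).
#'
#' @param ... named overrides of any field: `dx` (um), `length` (um),
#'   `tau_exc`, `tau_inh` (ms), `rho_e`, `rho_i` (cells/um), `A_ee`, `A_ie`,
#'   `A_ei` (pA/Hz), kernel profiles `P_ee`, `P_ie`, `P_ei`
#'   (each `list(peak, sigma)`), `kernel_family` (`"gaussian"`, `"box"`,
#'   `"quadratic"`, `"binomial"`), `w_thal_e`, `w_thal_i` (pA/Hz per
#'   afferent), `f_thal` (Hz), `nr_exc`, `nr_inh` (each
#'   `list(M, theta, n)`).
#' @return a list of class `rate_params`.
#' @export
rate_params <- function(...) {
  p <- list(
    dx = 5, length = 1185,
    tau_exc = 10, tau_inh = 8,
    rho_e = 160 / 1185, rho_i = 32 / 1185,
    A_ee = 0.3, A_ie = 0.7, A_ei = 3.5,
    P_ee = list(peak = 0.10, sigma = 145),
    P_ie = list(peak = 0.30, sigma = 92),
    P_ei = list(peak = 0.39, sigma = 92),
    kernel_family = "gaussian",
    w_thal_e = 1, w_thal_i = 1, f_thal = 20,
    nr_exc = list(M = 100, theta = 300, n = 2),
    nr_inh = list(M = 120, theta = 550, n = 2))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown rate-model parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$tau_exc > 0, p$tau_inh > 0, p$dx > 0,
            p$kernel_family %in% c("gaussian", "box", "quadratic", "binomial"))
  structure(p, class = "rate_params")
}

# kernel profile value at offsets x, unit peak, matched standard deviation
kernel_shape <- function(x, sigma, family) {
  switch(family,
    gaussian = exp(-x^2 / (2 * sigma^2)),
    box = as.numeric(abs(x) <= sigma * sqrt(3)),
    quadratic = pmax(1 - x^2 / (5 * sigma^2), 0),
    binomial = {
      # binomial(n, 1/2) pmf on the lattice, n chosen to match sd = sigma
      dx <- if (length(x) > 1) x[2] - x[1] else 1
      n <- max(2, round((2 * sigma / dx)^2))
      k <- round(x / dx) + n / 2
      v <- ifelse(k >= 0 & k <= n, dbinom(round(k), n, 0.5), 0)
      v / max(v)
    },
    stop("unsupported kernel family: ", family))
}

#' Discretized synaptic weight kernel
#'
#' `w(x) = rho * A * P(x)` sampled on the model lattice, where `P(x)` is the
#' pathway's connectivity profile in the configured kernel family (non-
#' Gaussian families are width-matched to the Gaussian's standard deviation).
#'
#' @param pathway `"ee"` (E to E), `"ie"` (E to I) or `"ei"` (I to E).
#' @param params a [rate_params()].
#' @return tibble with `x` (offset, um) and `w` (pA/Hz per um).
#' @export
weight_kernel <- function(pathway = c("ee", "ie", "ei"), params = rate_params()) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(params, "rate_params"))
  pr <- switch(pathway, ee = params$P_ee, ie = params$P_ie, ei = params$P_ei)
  A <- switch(pathway, ee = params$A_ee, ie = params$A_ie, ei = params$A_ei)
  rho <- switch(pathway, ee = params$rho_e, ie = params$rho_e, ei = params$rho_i)
  if (params$dx > pr$sigma / 2)
    stop("lattice spacing too coarse for kernel width")
  n <- ceiling(params$length / params$dx)
  x <- seq(-n, n) * params$dx
  v <- kernel_shape(x, pr$sigma, params$kernel_family)
  v[v < 1e-6] <- 0
  tibble(x = x, w = rho * A * pr$peak * v)
}

# lattice positions of the model
rate_lattice <- function(params) {
  n <- floor(params$length / params$dx)
  if (n %% 2 == 0) n <- n - 1
  (seq_len(n) - (n + 1) / 2) * params$dx
}

# dense weight matrix W[i, j] = w(x_i - x_j) * dx
weight_matrix <- function(pathway, params, x) {
  kt <- weight_kernel(pathway, params)
  wf <- approxfun(kt$x, kt$w, yleft = 0, yright = 0)
  outer(x, x, function(a, b) wf(a - b)) * params$dx
}

#' Integrate the spatial firing-rate model
#'
#' Explicit (Euler) integration of the coupled excitatory/inhibitory rate
#' fields from zero initial rates under a constant Gaussian thalamic drive.
#'
#' @param params a [rate_params()].
#' @param n_max peak thalamic input (afferent count; the center current is
#'   `w_thal * f_thal * n_max` pA).
#' @param sigma spatial standard deviation of the drive (um).
#' @param duration simulated time (ms).
#' @param dt time step (ms); must satisfy `dt <= min(tau)/20`.
#' @return object of class `rate_sim`: `x`, `t`, rate fields `f_exc`,
#'   `f_inh` (space x time, Hz) and current-input fields `i_exc`, `i_inh`
#'   onto excitatory cells (pA).
#' @export
rate_sim <- function(params, n_max, sigma, duration = 100, dt = 0.25) {
  stopifnot(inherits(params, "rate_params"), n_max >= 0, sigma > 0)
  if (dt > min(params$tau_exc, params$tau_inh) / 20)
    stop("dt too large: must be <= min(tau_exc, tau_inh)/20")
  x <- rate_lattice(params)
  nx <- length(x)
  W_ee <- weight_matrix("ee", params, x)
  W_ie <- weight_matrix("ie", params, x)
  W_ei <- weight_matrix("ei", params, x)
  thal_e <- params$w_thal_e * params$f_thal * n_max * exp(-x^2 / (2 * sigma^2))
  thal_i <- params$w_thal_i * params$f_thal * n_max * exp(-x^2 / (2 * sigma^2))
  nt <- round(duration / dt)
  f_e <- matrix(0, nx, nt); f_i <- matrix(0, nx, nt)
  i_e <- matrix(0, nx, nt); i_i <- matrix(0, nx, nt)
  Fe <- numeric(nx); Fi <- numeric(nx)
  for (s in seq_len(nt)) {
    exc_in <- thal_e + as.numeric(W_ee %*% Fe)
    inh_in <- as.numeric(W_ei %*% Fi)
    Se <- naka_rushton(exc_in - inh_in, params$nr_exc$M, params$nr_exc$theta,
                       params$nr_exc$n)
    Si <- naka_rushton(thal_i + as.numeric(W_ie %*% Fe), params$nr_inh$M,
                       params$nr_inh$theta, params$nr_inh$n)
    Fe <- Fe + dt / params$tau_exc * (-Fe + Se)
    Fi <- Fi + dt / params$tau_inh * (-Fi + Si)
    if (any(!is.finite(Fe)) || any(!is.finite(Fi)))
      stop("non-finite rate field at t = ", s * dt, " ms")
    f_e[, s] <- Fe; f_i[, s] <- Fi
    i_e[, s] <- exc_in; i_i[, s] <- inh_in
  }
  structure(list(x = x, t = seq_len(nt) * dt, f_exc = f_e, f_inh = f_i,
                 i_exc = i_e, i_inh = i_i, n_max = n_max, sigma = sigma,
                 dt = dt, params = params),
            class = "rate_sim")
}

#' Mean center-cell rate over a window
#'
#' @param sim a [rate_sim()] result.
#' @param window averaging window (ms); the first 50 ms by default.
#' @return mean excitatory rate of the center cell (Hz).
#' @export
mean_center_rate <- function(sim, window = c(0, 50)) {
  stopifnot(inherits(sim, "rate_sim"))
  ic <- which.min(abs(sim$x))
  keep <- sim$t > window[1] & sim$t <= window[2]
  mean(sim$f_exc[ic, keep])
}

#' Width ratio of the current inputs to excitatory cells
#'
#' FWHM of the spatial profile of per-position peak inhibitory current over
#' that of peak excitatory current, within a window.
#'
#' @param sim a [rate_sim()].
#' @param window peak-search window (ms).
#' @return one-row tibble with `w_exc`, `w_inh`, `ratio` (`NA` if the
#'   inhibitory field is identically zero).
#' @export
rate_width_ratio <- function(sim, window = c(0, 50)) {
  stopifnot(inherits(sim, "rate_sim"))
  keep <- sim$t > window[1] & sim$t <= window[2]
  pe <- apply(sim$i_exc[, keep, drop = FALSE], 1, max)
  pinh <- apply(sim$i_inh[, keep, drop = FALSE], 1, max)
  if (max(pe) <= 0)
    return(tibble(w_exc = NA_real_, w_inh = NA_real_, ratio = NA_real_))
  w_exc <- fwhm_linear(sim$x, pe)
  if (max(pinh) <= 0)
    return(tibble(w_exc = w_exc, w_inh = NA_real_, ratio = NA_real_))
  tibble(w_exc = w_exc, w_inh = fwhm_linear(sim$x, pinh),
         ratio = fwhm_linear(sim$x, pinh) / w_exc)
}

#' Rate-model response surfaces over the stimulus plane
#'
#' For every (n_max, sigma) grid point: the center cell's mean excitatory
#' rate over the first 50 ms, the inhibitory/excitatory input width ratio,
#' and the peak input currents.
#'
#' @param params a [rate_params()].
#' @param n_max,sigma grid axes.
#' @param duration simulated time per point (ms).
#' @param dt integration step (ms).
#' @param window analysis window (ms).
#' @return tibble with `n_max`, `sigma`, `mean_rate`, `w_exc`, `w_inh`,
#'   `ratio`, `peak_exc`, `peak_inh`.
#' @export
rate_surfaces <- function(params = rate_params(), n_max, sigma,
                          duration = 55, dt = 0.25, window = c(0, 50)) {
  grid <- tidyr::expand_grid(n_max = n_max, sigma = sigma)
  purrr::pmap_dfr(grid, function(n_max, sigma) {
    sim <- rate_sim(params, n_max, sigma, duration = duration, dt = dt)
    wr <- rate_width_ratio(sim, window)
    keep <- sim$t > window[1] & sim$t <= window[2]
    tibble(n_max = n_max, sigma = sigma,
           mean_rate = mean_center_rate(sim, window),
           w_exc = wr$w_exc, w_inh = wr$w_inh, ratio = wr$ratio,
           peak_exc = max(sim$i_exc[, keep]),
           peak_inh = max(sim$i_inh[, keep]))
  })
}

#' Stimulus-intensity transfer functions
#'
#' Maps stimulus intensity in \[0, 1\] to the (n_max, sigma) of the thalamic
#' drive through two Naka-Rushton transfers, emulating how thalamic
#' recruitment grows with sound level. An additive `sigma_offset` emulates a
#' broader thalamocortical terminal field.
#'
#' @param nmax `list(M, theta, n)` for the n_max transfer.
#' @param sigma `list(M, theta, n)` for the sigma transfer (um).
#' @param sigma_offset additive offset on sigma (um).
#' @return a list of class `intensity_transfer`.
#' @export
intensity_transfer <- function(nmax = list(M = 1000, theta = 0.4, n = 5),
                               sigma = list(M = 75, theta = 0.5, n = 4),
                               sigma_offset = 0) {
  structure(list(nmax = nmax, sigma = sigma, sigma_offset = sigma_offset),
            class = "intensity_transfer")
}

# evaluate a transfer at intensities
eval_transfer <- function(transfer, intensity) {
  tibble(intensity = intensity,
         n_max = naka_rushton(intensity, transfer$nmax$M, transfer$nmax$theta,
                              transfer$nmax$n),
         sigma = transfer$sigma_offset +
           naka_rushton(intensity, transfer$sigma$M, transfer$sigma$theta,
                        transfer$sigma$n))
}

#' Rate-versus-intensity trajectory
#'
#' Traverses the mean-rate surface along the (n_max, sigma) trajectory
#' defined by an intensity transfer and classifies the resulting
#' rate-intensity function. The curve is non-monotonic when its maximum
#' occurs at an interior intensity and the terminal value falls below 90% of
#' that maximum (robust to plateau noise); otherwise it is
#' monotonic-increasing.
#'
#' @param params a [rate_params()].
#' @param transfer an [intensity_transfer()].
#' @param intensities sorted intensities in \[0, 1\].
#' @param surface optional precomputed [rate_surfaces()] tibble on a regular
#'   grid; when supplied the trajectory is bilinearly interpolated on it
#'   (an error is raised if the trajectory leaves the grid), otherwise each
#'   trajectory point is integrated directly.
#' @param duration,dt integration controls (direct evaluation).
#' @param sigma_floor smallest sigma used (um); transfers start at 0.
#' @return list with `curve` (tibble: `intensity`, `n_max`, `sigma`, `rate`)
#'   and `class` (`"monotonic-increasing"` or `"non-monotonic"`).
#' @export
intensity_response <- function(params = rate_params(), transfer,
                               intensities = seq(0, 1, by = 0.05),
                               surface = NULL, duration = 55, dt = 0.25,
                               sigma_floor = 5) {
  stopifnot(inherits(transfer, "intensity_transfer"),
            !is.unsorted(intensities),
            all(intensities >= 0 & intensities <= 1))
  traj <- eval_transfer(transfer, intensities)
  traj$sigma <- pmax(traj$sigma, sigma_floor)
  if (is.null(surface)) {
    traj$rate <- purrr::map2_dbl(traj$n_max, traj$sigma, function(nm, sg) {
      mean_center_rate(rate_sim(params, nm, sg, duration = duration, dt = dt))
    })
  } else {
    gx <- sort(unique(surface$n_max)); gy <- sort(unique(surface$sigma))
    if (any(traj$n_max < min(gx) - 1e-9) || any(traj$n_max > max(gx) + 1e-9) ||
        any(traj$sigma < min(gy) - 1e-9) || any(traj$sigma > max(gy) + 1e-9))
      stop("trajectory leaves the computed surface; extend the grid")
    zm <- matrix(NA_real_, length(gx), length(gy))
    zm[cbind(match(surface$n_max, gx), match(surface$sigma, gy))] <-
      surface$mean_rate
    bilin <- function(xq, yq) {
      i <- findInterval(xq, gx, rightmost.closed = TRUE)
      j <- findInterval(yq, gy, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1), length(gx) - 1)
      j <- pmin(pmax(j, 1), length(gy) - 1)
      tx <- (xq - gx[i]) / (gx[i + 1] - gx[i])
      ty <- (yq - gy[j]) / (gy[j + 1] - gy[j])
      zm[cbind(i, j)] * (1 - tx) * (1 - ty) +
        zm[cbind(i + 1, j)] * tx * (1 - ty) +
        zm[cbind(i, j + 1)] * (1 - tx) * ty +
        zm[cbind(i + 1, j + 1)] * tx * ty
    }
    traj$rate <- bilin(traj$n_max, traj$sigma)
  }
  pk <- which.max(traj$rate)
  interior <- pk > 1 && pk < nrow(traj)
  spread <- max(traj$rate) - min(traj$rate)
  cls <- if (spread <= 1e-9) {
    "monotonic-increasing"   # flat curve, monotonic by convention
  } else if (interior && traj$rate[nrow(traj)] < 0.9 * max(traj$rate)) {
    "non-monotonic"
  } else "monotonic-increasing"
  list(curve = traj, class = cls)
}
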