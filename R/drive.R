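#' Spatially Gaussian thalamic drive
#'
#' Describes the stimulus delivered to the cortical sheet: every cortical cell
#' receives a number of thalamic afferents that is Gaussian-distributed in
#' space (peak `n_max` afferents at the stimulus center, standard deviation
#' `sigma`), each afferent firing a jittered regular train whose rate follows
#' the same Gaussian envelope (peak `f_max`). Two-tone stimuli are composites
#' of two such envelopes (see [two_tone_drive()]).
#'
#' @param n_max peak number of afferents converging on the cell at the
#'   stimulus center (dimensionless count, >= 0).
#' @param sigma standard deviation of the spatial envelope (um).
#' @param f_max peak afferent firing rate (Hz). Default 50.
#' @param center stimulus center `c(x, y)` (um).
#' @param duration train duration (ms). Default 100.
#' @return an object of class `thalamic_drive`.
#' @examples
#' d <- thalamic_drive(n_max = 60, sigma = 40)
#' spatial_envelope(d, x = 0, y = 0)          # 60 at the center
#' spatial_envelope(d, x = 40, y = 0)         # 60 * exp(-1/2)
#' @export
thalamic_drive <- function(n_max, sigma, f_max = 50, center = c(0, 0),
                           duration = 100) {
  stopifnot(is.numeric(n_max), length(n_max) == 1, n_max >= 0)
  if (!is.numeric(f_max) || f_max <= 0) stop("`f_max` must be > 0")
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  stopifnot(length(center) == 2)
  structure(
    list(n_max = n_max, f_max = f_max, sigma = sigma,
         centers = matrix(center, nrow = 1, dimnames = list(NULL, c("x", "y"))),
         duration = duration),
    class = "thalamic_drive")
}

#' Two-tone composite drive
#'
#' Superposes a second, identical Gaussian envelope at a separation `delta_x`
#' along the tonotopic (x) axis, emulating a two-tone stimulus. Per-cell
#' afferent counts from the two envelopes add before rounding; each afferent
#' fires at the rate envelope of the stimulus it belongs to.
#'
#' @param drive a single-stimulus [thalamic_drive()].
#' @param delta_x separation of the second stimulus center along x (um, >= 0).
#' @return a `thalamic_drive` with two centers.
#' @export
two_tone_drive <- function(drive, delta_x) {
  stopifnot(inherits(drive, "thalamic_drive"))
  if (nrow(drive$centers) != 1) stop("`drive` must be a single-stimulus drive")
  if (!is.numeric(delta_x) || delta_x < 0) stop("`delta_x` must be >= 0")
  drive$centers <- rbind(drive$centers,
                         drive$centers[1, ] + c(delta_x, 0))
  drive
}

# per-stimulus Gaussian envelopes at (x, y): matrix [points x stimuli]
stim_envelopes <- function(drive, x, y, peak) {
  vapply(seq_len(nrow(drive$centers)), function(s) {
    d2 <- (x - drive$centers[s, 1])^2 + (y - drive$centers[s, 2])^2
    peak * exp(-d2 / (2 * drive$sigma^2))
  }, numeric(length(x)))
}

#' Evaluate the spatial envelope of a drive
#'
#' The count envelope gives the (pre-rounding) number of afferents a cell at
#' `(x, y)` receives; the rate envelope gives the firing rate of those
#' afferents. For two-tone composites the count envelopes of the stimuli add;
#' the rate envelope is the count-weighted mean of the per-stimulus rates
#' (each afferent fires at its own stimulus' rate).
#'
#' @param drive a [thalamic_drive()].
#' @param x,y positions (um); vectors of equal length.
#' @param which `"count"` or `"rate"`.
#' @return numeric vector of envelope values.
#' @export
spatial_envelope <- function(drive, x, y, which = c("count", "rate")) {
  stopifnot(inherits(drive, "thalamic_drive"), length(x) == length(y))
  which <- match.arg(which)
  cnt <- matrix(stim_envelopes(drive, x, y, drive$n_max), nrow = length(x))
  if (which == "count") return(rowSums(cnt))
  rate <- matrix(stim_envelopes(drive, x, y, drive$f_max), nrow = length(x))
  tot <- rowSums(cnt)
  out <- rowSums(rate * cnt) / tot
  out[tot == 0] <- 0
  out
}

#' Generate jittered regular spike trains
#'
#' Each train fires repetitively at a nominal rate: the latency of the first
#' spike and every successive inter-spike interval are Gaussian with mean
#' `1/rate` and standard deviation `0.25/rate`, so the population is
#' phasic-tonic (synchronous at onset, desynchronizing over time). Sampled
#' non-positive intervals are re-drawn (tail mass ~3e-5), preserving strictly
#' increasing spike times. Trains are truncated at `duration`.
#'
#' @param rate firing rate (Hz); scalar or one value per train.
#' @param duration train duration (ms).
#' @param n_trains number of trains.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return tibble with columns `train` and `t` (ms), times increasing within
#'   each train. Trains with no spike before `duration` are absent.
#' @export
generate_trains <- function(rate, duration, n_trains, seed = NULL) {
  if (any(!is.finite(rate)) || any(rate <= 0)) stop("`rate` must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  stopifnot(n_trains >= 0)
  if (n_trains == 0) return(tibble(train = integer(), t = numeric()))
  rate <- rep_len(rate, n_trains)
  with_seed(seed, {
    m <- 1000 / rate                      # mean ISI, ms
    k <- max(8L, ceiling(1.4 * duration * max(rate) / 1000 + 6))
    draw <- function(n, mm) {
      z <- rnorm(n, mean = mm, sd = 0.25 * mm)
      while (any(bad <- z <= 0)) z[bad] <- rnorm(sum(bad), mean = mm[bad], sd = 0.25 * mm[bad])
      z
    }
    mm <- rep(m, each = k)
    isi <- matrix(draw(k * n_trains, mm), nrow = k)
    tt <- apply(isi, 2, cumsum)
    # extend any train still short of `duration` (rare for sane k)
    while (any(tt[k, ] <= duration)) {
      short <- which(tt[k, ] <= duration)
      extra <- matrix(draw(k * length(short), rep(m[short], each = k)), nrow = k)
      tt2 <- matrix(rep(tt[k, short], each = k), nrow = k) + apply(extra, 2, cumsum)
      tt <- rbind(tt, matrix(Inf, 2 * k, n_trains))
      tt[(k + 1):(2 * k), short] <- tt2
      k <- 2 * k
    }
    keep <- tt <= duration
    tibble(train = rep(seq_len(n_trains), each = k)[keep], t = tt[keep])
  })
}

#' Realize a drive as per-cell afferent spike trains
#'
#' Instantiates the drive on a set of cortical cells: the cell at position
#' \eqn{p} receives `round(count_envelope(p))` independent afferent trains,
#' each firing at `rate_envelope(p)` of its stimulus. Counts are rounded half
#' up; cells with rounded count 0 receive no drive. Afferents are private to
#' their target cell.
#'
#' @param drive a [thalamic_drive()].
#' @param coords data frame with columns `x`, `y` (um) and optionally `cell`
#'   (defaults to row number).
#' @param seed optional integer seed.
#' @return tibble with columns `cell`, `train` (afferent id within cell),
#'   `stimulus`, `rate` (Hz) and `t` (ms).
#' @export
realize_drive <- function(drive, coords, seed = NULL) {
  stopifnot(inherits(drive, "thalamic_drive"))
  coords <- as_tibble(coords)
  if (nrow(coords) == 0) stop("`coords` must be nonempty")
  if (is.null(coords$cell)) coords$cell <- seq_len(nrow(coords))
  cnt <- matrix(stim_envelopes(drive, coords$x, coords$y, drive$n_max),
                nrow = nrow(coords))
  rate <- matrix(stim_envelopes(drive, coords$x, coords$y, drive$f_max),
                 nrow = nrow(coords))
  tot <- rowSums(cnt)
  k_tot <- round_half_up(tot)
  n_stim <- ncol(cnt)
  # split counts across stimuli proportionally to their envelopes
  k <- matrix(0L, nrow(coords), n_stim)
  if (n_stim == 1) {
    k[, 1] <- k_tot
  } else {
    frac <- cnt[, 1] / pmax(tot, .Machine$double.eps)
    k[, 1] <- round_half_up(k_tot * frac)
    k[, 2] <- k_tot - k[, 1]
  }
  cell_id <- integer(0); stim_id <- integer(0); aff_rate <- numeric(0)
  for (s in seq_len(n_stim)) {
    nz <- which(k[, s] > 0)
    cell_id <- c(cell_id, rep(coords$cell[nz], k[nz, s]))
    stim_id <- c(stim_id, rep.int(s, sum(k[nz, s])))
    aff_rate <- c(aff_rate, rep(rate[nz, s], k[nz, s]))
  }
  if (length(cell_id) == 0)
    return(tibble(cell = integer(), train = integer(), stimulus = integer(),
                  rate = numeric(), t = numeric()))
  trains <- generate_trains(aff_rate, drive$duration, length(cell_id), seed = seed)
  out <- trains
  out$cell <- cell_id[trains$train]
  out$stimulus <- stim_id[trains$train]
  out$rate <- aff_rate[trains$train]
  # afferent id within cell
  ord <- order(out$cell, out$train, out$t)
  out <- out[ord, ]
  out$train <- match(out$train, unique(out$train))
  # renumber within cell
  first <- !duplicated(paste(out$cell, out$train))
  idx <- stats::ave(as.numeric(first), out$cell, FUN = cumsum)
  out$train <- as.integer(idx)
  tibble(cell = out$cell, train = out$train, stimulus = out$stimulus,
         rate = out$rate, t = out$t)
}
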