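#' Post-stimulus time histogram
#'
#' Spike counts per time bin divided by the number of sweeps, for a selectable
#' population and radial annulus.
#'
#' @param spikes a spike tibble (`sweep`, `pop`, `x`, `y`, `t`) or a
#'   `sim_record`.
#' @param bin_width bin width (ms), > 0.
#' @param n_sweeps number of sweeps (taken from the record if one is given).
#' @param pop optional population filter (`"P"` or `"FS"`).
#' @param r_range radial annulus `c(min, max)` (um) about `center`.
#' @param center reference point (um); defaults to the record's stimulus
#'   center or the origin.
#' @param t_max histogram extent (ms); defaults to the last spike's bin.
#' @return tibble with `t` (bin midpoint, ms) and `count` (spikes per bin per
#'   sweep).
#' @export
psth <- function(spikes, bin_width = 5, n_sweeps = NULL, pop = NULL,
                 r_range = c(0, Inf), center = NULL, t_max = NULL) {
  if (inherits(spikes, "sim_record")) {
    if (is.null(n_sweeps)) n_sweeps <- spikes$n_sweeps
    if (is.null(center)) center <- spikes$center
    spikes <- spikes$spikes
  }
  stopifnot(bin_width > 0)
  if (is.null(n_sweeps)) n_sweeps <- if (nrow(spikes)) max(spikes$sweep) else 1
  if (is.null(center)) center <- c(0, 0)
  df <- as_tibble(spikes)
  if (!is.null(pop)) df <- df[df$pop == pop, ]
  if (nrow(df) && (r_range[1] > 0 || is.finite(r_range[2]))) {
    r <- sqrt((df$x - center[1])^2 + (df$y - center[2])^2)
    df <- df[r >= r_range[1] & r < r_range[2], ]
  }
  if (is.null(t_max)) t_max <- if (nrow(df)) max(df$t) else bin_width
  breaks <- seq(0, ceiling(t_max / bin_width) * bin_width, by = bin_width)
  counts <- if (nrow(df)) {
    tabulate(findInterval(df$t, breaks, left.open = TRUE,
                          rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else rep(0L, length(breaks) - 1)
  tibble(t = breaks[-length(breaks)] + bin_width / 2,
         count = counts / n_sweeps)
}

#' Mean spike count per cell in a response window
#'
#' The standard quantification of evoked firing: spikes within a window after
#' stimulus onset, divided by the number of sweeps.
#'
#' @param spikes a spike tibble or `sim_record` (see [psth()]).
#' @param window counting window `c(start, end)` (ms); the first 50 ms by
#'   default.
#' @param pop population filter, `"P"` by default.
#' @param n_sweeps,coords number of sweeps and the population's cell
#'   coordinates (taken from the record if one is given).
#' @return tibble with one row per cell (`cell`, `x`, `y`, `count`),
#'   including zero-count cells.
#' @export
count_window <- function(spikes, window = c(0, 50), pop = "P",
                         n_sweeps = NULL, coords = NULL) {
  if (inherits(spikes, "sim_record")) {
    if (is.null(n_sweeps)) n_sweeps <- spikes$n_sweeps
    if (is.null(coords))
      coords <- if (pop == "P") spikes$p_coords else spikes$fs_coords
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(coords), !is.null(n_sweeps), length(window) == 2,
            window[2] > window[1])
  df <- spikes[spikes$pop == pop & spikes$t >= window[1] &
                 spikes$t <= window[2], ]
  n <- tabulate(df$cell, nbins = nrow(coords))
  tibble(cell = coords$cell, x = coords$x, y = coords$y,
         count = n / n_sweeps)
}

# index of the cell nearest a point
nearest_cell <- function(coords, point) {
  which.min((coords$x - point[1])^2 + (coords$y - point[2])^2)
}

#' Radially binned spatial profile
#'
#' Averages a per-cell quantity over annuli about a center, the standard
#' reduction of the sheet to a radial tuning profile.
#'
#' @param values tibble with columns `x`, `y` and `value`.
#' @param center reference point (um).
#' @param bin_width annulus width (um).
#' @param normalize divide by the peak value.
#' @return a `cotune_profile` tibble with `r` (bin midpoint, um), `value`,
#'   and `n` (cells per bin); empty annuli are dropped.
#' @export
radial_profile <- function(values, center = c(0, 0), bin_width = 15,
                           normalize = FALSE) {
  stopifnot(all(c("x", "y", "value") %in% names(values)), bin_width > 0)
  r <- sqrt((values$x - center[1])^2 + (values$y - center[2])^2)
  bin <- round(r / bin_width)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(bin = bin, value = values$value), .data$bin),
    value = mean(.data$value), n = dplyr::n(), .groups = "drop")
  agg <- agg[order(agg$bin), ]
  out <- tibble(r = agg$bin * bin_width, value = agg$value, n = agg$n)
  if (normalize) out$value <- out$value / max(out$value)
  class(out) <- c("cotune_profile", class(out))
  attr(out, "radial") <- TRUE
  out
}

#' Full width at half maximum of a spatial profile
#'
#' Half-maximum crossings are located by linear interpolation between bins,
#' taking the outermost crossings. Radial profiles (from [radial_profile()])
#' are reflected about the center before measuring, so the value returned is
#' a full width in both cases.
#'
#' @param profile a `cotune_profile`, or any data frame with a position
#'   column (`r` or `x`) and a `value` column.
#' @return width (um).
#' @export
half_width <- function(profile) {
  pos_col <- if ("r" %in% names(profile)) "r" else "x"
  x <- profile[[pos_col]]
  y <- profile$value
  if (isTRUE(attr(profile, "radial")) || pos_col == "r") {
    o <- order(x)
    x <- x[o]; y <- y[o]
    x <- c(-rev(x), x)
    y <- c(rev(y), y)
  }
  fwhm_linear(x, y)
}

#' Per-cell peak synaptic conductances onto P cells
#'
#' For every P cell, the maximum of the sweep-averaged conductance trace of
#' each pathway within a window (peak of the mean trace, robust to sweep
#' noise). The composite excitatory conductance sums the thalamic and
#' recurrent traces before taking the peak.
#'
#' @param record a `sim_record` with conductance traces.
#' @param window peak-search window `c(start, end)` (ms).
#' @return tibble with `cell`, `x`, `y`, `thal`, `rec`, `inh`, `exc`.
#' @export
conductance_peaks <- function(record, window = c(0, 50)) {
  stopifnot(inherits(record, "sim_record"))
  keep <- record$cond$times >= window[1] & record$cond$times <= window[2]
  if (!any(keep)) stop("recording window does not cover the requested window")
  pk <- function(m) apply(m[, keep, drop = FALSE], 1, max)
  tibble(cell = record$p_coords$cell,
         x = record$p_coords$x, y = record$p_coords$y,
         thal = pk(record$cond$thal), rec = pk(record$cond$rec),
         inh = pk(record$cond$inh),
         exc = pk(record$cond$thal + record$cond$rec))
}

#' Inhibitory-to-excitatory tuning width ratio of a simulation
#'
#' The package's central measurement: radial profiles of per-cell peak
#' FS-inhibitory and composite excitatory (thalamic + recurrent) conductance
#' onto P cells are reduced to half-widths, and their ratio reported. Values
#' above 1 indicate lateral inhibition, values near 1 co-tuning.
#'
#' @param record a `sim_record`.
#' @param window analysis window (ms).
#' @param bin_width radial bin width (um).
#' @return one-row tibble with `w_exc`, `w_inh` (um) and `ratio`; `ratio` is
#'   `NA` when the inhibitory profile is identically zero.
#' @export
ei_width_ratio <- function(record, window = c(0, 50), bin_width = 15) {
  pk <- conductance_peaks(record, window)
  center <- record$center
  pe <- radial_profile(dplyr::rename(pk[c("x", "y", "exc")], value = "exc"),
                       center = center, bin_width = bin_width)
  pinh <- radial_profile(dplyr::rename(pk[c("x", "y", "inh")], value = "inh"),
                         center = center, bin_width = bin_width)
  if (max(pinh$value) <= 0) {
    return(tibble(w_exc = half_width(pe), w_inh = NA_real_, ratio = NA_real_))
  }
  w_exc <- half_width(pe)
  w_inh <- half_width(pinh)
  tibble(w_exc = w_exc, w_inh = w_inh, ratio = w_inh / w_exc)
}

#' Two-tone response curve
#'
#' Mean spike count of the cell nearest the first stimulus center (S1) as a
#' function of the separation of a second, identical stimulus, with the
#' single-stimulus count attached as baseline. Sideband suppression shows as
#' counts dipping below the baseline at intermediate separations.
#'
#' @param records named list of `sim_record`s from two-tone drives; names (or
#'   the drives themselves) give the separation.
#' @param baseline a single-stimulus `sim_record` at matched `n_max` and
#'   `sigma`.
#' @param window counting window (ms).
#' @param r_max radius (um) of the neighborhood around the S1 center whose
#'   cells are averaged; averaging a small annulus rather than the single
#'   nearest cell reduces count quantization across sweeps.
#' @return tibble with `delta_x` (um), `count`, `baseline`.
#' @export
two_tone_curve <- function(records, baseline, window = c(0, 50), r_max = 30) {
  stopifnot(inherits(baseline, "sim_record"))
  base_drive <- baseline$drive
  center_count <- function(rec) {
    cw <- count_window(rec, window = window)
    r <- sqrt((cw$x - rec$center[1])^2 + (cw$y - rec$center[2])^2)
    mean(cw$count[r <= max(r_max, min(r))])
  }
  rows <- purrr::map_dfr(records, function(rec) {
    stopifnot(inherits(rec, "sim_record"))
    if (!isTRUE(all.equal(rec$drive$n_max, base_drive$n_max)) ||
        !isTRUE(all.equal(rec$drive$sigma, base_drive$sigma))) {
      stop("two-tone records must match the baseline's n_max and sigma")
    }
    dx <- if (nrow(rec$drive$centers) == 2) {
      unname(rec$drive$centers[2, 1] - rec$drive$centers[1, 1])
    } else 0
    tibble(delta_x = dx, count = center_count(rec))
  })
  rows$baseline <- center_count(baseline)
  dplyr::arrange(rows, .data$delta_x)
}

#' Gain and onset summary of count-versus-input curves
#'
#' Summarises center-cell count vs `n_max` curves measured at several input
#' widths: the least-squares slope over the supra-onset range, the onset (the
#' first `n_max` with a nonzero count), and whether the family is consistent
#' with a purely divisive gain change (slopes differ while onsets agree
#' within one `n_max` grid step).
#'
#' @param counts tibble with columns `sigma`, `n_max`, `count` (one row per
#'   condition), at least 4 `n_max` points per `sigma`.
#' @return list with `summary` (tibble: `sigma`, `slope`, `onset`,
#'   `degenerate`) and `divisive` (logical flag).
#' @export
gain_summary <- function(counts) {
  stopifnot(all(c("sigma", "n_max", "count") %in% names(counts)))
  sm <- purrr::map_dfr(split(counts, counts$sigma), function(df) {
    df <- df[order(df$n_max), ]
    if (nrow(df) < 4) stop("need at least 4 n_max points per sigma")
    nz <- which(df$count > 0)
    if (length(nz) == 0) {
      return(tibble(sigma = df$sigma[1], slope = NA_real_, onset = NA_real_,
                    degenerate = TRUE))
    }
    onset <- df$n_max[nz[1]]
    supra <- df[df$n_max >= onset, ]
    slope <- if (nrow(supra) >= 2) {
      unname(coef(lm(count ~ n_max, data = supra))[2])
    } else NA_real_
    tibble(sigma = df$sigma[1], slope = slope, onset = onset,
           degenerate = FALSE)
  })
  steps <- diff(sort(unique(counts$n_max)))
  step <- if (length(steps)) min(steps) else 0
  ok <- !sm$degenerate & is.finite(sm$slope)
  divisive <- sum(ok) >= 2 &&
    (max(sm$slope[ok]) - min(sm$slope[ok])) > 0.05 * max(abs(sm$slope[ok])) &&
    (max(sm$onset[ok]) - min(sm$onset[ok])) <= step
  list(summary = sm, divisive = divisive)
}
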