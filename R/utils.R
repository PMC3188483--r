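# internal helpers shared across modules

# round half away from zero (x >= 0 in all uses); base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a master seed (kept below 2^31)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1103515245 + 12345 + 97 * k) %% 2147483647
}

#' Full width at half maximum of a sampled profile
#'
#' Measures the width of a single-peaked profile at half its peak value by
#' linear interpolation between lattice points, taking the outermost
#' half-maximum crossings on each side of the peak.
#'
#' @param x positions (ascending).
#' @param y values at `x` (non-negative, single dominant peak).
#' @return width in the units of `x`.
#' @keywords internal
fwhm_linear <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= 0) stop("profile has no positive peak")
  half <- ymax / 2
  ipk <- which.max(y)
  above <- y >= half
  # outermost crossing left of peak: last transition below->above at or before peak
  left <- NA_real_
  for (i in seq_len(ipk)) {
    if (above[i]) {
      left <- if (i == 1) x[1] else {
        x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
      }
      break
    }
  }
  right <- NA_real_
  n <- length(y)
  for (i in seq(n, ipk)) {
    if (above[i]) {
      right <- if (i == n) x[n] else {
        x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
      }
      break
    }
  }
  if (!is.finite(left) || !is.finite(right)) stop("half-maximum crossing not found")
  if ((identical(left, x[1]) && y[1] > half) || (identical(right, x[n]) && y[n] > half))
    stop("profile does not fall below half maximum within range")
  right - left
}
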